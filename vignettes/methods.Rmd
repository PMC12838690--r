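---
title: "Habituation-aware adaptive neuro-fuzzy stimulation control: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Habituation-aware adaptive neuro-fuzzy stimulation control: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anfishab)
```

## The problem

Insect bio-bots are steered by electrical micro-stimulation of sensory
nerves: a pulse on the left antennal pathway evokes a turn away from the
perceived obstacle, i.e. to the right of the stimulated side (we abstract
the signed geometry into a left/right turn command). Two properties of the
living actuator dominate the control problem:

* **Habituation.** Repeated stimulation attenuates the behavioural
  response, on a fast timescale that recovers within minutes and a slow
  timescale that accumulates over the better part of an hour.
* **Inter-individual variability.** Response thresholds differ by tens of
  percent between specimens (we model a 45% coefficient of variation), so
  any fixed stimulation amplitude is simultaneously too strong for some
  animals and sub-threshold for others.

`anfishab` implements a closed-loop controller that addresses both — an
8-input/3-output first-order Takagi–Sugeno ANFIS with hybrid learning,
a habituation observer, and a compensating stimulation scheduler — plus a
virtual-insect plant rich enough to exercise every mechanism, and a
benchmark harness against a frozen PID fuzzy-hybrid baseline and natural
(unstimulated) behaviour.

## Model components

### Fuzzy inference core

The controller maps the sensed state
$(\mathrm{Prox}_F, \mathrm{Prox}_B, V_{lin}, V_{ang},
 D_{targ}, e_{bear}, \dot V_{ang}, \hat H)$
to stimulation amplitude (V), frequency (Hz) and duration (ms).  Each
input carries 3–5 fuzzy sets (32 in total); membership functions are
two-sided Gaussians
$\mu(x) = \exp\{-(x-c)^2/2\sigma_{1,2}^2\}$ (left/right widths), with the
generalized bell $1/(1+|(x-c)/a|^{2b})$ available as an alternative kind.
Rule firing is the product T-norm, normalized to a partition of unity, and
rule consequents are affine in the inputs; the output is the single-
normalization weighted average
$y = \sum_i \bar w_i (p_{i0} + \sum_j p_{ij} x_j)$.
A literal reading of the printed layer equations would apply $\bar w_i$
twice; that variant breaks convexity (a constant-consequent system could
leave the convex hull of its consequents) and contradicts the stated
weighted-average defuzzification, so it exists only behind
`compat_double_weight` for comparison.

The bearing error is fuzzified on a normalized scale ($e_{bear}/180 \in
[-1,1]$) so that all partitions live on unit-comparable ranges; every
other input is fuzzified in its native normalized range.

The rule base holds ~105 rules (bounded 80–150).  It is *never* the full
$4\cdot4\cdot4\cdot5\cdot4\cdot5\cdot3\cdot3 = 57{,}600$ antecedent grid:
initial rules come from clustering a seed batch of sampled states onto
their per-input argmax-membership tuples, keeping the most frequent
distinct tuples.  Online, a state at which no rule reaches the normalized
firing threshold $\varepsilon_{fire} = 0.1$ grows a new rule (antecedent =
argmax memberships; consequent = the current aggregate output's
linearization, so the output surface is unchanged at the growth point),
and beyond the cap the rule with the lowest exponentially discounted
cumulative firing utility is pruned.

### Hybrid learning on two timescales

Consequents are estimated by recursive least squares with forgetting
factor $\lambda = 0.995$,
$K = Pa/(\lambda + a^\top P a)$, $\theta' = \theta + K(y - a^\top\theta)$,
$P' = (P - Ka^\top P)/\lambda$ (re-symmetrized; $P_0 = 10^3 I$,
$\theta_0 = 0$), with the regressor $a$ laid out rule-by-rule as
$\bar w_i\,(1, x)$.  Membership (premise) parameters are refined on the
slow timescale by damped Gauss–Newton: solve
$(J^\top J + \lambda_{lm}\,\mathrm{diag}(J^\top J))\,\Delta\alpha =
J^\top e$ with a forward-finite-difference Jacobian (relative step
$10^{-6}$), accept only if the batch RMSE decreases, damping ÷10 on
acceptance and ×10 on rejection (start $10^{-2}$, give up past $10^{12}$).
Gradient descent with momentum (learning rate 0.01, momentum 0.9) is the
config-selectable alternative, since the configuration summary prescribes
it while the algorithm listing prescribes the damped Gauss–Newton; both
are first-class and neither is presumed.

Two engineering choices keep the 10 Hz loop tractable in interpreted R
and are documented deviations, not behavioural changes:

* the ~105-rule online controller adapts consequents by **local** per-rule
  weighted RLS (the standard evolving-Takagi–Sugeno local-learning
  scheme) rather than one global 945-parameter filter per channel; the
  global filter is used verbatim everywhere its contract is tested and in
  offline training;
* online premise refinement is exercised through
  `dual_timescale_update()` (every `n_premise = 50` samples on a
  500-sample sliding window) but is not re-run inside closed-loop trials.

### Habituation dynamics

The latent habituation state has fast and slow components driven by the
normalized stimulus $S(t) \in [0,1]$ (delivered amplitude over the safe
maximum):

$$dH_s = (-D_s H_s + I_s(v)\,S)\,dt + \sigma_s dW_s, \qquad
  dH_l = (-D_l H_l + I_l H_s)\,dt + \sigma_l dW_l,$$

with the velocity-dependent increment $I_s(v) = I_{s0} e^{-k_v v}$ —
habituation accrues more slowly in a fast-moving animal.  Integration is
Euler–Maruyama at fixed `dt` (stability guard
`dt <= 0.1/max(D_s, D_l)`), with both components clamped to $[0,1]$ by
projection after each step.  The scalar level used everywhere downstream
is the clamped sum $H = \min(1, H_s + H_l)$ (a weighted variant is
config-selectable); the combination rule is a documented default since no
canonical form exists.  Numeric defaults
($D_s = 0.02, D_l = 5\times10^{-4}, I_{s0} = 0.08, k_v = 1.5,
I_l = 0.002, \sigma_s = 0.005, \sigma_l = 0.001$ /s, `dt` 0.05 s)
are calibration choices reproducing the reported phenomenology:
noticeable short-term habituation after ~6–12 stimulation episodes at a
10 s cadence, roughly two-thirds recovery after a 5-minute rest, and a
dominant long-term component after ~45 minutes of operation.

The controller's **observer** integrates the same equations noise-free,
replaying exactly the stimulus drive delivered each control step (lagged
one step); its level feeds the `Hab_Lvl` input and the scheduler.  With a
noise-free matched plant the observer tracks the latent truth to within
the one-step integration lag.

### Compensating scheduler

Within a burst the amplitude envelope is chirp-modulated,
$P(t) = P_{base}(1 + A(H)\sin\phi(t))$ with
$\phi(t) = 2\pi\int_0^t (f_{start} + k_f H\tau)\,d\tau$ accumulated by
cumulative trapezoid (exact for constant $H$), so the temporal pattern
varies more as habituation grows.  $A(H) = 0.5H$ by default (affine,
bounded by 1 to keep the envelope non-negative).  Between bursts the rest
interval lengthens with habituation,
$\mathrm{IBI}(H) = \mathrm{IBI}_{max} - (\mathrm{IBI}_{max} -
\mathrm{IBI}_{min})e^{-kH}$, defaults 2–30 s with $k = 3$; commands are
also suppressed inside a 10° bearing deadband ("stimulate only when
instinct deviates from the path").  $f_{start} = 25$ Hz sits inside the
20–80 Hz band where responsiveness is strongest; outputs are always
clipped to the safe ranges (0–3 V, 10–200 Hz, 50–500 ms).

### Virtual insect

A specimen is a thresholded, saturating, habituation-attenuated turning
responder with Wiener-cascade dynamics: supra-threshold drive
$u = g_f(f)\max(0, A - \theta_{thr})$ → first-order low-pass
($\tau_c = 0.4$ s) → static saturation
$s\,\tanh(z/s)$ → turn rate $\times\,\mathrm{gain}\times(1-H)$, signed by
the stimulated side.  $g_f$ is a trapezoid over 10–200 Hz, flat at 1 in
20–80 Hz.  Thresholds and gains are sampled log-normally with CV 0.45
(mean preserved).  Natural locomotion is an Ornstein–Uhlenbeck heading
jitter (6 deg/s, $\tau$ 1 s) plus speed fluctuation around 5 cm/s; these
walk parameters, the nominal turn gain (60 deg/s per V) and the arena
(200×200 cm, 8 cm completion radius) are calibration knobs of this
package, chosen once for a realistic mid-sized walker, not measured
values.

### What the synthetic plant does and does not establish

No real behavioural dataset is available to this package
and none of its plant parameters are printed, so the virtual insect is a
*structurally* faithful stand-in: thresholded saturating responses,
frequency band-pass, dual-timescale stochastic habituation,
inter-individual spread, exploratory walk.  A green closed-loop test
establishes that the adaptive machinery beats a frozen baseline *in this
stated world* and that every analytic contract holds; it does not
establish behavioural equivalence to any living species, and the live
headline magnitudes (81% maze completion, MAE 12.3°, ECD 47 min,
half-life > 250 stimuli) are explicitly out of reach at desk scale.

## Experiment design

**Time compression.** Hour-scale habituation phenomena are run at a 10×
compressed clock: all habituation rates ×10, noise scales ×√10 — the
exact substitution $t \to t/10$ — with the rest-interval bounds scaled by
the same factor, because they are calibrated to recovery time constants.
Durations measured on the compressed clock convert back through the same
factor (ECD is reported in *equivalent minutes*).

**Protocols.** Navigation precision and temporal stability are measured
separately, as such systems are conventionally reported: short multi-waypoint
navigation courses — a maze-traversal proxy in which successive targets
must be reached under a per-leg time budget, so later legs are attempted
at elevated habituation (completion rate = legs completed / legs
attempted, completion time per leg, bearing MAE, response time,
consistency index) — and one long endurance run with periodic
retargeting for the rolling performance score.  The performance
score is $0.5(1 - \overline{|e_{bear}|}/180) + 0.5\,\bar\rho$ over a
trailing window, where $\rho$ is the per-command ratio of the realized
turn response to the habituation-free prediction (clipped to $[0,1]$;
zero until a controller has ever stimulated, carried forward between
commands).  ECD is the first crossing below 0.5.  The score is this
package's operationalization — the study plots such a score without
defining it.  Similarly the consistency index (undefined in the source)
is the percentage of commands whose response crosses 25% of the
habituation-free prediction within 2 s.

**Online specimen adaptation.** The online stream pairs each state with
the *realized* response: the controller compares the observed peak turn
rate after each command against its nominal-plant prediction and scales
the amplitude channel toward unit response ratio (bounded ×0.5–×2.5),
while local RLS keeps distilling the compensation policy into the rule
base.  This is the mechanism that lets the adaptive controller serve
high-threshold/low-gain specimens that defeat any fixed amplitude — the
variability argument for adaptive control.  The PID fuzzy-hybrid baseline
(PID on normalized bearing with anti-windup, a static 3×2 demand×proximity
lookup of fixed amplitude/frequency/duration, fixed rest interval) is
tuned once on the habituation-free plant and frozen, operationalizing
"fixed-parameter".

**Paired design.** Every comparison pairs controllers on identical worlds
(same specimen draw, same initial state, same target sequence, same
seed), and reports win fractions with ties counted one half.  In the
habituation-ablated world the ECD advantage collapses to near-tie — the
compensation machinery has nothing to compensate — while a residual
completion advantage on hard specimens remains, attributable to the
variability mechanism, not habituation.

## Numerical choices and degenerate inputs

* Membership degrees below $10^{-300}$ are flushed to zero so products
  over 8 inputs cannot denormalize; an all-silent rule base signals a
  `NoActiveRule` condition, and the controller's policy is to emit no
  command and grow a rule at the offending state.
* Inputs outside their admissible range are clipped before fuzzification;
  bearing angles are wrapped to $(-180, 180]$, never clipped.
* The damped-normal-matrix diagonal is floored at $10^{-12}$ so a locally
  inert parameter cannot make the system singular; widths are kept
  strictly positive by projection.
* Model serialization writes 17 significant digits, which round-trips
  IEEE doubles exactly.
* All randomness flows through R's seeded RNG; identical seeds give
  byte-identical telemetry files.

**The synthetic expert.** Training targets come from a synthetic expert
policy standing in for operator-guided ground truth: amplitude, frequency
and duration grow with a *saturating* urgency `tanh(2.2·|e|)`, the
habituation compensation interacts with urgency (a hard correction at
high habituation earns the amplitude ceiling, a small trim does not),
bursts shorten near frontal obstacles and lengthen for a slow-moving
animal, and the frequency stays inside the high-responsiveness band.
The curvature and interactions are deliberate: a practised operator's
choices are not affine, and an affine policy would be exactly
representable by a first-order Sugeno system at *any* rule count, making
rule-capacity studies vacuous.

**Rule-cap ablation caveat.** Even with the nonlinear expert, the
capacity effect measurable offline (policy approximation RMSE improves
from cap 45 to 105 and saturates beyond — the diminishing-returns shape)
does not propagate into closed-loop completion rates here: the residual
amplitude error across caps (~0.23–0.26 V RMSE) is small against the 45%
specimen threshold spread and the response-feedback loop absorbs most of
it, so paired-seed completion differences between caps sit inside seed
noise.  The corresponding acceptance check is therefore expected to fail
in this stated world, and is left failing rather than re-scoped; the
capacity-performance coupling reported for the live system evidently
runs through mechanisms (operator-data richness, decision content in the
rule base) that this synthetic world does not reproduce.

## Known limitations

* No analytic back-propagation through the fuzzy layers; Jacobians are
  finite-difference (adequate at these parameter counts, slow beyond).
* Frequency affects drive efficacy but habituation is amplitude-driven
  only; frequency-dependent habituation is out of scope.
* The plant is planar with symmetric left/right actuation; climbing,
  cercal acceleration channels and real sensor drivers are out of scope.
* The expert policy that generates training targets is synthetic; with an
  operator-guided dataset the same training path applies unchanged.
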