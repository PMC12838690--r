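Package: anfishab
Title: Adaptive Neuro-Fuzzy Stimulation Control with Habituation Compensation
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Closed-loop neurostimulation control for insect bio-bots, built
    around a first-order Takagi-Sugeno adaptive neuro-fuzzy inference system
    (ANFIS) trained by hybrid recursive least squares and damped Gauss-Newton
    (Levenberg-Marquardt) refinement on two timescales.  Includes a
    continuous-time dual-state habituation model (coupled short- and long-term
    stochastic differential equations with velocity-dependent increments), a
    habituation-compensating stimulation scheduler (linear-chirp amplitude
    modulation and adaptive inter-burst intervals), a virtual-insect plant
    simulator with inter-specimen variability and Wiener-cascade response
    dynamics, fixed-parameter PID-fuzzy and natural-behaviour baselines, and a
    trial runner with habituation-resistance and directional-control metrics
    for paired controller comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
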