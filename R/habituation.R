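#' Habituation model parameters
#'
#' Continuous-time dual-state habituation: a fast short-term component
#' \eqn{H_s} driven by the stimulus with a velocity-dependent increment, and
#' a slow long-term component \eqn{H_l} charged by \eqn{H_s}:
#' \deqn{dH_s = (-D_s H_s + I_s(v)\,S)\,dt + \sigma_s\, dW_s}
#' \deqn{dH_l = (-D_l H_l + I_l\, H_s)\,dt + \sigma_l\, dW_l}
#' \deqn{I_s(v) = I_{s0}\, e^{-k_v v}}
#' so habituation accrues more slowly while the animal is moving fast.
#' Both components are clamped to `[0, 1]` after each step.
#'
#' Defaults are calibrated to the phenomenology of repeated-stimulation
#' experiments on hissing cockroaches: noticeable short-term habituation
#' after 6-12 stimulation episodes, roughly 65% recovery after a 5-minute
#' rest, and a long-term component that dominates after ~45 minutes of
#' operation.  They are calibration choices of this package, not measured
#' constants.
#'
#' @param D_s,D_l decay rates (1/s, > 0) of the short/long components.
#' @param I_s0 baseline short-term increment rate (1/s, >= 0).
#' @param k_v velocity sensitivity (unitless, >= 0).
#' @param I_l coupling rate from short- into long-term (1/s, >= 0).
#' @param sigma_s,sigma_l Wiener-noise scales (>= 0).
#' @param dt Euler-Maruyama step (s, > 0); must satisfy
#'   `dt <= 0.1 / max(D_s, D_l)` for integrator stability.
#' @return an object of class `hab_params`.
#' @export
hab_params <- function(D_s = 0.02, D_l = 5e-4, I_s0 = 0.08, k_v = 1.5,
                       I_l = 0.002, sigma_s = 0.005, sigma_l = 0.001,
                       dt = 0.05) {
  stopifnot(D_s > 0, D_l > 0, I_s0 >= 0, k_v >= 0, I_l >= 0,
            sigma_s >= 0, sigma_l >= 0, dt > 0)
  if (dt > 0.1 / max(D_s, D_l))
    stop("dt = ", dt, " too large for stability: need dt <= ",
         0.1 / max(D_s, D_l))
  structure(list(D_s = D_s, D_l = D_l, I_s0 = I_s0, k_v = k_v, I_l = I_l,
                 sigma_s = sigma_s, sigma_l = sigma_l, dt = dt),
            class = "hab_params")
}

#' Habituation state
#'
#' @param H_s,H_l component levels in `[0, 1]`.
#' @param t elapsed time (s).
#' @return an object of class `hab_state`.
#' @export
hab_state <- function(H_s = 0, H_l = 0, t = 0) {
  stopifnot(H_s >= 0, H_s <= 1, H_l >= 0, H_l <= 1)
  structure(list(H_s = H_s, H_l = H_l, t = t), class = "hab_state")
}

#' Velocity-dependent short-term increment
#'
#' \eqn{I_s(v) = I_{s0} e^{-k_v v}}: monotone non-increasing in the
#' normalized velocity.
#'
#' @param v normalized linear velocity (>= 0).
#' @param params a [hab_params()] object.
#' @return increment rate (1/s).
#' @export
short_term_increment <- function(v, params) {
  stopifnot(all(v >= 0))
  params$I_s0 * exp(-params$k_v * v)
}

#' One Euler-Maruyama habituation step
#'
#' @param state a [hab_state()].
#' @param S stimulus drive in `[0, 1]` (amplitude normalized to the safe
#'   maximum).
#' @param v normalized linear velocity in `[0, 1]`.
#' @param params a [hab_params()].
#' @return updated [hab_state()]; both components clamped to `[0, 1]`.
#'   Noise draws use the current R RNG stream, so a seeded run is
#'   bit-reproducible.
#' @export
hab_step <- function(state, S, v, params) {
  dt <- params$dt
  zs <- if (params$sigma_s > 0) stats::rnorm(1) else 0
  zl <- if (params$sigma_l > 0) stats::rnorm(1) else 0
  Hs <- state$H_s +
    (-params$D_s * state$H_s + short_term_increment(v, params) * S) * dt +
    params$sigma_s * sqrt(dt) * zs
  Hl <- state$H_l +
    (-params$D_l * state$H_l + params$I_l * state$H_s) * dt +
    params$sigma_l * sqrt(dt) * zl
  state$H_s <- clip(Hs, 0, 1)
  state$H_l <- clip(Hl, 0, 1)
  state$t <- state$t + dt
  state
}

#' Combined habituation level
#'
#' The scalar level consumed by the scheduler and the controller's
#' `Hab_Lvl` input.  Default rule: `min(1, H_s + H_l)`; a weighted sum
#' (still clamped at 1) is available via the weights.
#'
#' @param state a [hab_state()].
#' @param w_s,w_l component weights (default 1, 1).
#' @return combined level in `[0, 1]`.
#' @export
combined_level <- function(state, w_s = 1, w_l = 1) {
  min(1, w_s * state$H_s + w_l * state$H_l)
}

#' Simulate a habituation trajectory
#'
#' Integrates the two-component system over `n_steps` with (possibly
#' time-varying) drive and velocity.  The inner loop is inlined for speed;
#' it is algebraically identical to repeated [hab_step()] calls and draws
#' the same per-step normal deviates in the same order.
#'
#' @param params a [hab_params()].
#' @param n_steps number of steps.
#' @param S drive: scalar or vector of length `n_steps`.
#' @param v velocity: scalar or vector of length `n_steps`.
#' @param state0 initial [hab_state()].
#' @return data.frame `t, H_s, H_l, H, S, v` with one row per step
#'   (post-update values).
#' @export
hab_simulate <- function(params, n_steps, S = 0, v = 0, state0 = hab_state()) {
  S <- rep_len(S, n_steps); v <- rep_len(v, n_steps)
  dt <- params$dt; sdt <- sqrt(dt)
  Hs <- state0$H_s; Hl <- state0$H_l
  out_s <- numeric(n_steps); out_l <- numeric(n_steps)
  Is <- params$I_s0 * exp(-params$k_v * v)
  for (i in seq_len(n_steps)) {
    zs <- if (params$sigma_s > 0) stats::rnorm(1) else 0
    zl <- if (params$sigma_l > 0) stats::rnorm(1) else 0
    Hs_new <- Hs + (-params$D_s * Hs + Is[i] * S[i]) * dt +
      params$sigma_s * sdt * zs
    Hl_new <- Hl + (-params$D_l * Hl + params$I_l * Hs) * dt +
      params$sigma_l * sdt * zl
    Hs <- min(max(Hs_new, 0), 1)
    Hl <- min(max(Hl_new, 0), 1)
    out_s[i] <- Hs; out_l[i] <- Hl
  }
  data.frame(t = state0$t + dt * seq_len(n_steps),
             H_s = out_s, H_l = out_l,
             H = pmin(1, out_s + out_l), S = S, v = v)
}
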