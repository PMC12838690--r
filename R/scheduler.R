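#' Chirp modulation parameters
#'
#' The stimulation envelope is amplitude-modulated by a linear chirp whose
#' instantaneous frequency grows with the habituation level:
#' \deqn{f(t) = f_{start} + k_f\, H(t)\, t, \qquad
#'       P(t) = P_{base}(t)\,\{1 + A(H(t))\,\sin \phi(t)\},}
#' \deqn{\phi(t) = 2\pi \int_0^t f(\tau)\, d\tau.}
#' As habituation grows the stimulus becomes both stronger and more varied
#' in its temporal pattern, countering neural adaptation.  The modulation
#' depth map defaults to the affine `A(H) = A1 * H` with `A1` in `[0, 1]`
#' so the modulated envelope stays non-negative for non-negative `P_base`.
#'
#' @param f_start base frequency (Hz, > 0); default 25 Hz sits inside the
#'   20-80 Hz band where responsiveness is strongest.
#' @param k_f chirp gain (Hz/s per unit habituation, >= 0).
#' @param A1 affine modulation-depth coefficient in `[0, 1]`.
#' @return an object of class `chirp_params`.
#' @export
chirp_params <- function(f_start = 25, k_f = 5, A1 = 0.5) {
  stopifnot(f_start > 0, k_f >= 0, A1 >= 0, A1 <= 1)
  structure(list(f_start = f_start, k_f = k_f, A1 = A1),
            class = "chirp_params")
}

mod_depth <- function(H, params) params$A1 * H

#' Accumulated chirp phase on a time grid
#'
#' \eqn{\phi(t) = 2\pi \int_0^t (f_{start} + k_f H(\tau) \tau)\, d\tau}
#' by cumulative trapezoid; exact for constant `H` (the integrand is then
#' linear in `t`).  `phi[1] = 0` and the phase is non-decreasing for
#' in-range inputs.
#'
#' @param times uniform, increasing time grid starting at the burst origin.
#' @param H habituation series on the grid, values in `[0, 1]`.
#' @param params a [chirp_params()].
#' @return phase series (radians), same length as `times`.
#' @export
chirp_phase <- function(times, H, params) {
  stopifnot(length(times) == length(H), all(H >= 0), all(H <= 1))
  f <- params$f_start + params$k_f * H * (times - times[1])
  n <- length(times)
  if (n == 1L) return(0)
  dt <- diff(times)
  2 * pi * c(0, cumsum(dt * (f[-n] + f[-1]) / 2))
}

#' Chirp-modulate a pulse envelope
#'
#' \eqn{P(t) = P_{base}(t)\,(1 + A(H(t)) \sin\phi(t))}; the envelope bound
#' \eqn{|P| \le P_{base} (1 + A_{max})} holds pointwise.
#'
#' @param P_base base envelope series (>= 0).
#' @param H habituation series on the same grid.
#' @param times the grid.
#' @param params a [chirp_params()].
#' @return modulated series.
#' @export
modulate_pulse <- function(P_base, H, times, params) {
  stopifnot(length(P_base) == length(times), length(H) == length(times))
  phi <- chirp_phase(times, H, params)
  P_base * (1 + mod_depth(H, params) * sin(phi))
}

#' Adaptive inter-burst interval parameters
#'
#' @param IBI_min,IBI_max interval bounds (s, `0 < IBI_min <= IBI_max`).
#' @param k scaling (> 0): how aggressively the rest period lengthens with
#'   habituation.
#' @return an object of class `ibi_params`.
#' @export
ibi_params <- function(IBI_min = 2, IBI_max = 30, k = 3) {
  stopifnot(IBI_min > 0, IBI_min <= IBI_max, k > 0)
  structure(list(IBI_min = IBI_min, IBI_max = IBI_max, k = k),
            class = "ibi_params")
}

#' Habituation-adaptive inter-burst interval
#'
#' \deqn{IBI(H) = IBI_{max} - (IBI_{max} - IBI_{min})\, e^{-k H}}
#' Strictly increasing in `H` for `k > 0`, equal to `IBI_min` at `H = 0`,
#' and approaching `IBI_max` as `k H` grows: the controller rests the
#' preparation longer the more habituated it estimates it to be.
#'
#' @param H habituation level in `[0, 1]` (vectorized).
#' @param params an [ibi_params()].
#' @return interval(s) in seconds, always within `[IBI_min, IBI_max]`.
#' @export
inter_burst_interval <- function(H, params) {
  stopifnot(all(H >= 0), all(H <= 1))
  params$IBI_max - (params$IBI_max - params$IBI_min) * exp(-params$k * H)
}

#' Stimulation command
#'
#' @param amplitude volts.
#' @param frequency Hz; must lie in the configured safe band.
#' @param duration ms (> 0 when a side is stimulated).
#' @param ibi scheduled inter-burst interval (s).
#' @param side `"left"`, `"right"` or `"none"`.
#' @return an object of class `stim_command`.
#' @export
stim_command <- function(amplitude, frequency, duration, ibi,
                         side = c("none", "left", "right")) {
  side <- match.arg(side)
  if (side != "none" && duration <= 0) stop("stimulated command needs duration > 0")
  structure(list(amplitude = amplitude, frequency = frequency,
                 duration = duration, ibi = ibi, side = side),
            class = "stim_command")
}
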