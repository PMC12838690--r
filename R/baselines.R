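#' Fixed-parameter PID fuzzy-hybrid baseline
#'
#' PID on the normalized bearing error produces a signed turn demand; a
#' static fuzzy lookup (three demand-magnitude bins crossed with two
#' frontal-proximity bins) maps the demand to fixed amplitude, frequency
#' and duration.  The inter-burst interval is fixed, the gains are frozen
#' at construction, and nothing is learned online — this operationalizes
#' the fixed-parameter comparison system.  The integral term carries an
#' anti-windup clamp.
#'
#' Gains were tuned once on the habituation-free plant (see
#' `scripts/tune_pid.R`) and then frozen.
#'
#' @param Kp,Ki,Kd gains on the normalized bearing error (error / 180).
#' @param i_max integral clamp (absolute bound).
#' @param dev_threshold_deg no-stimulation deadband (deg).
#' @param ibi_fixed fixed inter-burst interval (s).
#' @param amp_table,freq_table,dur_table 3 x 2 lookup tables
#'   (rows: demand small/medium/large; cols: path clear / obstacle near).
#' @param dt control step (s).
#' @return a `pid_fuzzy_controller` (environment).
#' @export
pid_fuzzy <- function(Kp = 0.8, Ki = 0.05, Kd = 0.2, i_max = 2,
                      dev_threshold_deg = 10, ibi_fixed = 2,
                      amp_table = rbind(c(1.8, 1.6), c(2.2, 2.0), c(2.6, 2.4)),
                      freq_table = rbind(c(30, 30), c(40, 40), c(50, 50)),
                      dur_table = rbind(c(150, 100), c(250, 150), c(350, 200)),
                      dt = 0.1) {
  ctrl <- new.env(parent = emptyenv())
  ctrl$Kp <- Kp; ctrl$Ki <- Ki; ctrl$Kd <- Kd; ctrl$i_max <- i_max
  ctrl$dev_threshold_deg <- dev_threshold_deg
  ctrl$ibi_fixed <- ibi_fixed
  ctrl$amp_table <- amp_table; ctrl$freq_table <- freq_table
  ctrl$dur_table <- dur_table
  ctrl$dt <- dt
  ctrl$integ <- 0; ctrl$prev_err <- NA_real_
  ctrl$burst_until <- -Inf; ctrl$next_allowed <- -Inf; ctrl$burst <- NULL
  class(ctrl) <- c("pid_fuzzy_controller", "environment")
  ctrl
}

#' One control step of the PID fuzzy-hybrid baseline
#'
#' @param ctrl a [pid_fuzzy()] controller.
#' @param sensors named sensed state from [sense()].
#' @param t current time (s).
#' @return same contract as [control_step()]; `H` is always `NA` (the
#'   baseline carries no habituation estimate).
#' @export
pid_fuzzy_step <- function(ctrl, sensors, t) {
  dt <- ctrl$dt
  if (!is.null(ctrl$burst) && t < ctrl$burst_until) {
    return(list(command = NULL, drive = ctrl$burst, H = NA_real_))
  }
  err <- wrap_angle(sensors[["Err_Bear"]]) / 180
  derr <- if (is.na(ctrl$prev_err)) 0 else (err - ctrl$prev_err) / dt
  ctrl$prev_err <- err
  ctrl$integ <- clip(ctrl$integ + err * dt, -ctrl$i_max, ctrl$i_max)
  if (t < ctrl$next_allowed)
    return(list(command = NULL, drive = NULL, H = NA_real_))
  if (abs(err) * 180 < ctrl$dev_threshold_deg) {
    if (abs(ctrl$integ) < 1e-12)
      return(list(command = NULL, drive = NULL, H = NA_real_))
    return(list(command = NULL, drive = NULL, H = NA_real_))
  }
  demand <- clip(ctrl$Kp * err + ctrl$Ki * ctrl$integ + ctrl$Kd * derr, -1, 1)
  if (demand == 0) return(list(command = NULL, drive = NULL, H = NA_real_))
  mag_bin <- findInterval(abs(demand), c(1 / 3, 2 / 3)) + 1L
  prox_bin <- if (sensors[["Prox_F"]] > 0.5) 2L else 1L
  amp <- ctrl$amp_table[mag_bin, prox_bin]
  freq <- ctrl$freq_table[mag_bin, prox_bin]
  dur <- ctrl$dur_table[mag_bin, prox_bin]
  side <- if (demand > 0) "left" else "right"
  cmd <- stim_command(amp, freq, dur, ctrl$ibi_fixed, side)
  ctrl$burst_until <- t + dur / 1000
  ctrl$next_allowed <- ctrl$burst_until + ctrl$ibi_fixed
  ctrl$burst <- list(amplitude = amp, frequency = freq, side = side)
  list(command = cmd, drive = ctrl$burst, H = NA_real_)
}

#' Reset the baseline's run state
#' @param ctrl a [pid_fuzzy()] controller.
#' @return the controller, invisibly.
#' @export
reset_pid <- function(ctrl) {
  ctrl$integ <- 0; ctrl$prev_err <- NA_real_
  ctrl$burst_until <- -Inf; ctrl$next_allowed <- -Inf; ctrl$burst <- NULL
  invisible(ctrl)
}

# uniform stepping interface over the three controller kinds
controller_kind <- function(ctrl) {
  if (inherits(ctrl, "anfis_controller")) "anfis"
  else if (inherits(ctrl, "pid_fuzzy_controller")) "pid"
  else if (identical(ctrl, "natural")) "natural"
  else stop("unknown controller type")
}

step_controller <- function(ctrl, sensors, t) {
  switch(controller_kind(ctrl),
         anfis = control_step(ctrl, sensors, t),
         pid = pid_fuzzy_step(ctrl, sensors, t),
         natural = list(command = NULL, drive = NULL, H = NA_real_))
}

reset_any <- function(ctrl) {
  switch(controller_kind(ctrl),
         anfis = reset_controller(ctrl),
         pid = reset_pid(ctrl),
         natural = invisible(NULL))
}
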