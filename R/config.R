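#' Default experiment configuration
#'
#' One structured document with sections `plant`, `habituation`,
#' `controller`, `scheduler`, `arena` and `experiment`; every field is
#' overridable from a JSON config file (the package's structured-text
#' config dialect).
#'
#' @return nested named list of defaults.
#' @export
default_config <- function() {
  list(
    plant = list(threshold = 1.0, gain = 60, tau_c = 0.4, sat_drive = 2.0,
                 speed_mean = 0.50, speed_sd = 0.10, speed_tau = 2.0,
                 turn_sigma = 6, turn_tau = 1.0, v_max = 10, ang_max = 180,
                 amp_max = 3.0, walk_noise = TRUE, variability = 0.45),
    habituation = list(D_s = 0.02, D_l = 5e-4, I_s0 = 0.08, k_v = 1.5,
                       I_l = 0.002, sigma_s = 0.005, sigma_l = 0.001,
                       dt = 0.05, speedup = 1),
    controller = list(rule_bounds = c(80, 150), rule_target = 105,
                      eps_fire = 0.1, util_discount = 0.99,
                      dev_threshold_deg = 10, amp_range = c(0, 3),
                      freq_range = c(10, 200), dur_range = c(50, 500),
                      lambda = 0.995, lr = 0.01, momentum = 0.9,
                      n_premise = 50, online_rls = TRUE, seed_batch = 3000),
    scheduler = list(f_start = 25, k_f = 5, A1 = 0.5,
                     IBI_min = 2, IBI_max = 30, k = 3),
    baseline_pid = list(Kp = 0.8, Ki = 0.05, Kd = 0.2, i_max = 2,
                        dev_threshold_deg = 10, ibi_fixed = 2),
    arena = list(width = 200, height = 200, target = c(160, 160),
                 completion_radius = 8),
    experiment = list(dt = 0.1, duration = 360, leg_budget = 60,
                      window_s = 30, n_seeds = 20)
  )
}

# recursive override of defaults by a partial list
merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a configuration file
#'
#' @param path JSON file with any subset of the [default_config()]
#'   sections; missing fields keep their defaults.
#' @return full configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config file not found: ", path)
  merge_config(cfg, jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Write a configuration file
#'
#' @param cfg configuration list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Instantiate package objects from a configuration
#'
#' @param cfg a configuration list from [read_config()].
#' @return list `profile` ([specimen_profile()]), `hab` ([hab_params()],
#'   speedup applied), `ctrl_cfg` ([controller_config()]),
#'   `pid` (a fresh [pid_fuzzy()]), `arena` ([arena()]), `experiment`
#'   (the experiment section), `time_factor`.
#' @export
config_objects <- function(cfg = default_config()) {
  h <- cfg$habituation
  hp <- hab_params(D_s = h$D_s, D_l = h$D_l, I_s0 = h$I_s0, k_v = h$k_v,
                   I_l = h$I_l, sigma_s = h$sigma_s, sigma_l = h$sigma_l,
                   dt = h$dt)
  if ((h$speedup %||% 1) > 1) hp <- hab_speedup(hp, h$speedup)
  p <- cfg$plant
  profile <- specimen_profile(threshold = p$threshold, gain = p$gain,
                              tau_c = p$tau_c, sat_drive = p$sat_drive,
                              hab = hp, speed_mean = p$speed_mean,
                              speed_sd = p$speed_sd, speed_tau = p$speed_tau,
                              turn_sigma = p$turn_sigma, turn_tau = p$turn_tau,
                              v_max = p$v_max, ang_max = p$ang_max,
                              amp_max = p$amp_max, walk_noise = p$walk_noise)
  ctl <- cfg$controller; sch <- cfg$scheduler
  # time compression rescales every habituation-tied duration: the
  # inter-burst rest bounds and the fixed baseline rest shrink by the same
  # factor as the recovery time constants they are calibrated to
  kappa <- h$speedup %||% 1
  if (kappa > 1) {
    sch$IBI_min <- max(sch$IBI_min / kappa, 2 * cfg$experiment$dt)
    sch$IBI_max <- max(sch$IBI_max / kappa, sch$IBI_min)
    cfg$baseline_pid$ibi_fixed <-
      max(cfg$baseline_pid$ibi_fixed / kappa, 2 * cfg$experiment$dt)
  }
  ctrl_cfg <- controller_config(
    rule_bounds = ctl$rule_bounds, rule_target = ctl$rule_target,
    eps_fire = ctl$eps_fire, util_discount = ctl$util_discount,
    dev_threshold_deg = ctl$dev_threshold_deg, amp_range = ctl$amp_range,
    freq_range = ctl$freq_range, dur_range = ctl$dur_range,
    lambda = ctl$lambda, lr = ctl$lr, momentum = ctl$momentum,
    n_premise = ctl$n_premise,
    chirp = chirp_params(sch$f_start, sch$k_f, sch$A1),
    ibi = ibi_params(sch$IBI_min, sch$IBI_max, sch$k),
    hab = hp, dt = cfg$experiment$dt, online_rls = ctl$online_rls,
    seed_batch = ctl$seed_batch)
  b <- cfg$baseline_pid
  ar <- cfg$arena
  list(profile = profile, hab = hp, ctrl_cfg = ctrl_cfg,
       pid = function() pid_fuzzy(Kp = b$Kp, Ki = b$Ki, Kd = b$Kd,
                                  i_max = b$i_max,
                                  dev_threshold_deg = b$dev_threshold_deg,
                                  ibi_fixed = b$ibi_fixed,
                                  dt = cfg$experiment$dt),
       arena = arena(ar$width, ar$height, target = ar$target,
                     completion_radius = ar$completion_radius),
       experiment = cfg$experiment,
       time_factor = h$speedup %||% 1)
}
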