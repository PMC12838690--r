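#' Time-compress habituation dynamics
#'
#' Rescales all rate constants by `factor` (and the noise scales by
#' `sqrt(factor)`), which is exactly the substitution `t -> t / factor` in
#' the two stochastic differential equations.  Used to run hour-scale
#' habituation phenomena in desk-scale simulated minutes; durations
#' measured on the compressed clock multiply back by `factor` to give
#' equivalent real minutes.
#'
#' @param params a [hab_params()].
#' @param factor compression factor (>= 1).
#' @return a [hab_params()] with scaled rates.
#' @export
hab_speedup <- function(params, factor) {
  stopifnot(factor >= 1)
  hab_params(D_s = params$D_s * factor, D_l = params$D_l * factor,
             I_s0 = params$I_s0 * factor, k_v = params$k_v,
             I_l = params$I_l * factor,
             sigma_s = params$sigma_s * sqrt(factor),
             sigma_l = params$sigma_l * sqrt(factor),
             dt = min(params$dt, 0.1 / (factor * max(params$D_s, params$D_l))))
}

#' Run one closed-loop trial
#'
#' Fixed-step loop: sense, controller step, plant step.  In single-target
#' mode the trial ends at completion (inside the completion radius) or
#' timeout.  With `retarget = TRUE` a fresh random target is drawn whenever
#' the current one is reached or its per-leg time budget expires, so the
#' trial sustains navigation pressure for the full duration (the endurance
#' protocol behind the effective-control-duration metric).
#'
#' @param ctrl an `anfis_controller`, a [pid_fuzzy()] controller, or the
#'   string `"natural"`.
#' @param profile a [specimen_profile()].
#' @param arena_obj an [arena()].
#' @param duration trial length (s).
#' @param dt control step (s).
#' @param seed integer; seeds all trial randomness (target sequence and
#'   plant noise), so identical seeds give byte-identical telemetry.
#' @param retarget logical; endurance mode.
#' @param leg_budget per-leg time budget (s) in endurance mode.
#' @param start initial [plant_state()].
#' @return object of class `trial_telemetry`: a list with `steps` (one
#'   data.frame row per control step), `completed`, `completion_time`,
#'   `legs_attempted`, `legs_completed`, `duration`, `dt`, `seed`.
#' @export
run_trial <- function(ctrl, profile, arena_obj, duration, dt = 0.1,
                      seed = 1L, retarget = FALSE, leg_budget = 45,
                      start = plant_state()) {
  set.seed(seed)
  n <- floor(duration / dt)
  # pre-drawn target sequence so paired controllers see identical targets
  n_targets <- max(2L, ceiling(duration / 10))
  tgt_x <- stats::runif(n_targets, 0.15, 0.85) * arena_obj$width
  tgt_y <- stats::runif(n_targets, 0.15, 0.85) * arena_obj$height
  reset_any(ctrl)
  state <- start
  cols <- c("t", "x", "y", "heading", "v_lin", "v_ang", "turn_cmd",
            "err_bear", "dist_targ", "H_s", "H_l", "H_obs", "cmd_issued",
            "cmd_amp", "cmd_freq", "cmd_dur", "cmd_ibi", "cmd_side",
            "drive_amp", "drive_side", "leg", "target_x", "target_y")
  M <- matrix(0, n, length(cols), dimnames = list(NULL, cols))
  leg <- 1L; leg_start <- 0; legs_done <- 0L
  leg_times <- numeric(0)
  completed <- FALSE; completion_time <- NA_real_
  cur_target <- arena_obj$target
  i <- 0L
  t <- 0
  while (i < n) {
    i <- i + 1L
    arena_obj$target <- cur_target
    hl <- if (inherits(ctrl, "anfis_controller")) combined_level(ctrl$obs) else 0
    sensors <- sense(state, arena_obj, hab_lvl = hl, dt = dt)
    if (!all(is.finite(sensors)) ||
        !all(is.finite(c(state$x, state$y, state$heading)))) {
      M <- M[seq_len(i - 1L), , drop = FALSE]
      return(structure(list(steps = as.data.frame(M), completed = FALSE,
                            completion_time = NA_real_, aborted = TRUE,
                            diagnostic = "non-finite state",
                            legs_attempted = leg, legs_completed = legs_done,
                            duration = duration, dt = dt, seed = seed),
                       class = "trial_telemetry"))
    }
    out <- step_controller(ctrl, sensors, t)
    drv <- out$drive
    state <- plant_step(state, drv, profile, dt, arena_obj = arena_obj)
    t <- t + dt
    cmd <- out$command
    side_num <- function(s) if (is.null(s)) 0 else switch(s, left = 1, right = -1, 0)
    M[i, ] <- c(t, state$x, state$y, state$heading, state$v_lin, state$v_ang,
                attr(state, "turn_cmd") %||% 0,
                sensors[["Err_Bear"]], sensors[["Dist_Targ"]],
                state$hab$H_s, state$hab$H_l,
                if (is.na(out$H)) 0 else out$H,
                as.numeric(!is.null(cmd)),
                cmd$amplitude %||% 0, cmd$frequency %||% 0,
                cmd$duration %||% 0, cmd$ibi %||% 0,
                side_num(cmd$side),
                if (is.null(drv)) 0 else drv$amplitude,
                side_num(drv$side),
                leg, cur_target[1], cur_target[2])
    dist <- sqrt((cur_target[1] - state$x)^2 + (cur_target[2] - state$y)^2)
    if (dist <= arena_obj$completion_radius) {
      legs_done <- legs_done + 1L
      leg_times <- c(leg_times, t - leg_start)
      if (!retarget) {
        completed <- TRUE; completion_time <- t
        M <- M[seq_len(i), , drop = FALSE]
        break
      }
      leg <- leg + 1L; leg_start <- t
      cur_target <- c(tgt_x[(leg - 1L) %% n_targets + 1L],
                      tgt_y[(leg - 1L) %% n_targets + 1L])
    } else if (retarget && t - leg_start >= leg_budget) {
      leg <- leg + 1L; leg_start <- t
      cur_target <- c(tgt_x[(leg - 1L) %% n_targets + 1L],
                      tgt_y[(leg - 1L) %% n_targets + 1L])
    }
  }
  if (retarget) { completed <- legs_done > 0L }
  structure(list(steps = as.data.frame(M), completed = completed,
                 completion_time = completion_time, aborted = FALSE,
                 legs_attempted = leg, legs_completed = legs_done,
                 leg_times = leg_times,
                 duration = duration, dt = dt, seed = seed),
            class = "trial_telemetry")
}

#' Write / read telemetry as CSV
#'
#' The per-step table round-trips through a plain CSV with documented
#' headers; metric calculators are pure functions of this table, so
#' recomputing from the stored file reproduces a report exactly.
#'
#' @param telemetry a `trial_telemetry`.
#' @param path file path.
#' @return `path` (write) / a `trial_telemetry` without outcome fields (read).
#' @export
telemetry_write <- function(telemetry, path) {
  utils::write.csv(telemetry$steps, path, row.names = FALSE)
  invisible(path)
}

#' @rdname telemetry_write
#' @export
telemetry_read <- function(path) {
  steps <- utils::read.csv(path)
  structure(list(steps = steps, completed = NA, completion_time = NA_real_,
                 legs_attempted = max(steps$leg %||% 1L),
                 legs_completed = NA_integer_,
                 duration = max(steps$t), dt = stats::median(diff(steps$t)),
                 seed = NA_integer_),
            class = "trial_telemetry")
}

# habituation-free steady-state turn response (deg/s) to a command
predicted_response <- function(amp, freq, profile) {
  u <- freq_gain(freq) * pmax(0, amp - profile$threshold)
  profile$gain * profile$sat_drive * tanh(u / profile$sat_drive)
}

# per-command response events: peak stimulus-evoked turn rate within the
# detection window, latency to cross the detection threshold
command_responses <- function(steps, profile, dt, window_s = 2,
                              detect_frac = 0.25) {
  idx <- which(steps$cmd_issued == 1)
  if (!length(idx))
    return(data.frame(t = numeric(), peak = numeric(), predicted = numeric(),
                      latency = numeric(), detected = logical()))
  w <- max(1L, round(window_s / dt))
  n <- nrow(steps)
  out <- lapply(idx, function(i) {
    j <- i:min(n, i + w)
    resp <- steps$cmd_side[i] * steps$turn_cmd[j]
    pred <- predicted_response(steps$cmd_amp[i], steps$cmd_freq[i], profile)
    cross <- which(resp >= detect_frac * pred)
    data.frame(t = steps$t[i], peak = max(resp), predicted = pred,
               latency = if (length(cross)) (cross[1] - 1) * dt else NA_real_,
               detected = length(cross) > 0)
  })
  do.call(rbind, out)
}

#' Directional-control metrics from telemetry
#'
#' @param telemetry a `trial_telemetry`.
#' @param profile the [specimen_profile()] the trial ran against (for the
#'   habituation-free reference response).
#' @param v_min locomotion threshold on normalized linear velocity; steps
#'   below it are excluded from the bearing-error average.
#' @return list: `mae_deg` (mean absolute bearing error over locomoting
#'   steps), `response_time_s` (median command-to-response latency),
#'   `consistency_pct` (% of commands with a supra-threshold response),
#'   `path_efficiency_pct`, `n_commands`.  Response metrics are `NA` when
#'   no commands were issued.
#' @export
navigation_metrics <- function(telemetry, profile, v_min = 0.05) {
  s <- telemetry$steps
  dt <- telemetry$dt
  moving <- s$v_lin > v_min
  mae <- mean(abs(wrap_angle(s$err_bear[moving])))
  path_len <- sum(sqrt(diff(s$x)^2 + diff(s$y)^2))
  straight <- sqrt((s$x[nrow(s)] - s$x[1])^2 + (s$y[nrow(s)] - s$y[1])^2)
  eff <- if (path_len > 0) clip(100 * straight / path_len, 0, 100) else NA_real_
  cr <- command_responses(s, profile, dt)
  if (!nrow(cr)) {
    return(list(mae_deg = mae, response_time_s = NA_real_,
                consistency_pct = NA_real_, path_efficiency_pct = eff,
                n_commands = 0L))
  }
  list(mae_deg = mae,
       response_time_s = stats::median(cr$latency, na.rm = TRUE),
       consistency_pct = 100 * mean(cr$detected),
       path_efficiency_pct = eff,
       n_commands = nrow(cr))
}

#' Repeated-stimulus habituation protocol (open loop)
#'
#' Applies identical supra-threshold pulses at a fixed cadence to a plant
#' with stationary velocity, then rests it, probing the response during
#' rest.  Used by the habituation-resistance metrics.
#'
#' @param profile a [specimen_profile()].
#' @param n_stimuli number of identical pulses.
#' @param period cadence (s per pulse; default one pulse every 10 s).
#' @param amplitude,frequency,duration_ms the fixed pulse.
#' @param rest_s rest length after the train (s).
#' @param probe_period during rest, a probe pulse every this many seconds.
#' @param dt integration step (s).
#' @param seed RNG seed.
#' @param noise logical; `FALSE` freezes walk noise for deterministic runs
#'   (habituation noise follows the profile's sigma fields).
#' @return list `train` (data.frame: stimulus index, time, peak response),
#'   `rest` (data.frame: time into rest, peak probe response).
#' @export
run_habituation_protocol <- function(profile, n_stimuli = 50, period = 10,
                                     amplitude = 2.5, frequency = 30,
                                     duration_ms = 300, rest_s = 300,
                                     probe_period = 60, dt = 0.05,
                                     seed = 1L, noise = FALSE) {
  set.seed(seed)
  if (!noise) profile$walk_noise <- FALSE
  state <- plant_state(x = 100, y = 100, heading = 0, v_lin = profile$speed_mean)
  pulse_steps <- max(1L, round(duration_ms / 1000 / dt))
  gap_steps <- max(1L, round(period / dt) - pulse_steps)
  stim <- list(amplitude = amplitude, frequency = frequency, side = "left")
  peak_of_pulse <- function(state) {
    peak <- 0
    for (k in seq_len(pulse_steps)) {
      state <- plant_step(state, stim, profile, dt)
      peak <- max(peak, attr(state, "turn_cmd"))
    }
    state$cascade <- 0  # pulse ends; drive collapses
    list(state = state, peak = peak)
  }
  train <- data.frame(stimulus = seq_len(n_stimuli), t = NA_real_,
                      response = NA_real_)
  t <- 0
  for (m in seq_len(n_stimuli)) {
    train$t[m] <- t
    r <- peak_of_pulse(state)
    state <- r$state
    train$response[m] <- r$peak
    for (k in seq_len(gap_steps)) state <- plant_step(state, NULL, profile, dt)
    t <- t + period
  }
  probes <- seq(probe_period, rest_s, by = probe_period)
  rest <- data.frame(t_rest = probes, response = NA_real_)
  t_in_rest <- 0
  for (p in seq_along(probes)) {
    gap <- probes[p] - t_in_rest
    for (k in seq_len(round(gap / dt))) state <- plant_step(state, NULL, profile, dt)
    t_in_rest <- probes[p]
    r <- peak_of_pulse(state)
    state <- r$state
    rest$response[p] <- r$peak
  }
  list(train = train, rest = rest)
}

#' Habituation-resistance metrics
#'
#' @param train data.frame with a `response` column, one row per stimulus
#'   of the fixed-cadence train (at least 2).
#' @param rest optional data.frame `t_rest`, `response` of probe responses
#'   during rest.
#' @return list: `half_life` (number of repeated stimuli needed to halve
#'   the first response, i.e. for geometric decay `r^n` it equals
#'   `ceiling(log(0.5) / log(r))`; `Inf` when never reached), `mrl_pct`
#'   (maintained response level, final / initial x 100), `recovery_rate_pct_min`
#'   (mean percent of the initial response regained per minute of rest;
#'   `NA` without rest data).
#' @export
habituation_metrics <- function(train, rest = NULL) {
  r <- train$response
  if (length(r) < 2) stop("habituation metrics need at least 2 stimuli")
  below <- which(r <= 0.5 * r[1])
  half_life <- if (length(below)) below[1] - 1L else Inf
  mrl <- 100 * r[length(r)] / r[1]
  rr <- NA_real_
  if (!is.null(rest) && nrow(rest) > 0) {
    gain_pct <- 100 * (rest$response[nrow(rest)] - r[length(r)]) / r[1]
    rr <- gain_pct / (rest$t_rest[nrow(rest)] / 60)
  }
  list(half_life = half_life, mrl_pct = mrl, recovery_rate_pct_min = rr)
}

#' Rolling performance score and effective control duration
#'
#' Score at time `t`: `0.5 * (1 - mean |bearing error| / 180)` over the
#' trailing window plus `0.5 *` the mean per-command response ratio
#' (stimulus-evoked peak over the habituation-free prediction, clipped to
#' `[0, 1]`) over the same window; windows without commands carry the last
#' known ratio forward (zero until the first command is ever issued — a
#' controller that has never stimulated has no control authority).  The
#' effective control duration is
#' the first time the score falls below `threshold`, converted to
#' equivalent minutes through `time_factor` (the habituation compression
#' factor); if the score never falls below, the trial duration is returned
#' and `censored` is `TRUE`.
#'
#' @param telemetry a `trial_telemetry`.
#' @param profile the trial's [specimen_profile()].
#' @param window_s rolling window (s, on the trial clock).
#' @param threshold score threshold (default 0.5).
#' @param time_factor compression factor to equivalent minutes.
#' @return list `score` (data.frame t, score), `ecd_min`, `censored`.
#' @export
performance_score <- function(telemetry, profile, window_s = 30,
                              threshold = 0.5, time_factor = 1) {
  s <- telemetry$steps
  dt <- telemetry$dt
  n <- nrow(s)
  w <- max(1L, round(window_s / dt))
  cr <- command_responses(s, profile, dt)
  ratio_at <- rep(NA_real_, n)
  if (nrow(cr)) {
    ii <- pmin(n, pmax(1L, round(cr$t / dt)))
    ratio_at[ii] <- clip(cr$peak / cr$predicted, 0, 1)
  }
  abs_err <- abs(wrap_angle(s$err_bear))
  score <- numeric(n)
  last_ratio <- 0
  cum_err <- cumsum(abs_err)
  for (i in seq_len(n)) {
    j0 <- max(1L, i - w + 1L)
    m_err <- (cum_err[i] - if (j0 > 1L) cum_err[j0 - 1L] else 0) / (i - j0 + 1L)
    rr <- ratio_at[j0:i]
    rr <- rr[!is.na(rr)]
    if (length(rr)) last_ratio <- mean(rr)
    score[i] <- 0.5 * (1 - m_err / 180) + 0.5 * last_ratio
  }
  below <- which(score < threshold & s$t > window_s)
  ecd_s <- if (length(below)) s$t[below[1]] else telemetry$duration
  list(score = data.frame(t = s$t, score = score),
       ecd_min = ecd_s * time_factor / 60,
       censored = !length(below))
}

#' Paired multi-seed controller comparison
#'
#' For each seed, every controller faces the identical plant world (same
#' sampled specimen, same initial state, same target sequence) in two
#' protocols, mirroring how navigation precision and temporal stability are
#' reported separately: `n_nav` short multi-waypoint navigation courses
#' (a maze-traversal proxy — each course strings successive targets under
#' a per-leg time budget, so later legs are attempted at elevated
#' habituation; completion rate = legs completed / legs attempted) and one
#' long endurance run with periodic retargeting (rolling performance
#' score, effective control duration, maintained response level).  Paired
#' win fractions count ties one half.
#'
#' @param factories named list of zero-argument functions, each returning a
#'   fresh controller (so learning state never leaks between seeds); the
#'   first entry is the reference controller of the win fractions.
#' @param n_seeds number of paired seeds (>= 2).
#' @param profile_nominal nominal [specimen_profile()].
#' @param variability inter-specimen threshold/gain spread (CV).
#' @param arena_obj an [arena()].
#' @param nav_duration navigation-trial cap (s).
#' @param n_nav navigation trials per seed.
#' @param duration endurance-trial length (s).
#' @param dt control step (s).
#' @param leg_budget endurance per-leg budget (s).
#' @param window_s,time_factor passed to [performance_score()].
#' @param base_seed offset added to each seed index.
#' @return list `trials` (one row per controller x seed: completion_pct,
#'   mean_time_s, mae_deg, response_time_s, consistency_pct, ecd_min,
#'   mrl_pct, legs), `summary` (mean and sd per controller), `wins`
#'   (paired win fraction of the reference controller for ECD and
#'   completion).
#' @export
compare_controllers <- function(factories, n_seeds = 20,
                                profile_nominal = specimen_profile(),
                                variability = 0.45,
                                arena_obj = arena(), nav_duration = 120,
                                n_nav = 2, duration = 360,
                                dt = 0.1, leg_budget = 60, window_s = 30,
                                time_factor = 1, base_seed = 0L) {
  stopifnot(n_seeds >= 2, length(names(factories)) == length(factories))
  rows <- list()
  for (s in seq_len(n_seeds)) {
    seed <- base_seed + s
    specimen <- sample_specimen(profile_nominal, variability,
                                seed = 7000L + seed)
    for (nm in names(factories)) {
      ctrl <- factories[[nm]]()
      # navigation protocol: fresh habituation state per course
      done <- times <- rep(NA_real_, n_nav)
      maes <- resp <- cons <- rep(NA_real_, n_nav)
      for (k in seq_len(n_nav)) {
        reset_any(ctrl)
        tel <- run_trial(ctrl, specimen, arena_obj, nav_duration, dt = dt,
                         seed = seed + 500L * (k - 1L), retarget = TRUE,
                         leg_budget = leg_budget)
        done[k] <- tel$legs_completed / max(tel$legs_attempted, 1L)
        times[k] <- if (length(tel$leg_times)) mean(tel$leg_times) else NA_real_
        nav <- navigation_metrics(tel, specimen)
        maes[k] <- nav$mae_deg; resp[k] <- nav$response_time_s
        cons[k] <- nav$consistency_pct
      }
      # endurance protocol
      reset_any(ctrl)
      tel <- run_trial(ctrl, specimen, arena_obj, duration, dt = dt,
                       seed = seed, retarget = TRUE, leg_budget = leg_budget)
      ps <- performance_score(tel, specimen, window_s = window_s,
                              time_factor = time_factor)
      cr <- command_responses(tel$steps, specimen, dt)
      mrl <- if (nrow(cr) >= 2)
        100 * clip(cr$peak[nrow(cr)] / cr$predicted[nrow(cr)], 0, 1) /
          max(clip(cr$peak[1] / cr$predicted[1], 0, 1), 1e-9)
      else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        controller = nm, seed = seed,
        completion_pct = 100 * mean(done),
        mean_time_s = mean(times, na.rm = TRUE),
        mae_deg = mean(maes, na.rm = TRUE),
        response_time_s = stats::median(resp, na.rm = TRUE),
        consistency_pct = mean(cons, na.rm = TRUE),
        ecd_min = ps$ecd_min, mrl_pct = mrl,
        legs = tel$legs_completed)
    }
  }
  trials <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(trials, trials$controller), function(d) {
    data.frame(controller = d$controller[1],
               completion_mean = mean(d$completion_pct),
               completion_sd = stats::sd(d$completion_pct),
               time_mean = mean(d$mean_time_s, na.rm = TRUE),
               mae_mean = mean(d$mae_deg, na.rm = TRUE),
               mae_sd = stats::sd(d$mae_deg, na.rm = TRUE),
               response_mean = mean(d$response_time_s, na.rm = TRUE),
               consistency_mean = mean(d$consistency_pct, na.rm = TRUE),
               ecd_mean = mean(d$ecd_min), ecd_sd = stats::sd(d$ecd_min),
               mrl_mean = mean(d$mrl_pct, na.rm = TRUE))
  }))
  rownames(summary) <- NULL
  ref <- names(factories)[1]
  wins <- list()
  for (nm in setdiff(names(factories), ref)) {
    a <- trials[trials$controller == ref, ]
    b <- trials[trials$controller == nm, ]
    a <- a[order(a$seed), ]; b <- b[order(b$seed), ]
    wf <- function(x, y) mean((x > y) + 0.5 * (x == y))
    wins[[nm]] <- c(ecd = wf(a$ecd_min, b$ecd_min),
                    completion = wf(a$completion_pct, b$completion_pct))
  }
  list(trials = trials, summary = summary, wins = wins)
}

#' Rule-cap ablation harness
#'
#' Re-runs the paired endurance protocol for a set of rule caps, holding
#' everything else fixed, to expose the diminishing-returns shape of the
#' cap-performance curve.
#'
#' @param caps integer vector of `max_rules` caps (the initial rule target
#'   is set to `min(cap, 105)` and the minimum bound scaled accordingly).
#' @param n_seeds paired seeds per cap.
#' @param config_fn function `cap -> controller_config`.
#' @param ... forwarded to [compare_controllers()]-style trial settings:
#'   `profile_nominal`, `arena_obj`, `duration`, `dt`, `leg_budget`,
#'   `base_seed`.
#' @return data.frame: cap, seed, completion_pct, mae_deg.
#' @export
rule_cap_ablation <- function(caps = c(45, 105, 135), n_seeds = 10,
                              config_fn, profile_nominal = specimen_profile(),
                              arena_obj = arena(), duration = 120, dt = 0.1,
                              n_nav = 2, base_seed = 100L) {
  rows <- list()
  for (cap in caps) {
    cfg <- config_fn(cap)
    template <- build_controller(cfg, seed = 11L)
    train_controller(template, seed = 12L)
    for (s in seq_len(n_seeds)) {
      seed <- base_seed + s
      specimen <- sample_specimen(profile_nominal, 0.45, seed = 7000L + seed)
      done <- maes <- rep(NA_real_, n_nav)
      for (k in seq_len(n_nav)) {
        ctrl <- clone_controller(template)
        tel <- run_trial(ctrl, specimen, arena_obj, duration, dt = dt,
                         seed = seed + 500L * (k - 1L), retarget = TRUE,
                         leg_budget = 45)
        done[k] <- tel$legs_completed / max(tel$legs_attempted, 1L)
        maes[k] <- navigation_metrics(tel, specimen)$mae_deg
      }
      rows[[length(rows) + 1L]] <- data.frame(
        cap = cap, seed = seed, completion_pct = 100 * mean(done),
        mae_deg = mean(maes))
    }
  }
  do.call(rbind, rows)
}
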