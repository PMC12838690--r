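#' Controller configuration
#'
#' Assembles the 8-input / 3-output controller configuration: fuzzy
#' partitions for the eight sensed state variables (MF counts 4, 4, 4, 5,
#' 4, 5, 3, 3 — 32 fuzzy sets in total) with the package's standard initial
#' centers and widths, rule-count bounds maintained online by grow/prune,
#' safe output ranges, learning settings, and scheduler parameters.
#'
#' The bearing error is fuzzified on a normalized scale (`Err_Bear / 180`,
#' range `[-1, 1]`) so that all partitions live on comparable unit ranges;
#' the sensed value stays in degrees everywhere else.
#'
#' @param rule_bounds `c(min_rules, max_rules)` (default `c(80, 150)`).
#' @param rule_target initial rule count aimed for by the seed-batch
#'   clustering (default 105, the accuracy-cost knee).
#' @param eps_fire growth threshold on the maximum normalized firing
#'   strength (default 0.1).
#' @param util_discount per-step discount of the rule-utility accumulator.
#' @param dev_threshold_deg no-stimulation deadband on the bearing error
#'   (deg, default 10).
#' @param amp_range,freq_range,dur_range safe output ranges: volts,
#'   Hz (default the 10-200 Hz safe band), milliseconds.
#' @param lambda RLS forgetting factor (default 0.995).
#' @param lr,momentum premise gradient-descent settings (0.01, 0.9).
#' @param n_premise slow-timescale period in control steps (default 50).
#' @param chirp a [chirp_params()].
#' @param ibi an [ibi_params()].
#' @param hab observer habituation parameters ([hab_params()]); the
#'   observer always runs them noise-free.
#' @param dt control step (s).
#' @param online_rls logical: per-step local consequent adaptation.
#' @param seed_batch size of the state sample used to cluster initial rules.
#' @return an object of class `controller_config`.
#' @export
controller_config <- function(rule_bounds = c(80, 150), rule_target = 105,
                              eps_fire = 0.1, util_discount = 0.99,
                              dev_threshold_deg = 10,
                              amp_range = c(0, 3), freq_range = c(10, 200),
                              dur_range = c(50, 500), lambda = 0.995,
                              lr = 0.01, momentum = 0.9, n_premise = 50,
                              chirp = chirp_params(), ibi = ibi_params(),
                              hab = hab_params(), dt = 0.1,
                              online_rls = TRUE, seed_batch = 3000) {
  if (rule_bounds[1] < 1) stop("min_rules must be >= 1")
  if (eps_fire <= 0 || eps_fire >= 1) stop("eps_fire must be in (0, 1)")
  if (freq_range[1] < 10 || freq_range[2] > 200)
    stop("frequency range must stay within the 10-200 Hz safe band")
  if (rule_target < rule_bounds[1] || rule_target > rule_bounds[2])
    stop("rule_target outside rule_bounds")
  structure(list(rule_bounds = rule_bounds, rule_target = rule_target,
                 eps_fire = eps_fire, util_discount = util_discount,
                 dev_threshold_deg = dev_threshold_deg,
                 amp_range = amp_range, freq_range = freq_range,
                 dur_range = dur_range, lambda = lambda, lr = lr,
                 momentum = momentum, n_premise = n_premise,
                 chirp = chirp, ibi = ibi, hab = hab, dt = dt,
                 online_rls = online_rls, seed_batch = seed_batch,
                 # response-feedback adaptation: nominal plant prior and
                 # the gain-control loop on realized vs expected response
                 resp_gain = 60, resp_threshold = 1.0, resp_sat = 2.0,
                 agc_rate = 0.25, agc_window = 1.2,
                 gamma_range = c(0.5, 2.5)),
            class = "controller_config")
}

# standard fuzzy partitions: centers/widths of the 32 fuzzy sets over the
# eight inputs (symmetric Gaussians, sigma1 = sigma2 = width)
controller_input_specs <- function() {
  gmfs <- function(centers, widths) {
    widths <- rep_len(widths, length(centers))
    Map(function(c, w) mf("asym_gaussian", c = c, sigma1 = w, sigma2 = w),
        centers, widths)
  }
  list(
    input_spec("Prox_F", 0, 1, gmfs(c(0.15, 0.40, 0.65, 0.90), 0.10)),
    input_spec("Prox_B", 0, 1, gmfs(c(0.15, 0.40, 0.65, 0.90), 0.10)),
    input_spec("Vel_Lin", 0, 1, gmfs(c(0.05, 0.30, 0.60, 0.90),
                                     c(0.05, 0.15, 0.15, 0.10))),
    input_spec("Vel_Ang", -1, 1, gmfs(c(-0.80, -0.30, 0.00, 0.30, 0.80),
                                      c(0.20, 0.20, 0.15, 0.20, 0.20))),
    input_spec("Dist_Targ", 0, 1, gmfs(c(0.10, 0.30, 0.60, 0.90),
                                       c(0.10, 0.15, 0.20, 0.10))),
    input_spec("Err_Bear", -1, 1, gmfs(c(-0.80, -0.40, 0.00, 0.40, 0.80),
                                       0.20)),
    input_spec("Accel_Ang", -1, 1, gmfs(c(-0.50, 0.00, 0.50),
                                        c(0.25, 0.20, 0.25))),
    input_spec("Hab_Lvl", 0, 1, gmfs(c(0.20, 0.50, 0.80), 0.15))
  )
}

# normalize a sensed state vector to the fuzzification scale
normalize_state <- function(sensors) {
  x <- unname(sensors[c("Prox_F", "Prox_B", "Vel_Lin", "Vel_Ang",
                        "Dist_Targ", "Err_Bear", "Accel_Ang", "Hab_Lvl")])
  x[6] <- wrap_angle(x[6]) / 180
  x
}

# Synthetic expert policy: the desk-scale stand-in for operator-guided
# ground truth.  Shaped like a practiced operator's choices rather than a
# linear law: corrective urgency saturates with the bearing error,
# habituation compensation interacts with urgency (a hard turn at high
# habituation gets the amplitude ceiling, a trim does not), bursts shorten
# near frontal obstacles and lengthen for a slow-moving animal, and the
# frequency stays inside the high-responsiveness band.
teacher_policy <- function(x, cfg) {
  eb <- abs(x[6])           # normalized |bearing error|
  H <- x[8]
  urgency <- tanh(2.2 * eb)                  # saturating, not linear
  amp <- 1.5 + 1.3 * urgency + 1.4 * H * (0.4 + 0.6 * urgency)
  freq <- 25 + 40 * urgency + 12 * H * (1 - 0.5 * urgency)
  dur <- (150 + 330 * urgency) * (1 - 0.35 * x[1]) +
    70 * H + 60 * (1 - x[3])
  c(clip(amp, cfg$amp_range[1], cfg$amp_range[2]),
    clip(freq, cfg$freq_range[1], cfg$freq_range[2]),
    clip(dur, cfg$dur_range[1], cfg$dur_range[2]))
}

# sample plausible normalized states (uniform over the fuzzification
# ranges) for rule clustering and offline training
sample_states <- function(n, model_inputs) {
  lo <- vapply(model_inputs, `[[`, numeric(1), "lo")
  hi <- vapply(model_inputs, `[[`, numeric(1), "hi")
  X <- matrix(stats::runif(n * length(lo)), n)
  sweep(sweep(X, 2, hi - lo, "*"), 2, lo, "+")
}

# per-input argmax MF index for every row of X
argmax_antecedents <- function(inputs, X) {
  A <- matrix(0L, nrow(X), length(inputs))
  for (i in seq_along(inputs)) {
    D <- vapply(inputs[[i]]$mfs, membership_degree, numeric(nrow(X)),
                x = X[, i])
    if (nrow(X) == 1L) D <- matrix(D, nrow = 1L)
    A[, i] <- max.col(D, ties.method = "first")
  }
  A
}

#' Build the adaptive ANFIS controller
#'
#' Sets up the eight fuzzy input partitions, generates the initial rule set
#' by clustering a seed batch of sampled states (each state maps to its
#' per-input argmax-MF antecedent tuple; the most frequent distinct tuples
#' are kept, so the combinatorial antecedent grid is never instantiated),
#' and initializes consequents to zero ahead of [train_controller()].
#'
#' @param config a [controller_config()].
#' @param seed integer seed controlling the rule clustering.
#' @return a controller object (environment of class `anfis_controller`).
#' @export
build_controller <- function(config, seed = 1L) {
  stopifnot(inherits(config, "controller_config"))
  set.seed(seed)
  inputs <- controller_input_specs()
  X <- sample_states(config$seed_batch, inputs)
  A <- argmax_antecedents(inputs, X)
  key <- apply(A, 1, paste, collapse = ",")
  tab <- sort(table(key), decreasing = TRUE)
  n_rules <- min(config$rule_target, length(tab))
  keys <- names(tab)[seq_len(n_rules)]
  ants <- lapply(strsplit(keys, ","), as.integer)
  # top up with random distinct tuples if the batch produced too few
  n_mf <- vapply(inputs, function(s) length(s$mfs), integer(1))
  while (length(ants) < config$rule_bounds[1]) {
    cand <- vapply(n_mf, function(k) sample.int(k, 1), integer(1))
    k <- paste(cand, collapse = ",")
    if (!k %in% keys) { keys <- c(keys, k); ants <- c(ants, list(cand)) }
  }
  zero_cons <- matrix(0, 3, length(inputs) + 1L)
  rules <- lapply(ants, anfis_rule, consequent = zero_cons)
  model <- anfis_model(inputs, rules, n_outputs = 3L)

  ctrl <- new.env(parent = emptyenv())
  ctrl$cfg <- config
  ctrl$model <- model
  ctrl$util <- rep(1, length(rules))
  ctrl$P_loc <- replicate(length(rules), diag(1e2, length(inputs) + 1L),
                          simplify = FALSE)
  obs_par <- config$hab
  obs_par$sigma_s <- 0; obs_par$sigma_l <- 0
  obs_par$dt <- config$dt
  ctrl$obs_par <- obs_par
  ctrl$obs <- hab_state()
  ctrl$phase <- 0
  ctrl$burst_start <- -Inf
  ctrl$burst_until <- -Inf
  ctrl$next_allowed <- -Inf
  ctrl$burst <- NULL
  ctrl$n_grown <- 0L
  ctrl$n_pruned <- 0L
  ctrl$n_no_active <- 0L
  ctrl$gamma <- 1          # specimen-adaptation amplitude scale
  ctrl$pending <- NULL     # response-observation window of the last command
  ctrl$S_last <- 0         # normalized drive delivered during the last step
  ctrl$trained <- FALSE
  class(ctrl) <- c("anfis_controller", "environment")
  ctrl
}

#' Offline-train a controller against the synthetic expert
#'
#' Fits the rule consequents to the expert policy on a batch of sampled
#' states by local weighted least squares (each rule solves its own
#' normalized-firing-weighted affine regression; the standard local
#' learning scheme for evolving Takagi-Sugeno systems, used here because
#' the global stacked regression over ~105 rules x 9 coefficients x 3
#' channels is needlessly ill-conditioned at this scale).
#'
#' @param ctrl a [build_controller()] result.
#' @param n_samples training-batch size.
#' @param seed RNG seed for the batch.
#' @return the controller, invisibly (modified in place).
#' @export
train_controller <- function(ctrl, n_samples = 3000, seed = 2L) {
  set.seed(seed)
  model <- ctrl$model
  X <- sample_states(n_samples, model$inputs)
  Y <- t(apply(X, 1, teacher_policy, cfg = ctrl$cfg))
  W <- matrix(0, n_samples, length(model$rules))
  keep <- rep(TRUE, n_samples)
  for (t in seq_len(n_samples)) {
    w <- firing_strengths(model, X[t, ])
    s <- sum(w)
    if (s == 0) { keep[t] <- FALSE; next }
    W[t, ] <- w / s
  }
  X <- X[keep, , drop = FALSE]; Y <- Y[keep, , drop = FALSE]
  W <- W[keep, , drop = FALSE]
  Xa <- cbind(1, X)
  for (i in seq_along(model$rules)) {
    wi <- W[, i]
    G <- crossprod(Xa * wi, Xa) + diag(1e-6, ncol(Xa))
    B <- crossprod(Xa * wi, Y)
    theta <- solve(G, B)                    # (n_in+1) x 3
    for (o in 1:3) model$Cons[[o]][i, ] <- theta[, o]
    model$rules[[i]]$consequent <- t(theta)
  }
  ctrl$model <- model
  ctrl$trained <- TRUE
  invisible(ctrl)
}

#' One control step of the adaptive controller
#'
#' Implements the per-step computational sequence: advance the noise-free
#' habituation observer with the stimulus actually delivered over the last
#' step; form the normalized 8-input state (with `Hab_Lvl` from the
#' observer); run the ANFIS forward pass; clip the three outputs to the
#' safe ranges; apply chirp modulation within the active burst and the
#' adaptive inter-burst interval between bursts; and gate out commands when
#' the bearing error is inside the deviation deadband or the refractory
#' window is open.  An all-rules-silent state emits no command and triggers
#' rule growth at that state.
#'
#' @param ctrl an `anfis_controller`.
#' @param sensors named sensed state from [sense()] (with `Hab_Lvl`
#'   ignored; the observer supplies it).
#' @param t current time (s).
#' @return list with `command` (a [stim_command()] when a new burst was
#'   issued, else `NULL`), `drive` (instantaneous delivered stimulus:
#'   `amplitude`, `frequency`, `side`, or `NULL` when silent) and `H`
#'   (observer level).
#' @export
control_step <- function(ctrl, sensors, t) {
  cfg <- ctrl$cfg; dt <- cfg$dt
  # (1) observer replay of the stimulus actually delivered last step (the
  # same normalized drive the plant received, lagged one control step)
  ctrl$obs <- hab_step(ctrl$obs, S = ctrl$S_last %||% 0,
                       v = clip(sensors[["Vel_Lin"]], 0, 1),
                       params = ctrl$obs_par)
  H <- combined_level(ctrl$obs)

  # response-feedback adaptation: watch the realized turn rate after each
  # command and trim the amplitude scale toward unit response ratio.  This
  # is the individual-specimen adaptation channel; the fixed baseline has
  # no counterpart.
  if (!is.null(ctrl$pending)) {
    pd <- ctrl$pending
    ach <- pd$side_sign * sensors[["Vel_Ang"]] * 180
    if (ach > pd$peak) ctrl$pending$peak <- ach
    if (t >= pd$t_end) {
      rho <- clip(ctrl$pending$peak / max(pd$predicted, 1e-6), 0, 2)
      ctrl$gamma <- clip(ctrl$gamma * (1 + cfg$agc_rate * (1 - rho)),
                         cfg$gamma_range[1], cfg$gamma_range[2])
      ctrl$pending <- NULL
    }
  }

  # (2) active burst: advance the chirp and deliver, no new decision
  if (!is.null(ctrl$burst) && t < ctrl$burst_until) {
    tb <- t - ctrl$burst_start
    f_inst <- cfg$chirp$f_start + cfg$chirp$k_f * H * tb
    ctrl$phase <- ctrl$phase + 2 * pi * f_inst * dt
    amp <- clip(ctrl$burst$P_base *
                  (1 + mod_depth(H, cfg$chirp) * sin(ctrl$phase)),
                cfg$amp_range[1], cfg$amp_range[2])
    ctrl$burst$amp_now <- amp
    ctrl$S_last <- amp / cfg$amp_range[2]
    return(list(command = NULL,
                drive = list(amplitude = amp,
                             frequency = ctrl$burst$frequency,
                             side = ctrl$burst$side),
                H = H))
  }
  ctrl$S_last <- 0

  # (3) gating: refractory window, then deviation deadband
  err_deg <- wrap_angle(sensors[["Err_Bear"]])
  if (t < ctrl$next_allowed || abs(err_deg) < cfg$dev_threshold_deg)
    return(list(command = NULL, drive = NULL, H = H))

  x <- normalize_state(sensors)
  x[8] <- H
  fw <- tryCatch(anfis_forward(ctrl$model, x),
                 anfishab_no_active_rule = function(e) NULL)
  if (is.null(fw)) {
    ctrl$n_no_active <- ctrl$n_no_active + 1L
    grow_prune_rules(ctrl, x)
    return(list(command = NULL, drive = NULL, H = H))
  }
  wbar <- fw$trace$normalized
  ctrl$util <- cfg$util_discount * ctrl$util + wbar
  if (max(wbar) < cfg$eps_fire) {
    grow_prune_rules(ctrl, x)
    fw <- anfis_forward(ctrl$model, x)
    wbar <- fw$trace$normalized
  }
  if (cfg$online_rls && ctrl$trained) local_rls_update(ctrl, x, wbar)

  amp <- clip(fw$y[1] * ctrl$gamma, cfg$amp_range[1], cfg$amp_range[2])
  freq <- clip(fw$y[2], cfg$freq_range[1], cfg$freq_range[2])
  dur <- clip(fw$y[3], cfg$dur_range[1], cfg$dur_range[2])
  side <- if (err_deg > 0) "left" else "right"
  side_sign <- if (err_deg > 0) 1 else -1
  ibi <- inter_burst_interval(H, cfg$ibi)
  cmd <- stim_command(amp, freq, dur, ibi, side)
  # expected response under the nominal plant prior, for the feedback loop
  u_hat <- freq_gain(freq) * max(0, amp - cfg$resp_threshold)
  pred <- cfg$resp_gain * cfg$resp_sat * tanh(u_hat / cfg$resp_sat) * (1 - H)
  ctrl$pending <- list(t_end = t + cfg$agc_window, peak = 0,
                       predicted = pred, side_sign = side_sign)

  ctrl$burst_start <- t
  ctrl$burst_until <- t + dur / 1000
  ctrl$next_allowed <- ctrl$burst_until + ibi
  ctrl$phase <- 0
  ctrl$burst <- list(P_base = amp, amp_now = amp, frequency = freq,
                     side = side)
  ctrl$S_last <- amp / cfg$amp_range[2]
  list(command = cmd,
       drive = list(amplitude = amp, frequency = freq, side = side),
       H = H)
}

# local (per-rule) consequent RLS toward the expert policy at the visited
# state; only appreciably firing rules are touched
local_rls_update <- function(ctrl, x, wbar, w_floor = 0.02) {
  cfg <- ctrl$cfg
  y <- teacher_policy(x, cfg)
  xa <- c(1, x)
  idx <- which(wbar > w_floor)
  for (i in idx) {
    P <- ctrl$P_loc[[i]]
    Pa <- P %*% xa
    K <- (wbar[i] * Pa) / (cfg$lambda + wbar[i] * sum(xa * Pa))
    for (o in 1:3) {
      err <- y[o] - sum(ctrl$model$Cons[[o]][i, ] * xa)
      ctrl$model$Cons[[o]][i, ] <- ctrl$model$Cons[[o]][i, ] + K * err
    }
    P <- (P - K %*% crossprod(xa, P)) / cfg$lambda
    ctrl$P_loc[[i]] <- (P + t(P)) / 2
  }
  invisible(ctrl)
}

#' Grow (and if necessary prune) rules at a poorly covered state
#'
#' Adds a rule whose antecedent picks, per input, the MF with the highest
#' degree at `x` (no new MFs are created).  Its consequent reproduces the
#' current aggregate output at `x` (the normalized-firing-weighted average
#' of the existing consequents); when no rule fires at all, the plain mean
#' is used.  If the cap is exceeded the lowest-utility rule is pruned, so
#' the count never leaves its bounds and at least one rule always remains.
#'
#' @param ctrl an `anfis_controller`.
#' @param x normalized input state.
#' @return the controller, invisibly (modified in place).
#' @export
grow_prune_rules <- function(ctrl, x) {
  model <- ctrl$model
  w_cur <- firing_strengths(model, x)
  s_cur <- sum(w_cur)
  if (s_cur > 0 && max(w_cur / s_cur) >= ctrl$cfg$eps_fire)
    return(invisible(ctrl))                   # already covered: no growth
  ant <- drop(argmax_antecedents(model$inputs, matrix(x, nrow = 1)))
  key <- paste(ant, collapse = ",")
  existing <- vapply(model$rules, function(r) paste(r$antecedent, collapse = ","), "")
  if (key %in% existing) return(invisible(ctrl))  # best tuple already present
  wt <- if (s_cur > 0) w_cur / s_cur else rep(1 / length(w_cur), length(w_cur))
  cons <- matrix(0, 3, length(x) + 1L)
  for (o in 1:3) cons[o, ] <- drop(crossprod(model$Cons[[o]], wt))
  model$rules[[length(model$rules) + 1L]] <- anfis_rule(ant, cons)
  ctrl$util <- c(ctrl$util, mean(ctrl$util))
  ctrl$P_loc <- c(ctrl$P_loc, list(diag(1e2, length(x) + 1L)))
  if (length(model$rules) > ctrl$cfg$rule_bounds[2]) {
    drop_i <- which.min(ctrl$util[-length(ctrl$util)])
    model$rules[[drop_i]] <- NULL
    ctrl$util <- ctrl$util[-drop_i]
    ctrl$P_loc <- ctrl$P_loc[-drop_i]
    ctrl$n_pruned <- ctrl$n_pruned + 1L
  }
  ctrl$model <- anfis_compile(model)
  ctrl$n_grown <- ctrl$n_grown + 1L
  invisible(ctrl)
}

#' Deep-copy a controller
#'
#' Controllers are environments (mutable in place); paired studies need an
#' identical fresh copy per seed without paying the build/train cost again.
#'
#' @param ctrl an `anfis_controller`.
#' @return an independent copy with identical state.
#' @export
clone_controller <- function(ctrl) {
  cp <- new.env(parent = emptyenv())
  for (nm in ls(ctrl, all.names = TRUE)) assign(nm, get(nm, envir = ctrl), envir = cp)
  class(cp) <- class(ctrl)
  cp
}

#' Number of active rules
#' @param ctrl an `anfis_controller`.
#' @return integer rule count.
#' @export
n_rules <- function(ctrl) length(ctrl$model$rules)

#' Reset the controller's run state (observer, scheduler, counters)
#'
#' Keeps the learned rule base; clears everything tied to a particular
#' trial so the same controller can be reused across paired runs.
#'
#' @param ctrl an `anfis_controller`.
#' @return the controller, invisibly.
#' @export
reset_controller <- function(ctrl) {
  ctrl$obs <- hab_state()
  ctrl$phase <- 0
  ctrl$burst_start <- -Inf
  ctrl$burst_until <- -Inf
  ctrl$next_allowed <- -Inf
  ctrl$burst <- NULL
  ctrl$gamma <- 1
  ctrl$pending <- NULL
  ctrl$S_last <- 0
  invisible(ctrl)
}

#' Save a controller checkpoint
#'
#' Serializes the rule base (via the model serialization), the observer
#' state and the scheduler parameters to one JSON document.
#'
#' @param ctrl an `anfis_controller`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
controller_save <- function(ctrl, path) {
  # sync rule consequents from the runtime matrices before serializing
  model <- ctrl$model
  for (i in seq_along(model$rules))
    for (o in 1:3) model$rules[[i]]$consequent[o, ] <- model$Cons[[o]][i, ]
  tmp <- tempfile(fileext = ".json")
  anfis_save(model, tmp)
  doc <- list(model = jsonlite::read_json(tmp),
              observer = list(H_s = ctrl$obs$H_s, H_l = ctrl$obs$H_l,
                              t = ctrl$obs$t),
              chirp = unclass(ctrl$cfg$chirp),
              ibi = unclass(ctrl$cfg$ibi))
  unlink(tmp)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}
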