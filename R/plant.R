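#' Nominal specimen profile
#'
#' A virtual specimen is a thresholded, saturating, habituation-attenuated
#' turning responder with Wiener-cascade dynamics (first-order low-pass of
#' the supra-threshold drive followed by a static tanh-shaped saturation),
#' plus natural exploratory locomotion (Ornstein-Uhlenbeck heading jitter
#' and speed fluctuation).  Stimulation frequency scales the drive through
#' a responsiveness band: full response in 20-80 Hz, ramping down towards
#' the 10 and 200 Hz limits, zero outside.
#'
#' @param threshold response threshold (V).
#' @param gain small-signal turn gain (deg/s per V above threshold).
#' @param tau_c cascade low-pass time constant (s).
#' @param sat_drive saturation scale of the static nonlinearity (V); the
#'   commanded turn rate is `gain * sat_drive * tanh(z / sat_drive)`.
#' @param hab a [hab_params()] object (the plant's ground-truth dynamics).
#' @param speed_mean,speed_sd,speed_tau natural-walk speed process
#'   (normalized units, s).
#' @param turn_sigma,turn_tau natural-walk heading jitter (deg/s, s).
#' @param v_max,ang_max normalization scales: cm/s per unit `v_lin`,
#'   deg/s per unit `v_ang`.
#' @param amp_max safe amplitude ceiling (V), also the drive normalizer for
#'   the habituation stimulus input.
#' @param walk_noise logical; disable for deterministic analytic checks.
#' @return an object of class `specimen_profile`.
#' @export
specimen_profile <- function(threshold = 1.0, gain = 60, tau_c = 0.4,
                             sat_drive = 2.0, hab = hab_params(),
                             speed_mean = 0.50, speed_sd = 0.10,
                             speed_tau = 2.0, turn_sigma = 6,
                             turn_tau = 1.0, v_max = 10, ang_max = 180,
                             amp_max = 3.0, walk_noise = TRUE) {
  stopifnot(threshold > 0, gain > 0, tau_c > 0, sat_drive > 0)
  structure(list(threshold = threshold, gain = gain, tau_c = tau_c,
                 sat_drive = sat_drive, hab = hab,
                 speed_mean = speed_mean, speed_sd = speed_sd,
                 speed_tau = speed_tau, turn_sigma = turn_sigma,
                 turn_tau = turn_tau, v_max = v_max, ang_max = ang_max,
                 amp_max = amp_max, walk_noise = walk_noise),
            class = "specimen_profile")
}

#' Sample a specimen from the population
#'
#' Threshold and gain are drawn log-normally around the nominal values with
#' coefficient of variation `variability` (default 0.45, the configured
#' inter-individual spread of response thresholds), mean preserved.
#'
#' @param nominal a [specimen_profile()].
#' @param variability coefficient of variation (>= 0).
#' @param seed optional integer; when given, the draw is made reproducible
#'   by seeding the R RNG.
#' @return a [specimen_profile()].
#' @export
sample_specimen <- function(nominal, variability = 0.45, seed = NULL) {
  stopifnot(variability >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (variability == 0) return(nominal)
  s <- sqrt(log(1 + variability^2))
  draw <- function(nom) stats::rlnorm(1, meanlog = log(nom) - s^2 / 2, sdlog = s)
  nominal$threshold <- draw(nominal$threshold)
  nominal$gain <- draw(nominal$gain)
  nominal
}

# frequency-responsiveness factor: trapezoid over the 10-200 Hz band with a
# flat optimum at 20-80 Hz
freq_gain <- function(f) {
  g <- numeric(length(f))
  inb <- f >= 10 & f <= 200
  g[f >= 20 & f <= 80] <- 1
  lo <- inb & f < 20
  g[lo] <- 0.3 + 0.7 * (f[lo] - 10) / 10
  hi <- inb & f > 80
  g[hi] <- 1 - 0.7 * (f[hi] - 80) / 120
  g
}

#' Rectangular arena with obstacles
#'
#' @param width,height extent in cm (origin at the lower-left corner).
#' @param obstacles list of `list(type = "rect", xmin, xmax, ymin, ymax)`
#'   or `list(type = "circle", cx, cy, r)`.
#' @param target target point `c(x, y)` in cm.
#' @param completion_radius cm.
#' @return an object of class `arena`.
#' @export
arena <- function(width = 200, height = 200, obstacles = list(),
                  target = c(width * 0.8, height * 0.8),
                  completion_radius = 8) {
  a <- structure(list(width = width, height = height, obstacles = obstacles,
                      target = target, completion_radius = completion_radius,
                      diag = sqrt(width^2 + height^2)),
                 class = "arena")
  if (target[1] < 0 || target[1] > width || target[2] < 0 || target[2] > height)
    stop("target outside arena bounds")
  if (point_in_obstacle(target[1], target[2], a))
    stop("target inside an obstacle")
  a
}

point_in_obstacle <- function(x, y, arena) {
  for (ob in arena$obstacles) {
    if (ob$type == "rect" &&
        x >= ob$xmin && x <= ob$xmax && y >= ob$ymin && y <= ob$ymax)
      return(TRUE)
    if (ob$type == "circle" && (x - ob$cx)^2 + (y - ob$cy)^2 <= ob$r^2)
      return(TRUE)
  }
  FALSE
}

#' Ray-cast distance to the nearest wall or obstacle
#'
#' @param x,y origin (cm), inside the arena.
#' @param heading_deg ray direction (deg, CCW from +x).
#' @param arena an [arena()].
#' @param max_range cm (default 400, a 4 m time-of-flight-style range).
#' @return distance in cm, capped at `max_range`.
#' @export
raycast <- function(x, y, heading_deg, arena, max_range = 400) {
  if (x < 0 || x > arena$width || y < 0 || y > arena$height)
    stop("raycast origin outside arena bounds")
  th <- heading_deg * pi / 180
  dx <- cos(th); dy <- sin(th)
  ts <- c()
  if (dx > 1e-12) ts <- c(ts, (arena$width - x) / dx)
  if (dx < -1e-12) ts <- c(ts, (0 - x) / dx)
  if (dy > 1e-12) ts <- c(ts, (arena$height - y) / dy)
  if (dy < -1e-12) ts <- c(ts, (0 - y) / dy)
  best <- min(c(ts[ts >= 0], Inf))
  for (ob in arena$obstacles) {
    if (ob$type == "rect") {
      # slab intersection
      tx <- if (abs(dx) > 1e-12) sort(c((ob$xmin - x) / dx, (ob$xmax - x) / dx))
            else if (x >= ob$xmin && x <= ob$xmax) c(-Inf, Inf) else c(Inf, -Inf)
      ty <- if (abs(dy) > 1e-12) sort(c((ob$ymin - y) / dy, (ob$ymax - y) / dy))
            else if (y >= ob$ymin && y <= ob$ymax) c(-Inf, Inf) else c(Inf, -Inf)
      t0 <- max(tx[1], ty[1]); t1 <- min(tx[2], ty[2])
      if (t0 <= t1 && t1 >= 0) best <- min(best, max(t0, 0))
    } else if (ob$type == "circle") {
      ox <- x - ob$cx; oy <- y - ob$cy
      b <- ox * dx + oy * dy
      disc <- b^2 - (ox^2 + oy^2 - ob$r^2)
      if (disc >= 0) {
        t0 <- -b - sqrt(disc)
        if (t0 >= 0) best <- min(best, t0)
        else if (-b + sqrt(disc) >= 0) best <- min(best, 0)
      }
    }
  }
  min(best, max_range)
}

#' Initial plant state
#'
#' @param x,y position (cm); heading (deg, CCW from +x, in `(-180, 180]`).
#' @param v_lin,v_ang normalized velocities.
#' @param hab initial [hab_state()].
#' @return an object of class `plant_state`.
#' @export
plant_state <- function(x = 20, y = 20, heading = 45, v_lin = 0.4,
                        v_ang = 0, hab = hab_state()) {
  structure(list(x = x, y = y, heading = wrap_angle(heading),
                 v_lin = v_lin, v_ang = v_ang, hab = hab,
                 cascade = 0, prev_v_ang = v_ang),
            class = "plant_state")
}

#' Advance the plant one step
#'
#' The stimulation pathway is a Wiener cascade: the supra-threshold drive
#' `u = freq_gain(f) * max(0, amplitude - threshold)` is low-pass filtered
#' (time constant `tau_c`), passed through the static saturation
#' `sat_drive * tanh(z / sat_drive)`, scaled by `gain`, signed by the
#' stimulated side, and attenuated by the current habituation level through
#' the factor `(1 - H)`.  Natural-walk jitter is added to both velocity
#' channels, the habituation state advances with drive
#' `S = amplitude / amp_max`, and the kinematics are integrated with the
#' heading wrapped to `(-180, 180]`.
#'
#' @param state a [plant_state()].
#' @param stim `NULL` (no active stimulus) or a list with `amplitude` (V),
#'   `frequency` (Hz) and `side` (`"left"`/`"right"`).
#' @param profile a [specimen_profile()].
#' @param dt control step (s).
#' @param arena_obj optional [arena()]; when given, the position is kept
#'   inside the bounds.
#' @return updated [plant_state()].
#' @export
plant_step <- function(state, stim, profile, dt, arena_obj = NULL) {
  active <- !is.null(stim) && stim$side != "none"
  u <- 0; side_sign <- 0; S <- 0
  if (active) {
    u <- freq_gain(stim$frequency) * max(0, stim$amplitude - profile$threshold)
    side_sign <- if (stim$side == "left") 1 else -1
    S <- clip(stim$amplitude / profile$amp_max, 0, 1)
  }
  state$cascade <- state$cascade + dt / profile$tau_c * (u - state$cascade)
  H <- combined_level(state$hab)
  turn_cmd <- profile$gain * profile$sat_drive *
    tanh(state$cascade / profile$sat_drive) * (1 - H) * side_sign
  # natural walk: OU jitter on turn rate and speed
  nat_turn <- state$v_ang * profile$ang_max - turn_cmd_prev(state)
  if (profile$walk_noise) {
    nat_turn <- nat_turn + dt * (-nat_turn / profile$turn_tau) +
      profile$turn_sigma * sqrt(2 * dt / profile$turn_tau) * stats::rnorm(1)
    dv <- dt * (profile$speed_mean - state$v_lin) / profile$speed_tau +
      profile$speed_sd * sqrt(2 * dt / profile$speed_tau) * stats::rnorm(1)
    state$v_lin <- clip(state$v_lin + dv, 0, 1)
  } else {
    nat_turn <- 0
  }
  total_turn <- turn_cmd + nat_turn            # deg/s
  state$prev_v_ang <- state$v_ang
  state$v_ang <- clip(total_turn / profile$ang_max, -1, 1)
  attr(state, "turn_cmd") <- turn_cmd
  # habituation ground truth, integrated at the plant step (the habituation
  # dt field is overridden so the two clocks cannot drift apart)
  hp <- profile$hab
  hp$dt <- dt
  state$hab <- hab_step(state$hab, S = S, v = state$v_lin, params = hp)
  # kinematics
  state$heading <- wrap_angle(state$heading + total_turn * dt)
  sp <- state$v_lin * profile$v_max
  state$x <- state$x + sp * cos(state$heading * pi / 180) * dt
  state$y <- state$y + sp * sin(state$heading * pi / 180) * dt
  if (!is.null(arena_obj)) {
    state$x <- clip(state$x, 0.5, arena_obj$width - 0.5)
    state$y <- clip(state$y, 0.5, arena_obj$height - 0.5)
  }
  state
}

# the previous step's commanded turn is not stored separately; natural
# jitter is modeled as an OU process around zero, so its previous value is
# the previous total turn minus the previous command.  For simplicity the
# jitter memory is kept implicitly through v_ang; when noise is off the
# jitter is exactly zero.
turn_cmd_prev <- function(state) attr(state, "turn_cmd") %||% 0

#' Sense the 8-channel controller input
#'
#' @param state a [plant_state()].
#' @param arena_obj an [arena()].
#' @param hab_lvl estimated habituation level supplied by the controller's
#'   observer (the plant's latent truth is not exposed).
#' @param max_range proximity sensor range (cm).
#' @param dt control step, used for the angular-acceleration finite
#'   difference.
#' @return named numeric vector: `Prox_F`, `Prox_B` in `[0,1]` (1 = touching),
#'   `Vel_Lin` `[0,1]`, `Vel_Ang` `[-1,1]`, `Dist_Targ` `[0,1]` (arena-diagonal
#'   normalized), `Err_Bear` in degrees `(-180, 180]` (positive = target to
#'   the left), `Accel_Ang` `[-1,1]`, `Hab_Lvl` `[0,1]`.
#' @export
sense <- function(state, arena_obj, hab_lvl = 0, max_range = 400, dt = 0.1) {
  d_f <- raycast(state$x, state$y, state$heading, arena_obj, max_range)
  d_b <- raycast(state$x, state$y, wrap_angle(state$heading + 180),
                 arena_obj, max_range)
  tx <- arena_obj$target[1]; ty <- arena_obj$target[2]
  dist <- sqrt((tx - state$x)^2 + (ty - state$y)^2)
  bearing <- atan2(ty - state$y, tx - state$x) * 180 / pi
  err <- if (dist < 1e-9) 0 else wrap_angle(bearing - state$heading)
  accel <- clip((state$v_ang - state$prev_v_ang) / max(dt, 1e-9), -1, 1)
  c(Prox_F = clip(1 - d_f / max_range, 0, 1),
    Prox_B = clip(1 - d_b / max_range, 0, 1),
    Vel_Lin = clip(state$v_lin, 0, 1),
    Vel_Ang = clip(state$v_ang, -1, 1),
    Dist_Targ = clip(dist / arena_obj$diag, 0, 1),
    Err_Bear = err,
    Accel_Ang = accel,
    Hab_Lvl = clip(hab_lvl, 0, 1))
}
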