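# assembled adaptive controller: structure, gating, rule management,
# observer

world <- test_world()

test_that("controller structure follows the configured partitions", {
  specs <- anfishab:::controller_input_specs()
  counts <- vapply(specs, function(s) length(s$mfs), integer(1))
  expect_identical(sum(counts), 32L)
  expect_identical(counts, c(4L, 4L, 4L, 5L, 4L, 5L, 3L, 3L))
  # first proximity set: center 0.15, width 0.10
  pf_far <- specs[[1]]$mfs[[1]]
  expect_equal(pf_far$c, 0.15)
  expect_equal(pf_far$sigma1, 0.10)
  expect_equal(pf_far$sigma2, 0.10)
  names8 <- vapply(specs, `[[`, "", "name")
  expect_identical(names8, c("Prox_F", "Prox_B", "Vel_Lin", "Vel_Ang",
                             "Dist_Targ", "Err_Bear", "Accel_Ang", "Hab_Lvl"))
})

test_that("initial rule count lands inside the configured bounds", {
  ctrl <- trained_template(world)
  expect_gte(n_rules(ctrl), 80L)
  expect_lte(n_rules(ctrl), 150L)
})

test_that("config validation lists offending fields", {
  expect_error(controller_config(eps_fire = 0), "eps_fire")
  expect_error(controller_config(rule_bounds = c(0, 50)), "min_rules")
  expect_error(controller_config(freq_range = c(5, 200)), "safe band")
  expect_error(controller_config(rule_target = 200), "rule_target")
})

fixture_sensors <- function(err = 90, prox_f = 0.05, hab = 0) {
  c(Prox_F = prox_f, Prox_B = 0.05, Vel_Lin = 0.5, Vel_Ang = 0,
    Dist_Targ = 0.5, Err_Bear = err, Accel_Ang = 0, Hab_Lvl = hab)
}

test_that("deviation deadband and refractory window gate out commands", {
  ctrl <- clone_controller(trained_template(world))
  reset_controller(ctrl)
  out <- control_step(ctrl, fixture_sensors(err = 2), 0)
  expect_null(out$command)
  # a left-of-target fixture state produces a left command in safe ranges
  out2 <- control_step(ctrl, fixture_sensors(err = 90), 0.1)
  expect_false(is.null(out2$command))
  cmd <- out2$command
  expect_identical(cmd$side, "left")
  expect_gte(cmd$amplitude, 0); expect_lte(cmd$amplitude, 3)
  expect_gte(cmd$frequency, 10); expect_lte(cmd$frequency, 200)
  expect_gte(cmd$duration, 50); expect_lte(cmd$duration, 500)
  # refractory: immediately after the burst no new command is issued
  t_next <- 0.1 + cmd$duration / 1000 + cmd$ibi / 2
  out3 <- control_step(ctrl, fixture_sensors(err = 90), t_next)
  expect_null(out3$command)
  # right-of-target state commands the right side
  ctrl2 <- clone_controller(trained_template(world))
  reset_controller(ctrl2)
  out4 <- control_step(ctrl2, fixture_sensors(err = -90), 0)
  expect_identical(out4$command$side, "right")
})

test_that("commands stay inside safe ranges across a full noisy run", {
  ctrl <- clone_controller(trained_template(world))
  sp <- sample_specimen(world$profile, 0.45, seed = 7003)
  tel <- run_trial(ctrl, sp, world$arena, duration = 60, dt = 0.1, seed = 4,
                   retarget = TRUE, leg_budget = 20)
  s <- tel$steps[tel$steps$cmd_issued == 1, ]
  expect_gt(nrow(s), 0)
  expect_true(all(s$cmd_amp >= 0 & s$cmd_amp <= 3))
  expect_true(all(s$cmd_freq >= 10 & s$cmd_freq <= 200))
  expect_true(all(s$cmd_dur >= 50 & s$cmd_dur <= 500))
  expect_true(all(s$cmd_ibi >= world$ctrl_cfg$ibi$IBI_min &
                    s$cmd_ibi <= world$ctrl_cfg$ibi$IBI_max))
  expect_gte(n_rules(ctrl), world$ctrl_cfg$rule_bounds[1])
  expect_lte(n_rules(ctrl), world$ctrl_cfg$rule_bounds[2])
})

test_that("rule growth: no-op when covered, conservation at the cap, coverage after", {
  # a small rule base leaves genuine coverage gaps to exercise growth
  cfg_small <- world$ctrl_cfg
  cfg_small$rule_bounds <- c(5, 20)
  cfg_small$rule_target <- 20
  cfg_small$seed_batch <- 400
  small <- build_controller(cfg_small, seed = 3)
  expect_identical(n_rules(small), 20L)
  # force an uncovered region: give every rule the same corner antecedent,
  # so no rule can dominate anywhere (all fire identically)
  corner <- drop(anfishab:::argmax_antecedents(
    small$model$inputs, matrix(c(0, 0, 0, -1, 0, -1, -1, 0), 1)))
  for (k in seq_along(small$model$rules))
    small$model$rules[[k]]$antecedent <- corner
  small$model <- anfishab:::anfis_compile(small$model)
  x_mid <- c(0.4, 0.4, 0.6, 0, 0.6, 0, 0, 0.5)
  w0 <- firing_strengths(small$model, x_mid)
  expect_lt(max(w0 / sum(w0)), small$cfg$eps_fire)   # 1/20 each
  # growth restores coverage at the uncovered state
  grow_prune_rules(small, x_mid)
  w1 <- firing_strengths(small$model, x_mid)
  expect_gte(max(w1 / sum(w1)), small$cfg$eps_fire)
  # growth is a no-op once the state is covered
  n0 <- n_rules(small)
  grow_prune_rules(small, x_mid)
  expect_identical(n_rules(small), n0)
  # at the cap the count is conserved by pruning the lowest utility
  for (i in 1:30) {
    x <- anfishab:::sample_states(1, small$model$inputs)[1, ]
    grow_prune_rules(small, x)
    expect_lte(n_rules(small), 20L)
    expect_gte(n_rules(small), 5L)
  }
})

test_that("growth preserves the aggregate output at the growth point", {
  ctrl <- clone_controller(trained_template(world))
  x <- c(0.9, 0.9, 0.1, -0.9, 0.9, -0.9, 0.9, 0.9)
  y0 <- tryCatch(anfis_forward(ctrl$model, x)$y,
                 anfishab_no_active_rule = function(e) NULL)
  grow_prune_rules(ctrl, x)
  y1 <- anfis_forward(ctrl$model, x)$y
  if (!is.null(y0)) expect_equal(y1, y0, tolerance = 1e-6)
})

test_that("observer tracks the plant's latent habituation when matched", {
  # noise-free plant with the controller's own parameters: the observer
  # replays the delivered stimulus, so the two levels must stay close
  hp <- hab_params(sigma_s = 0, sigma_l = 0, dt = 0.1)  # uncompressed, noise-free
  sp <- world$profile
  sp$hab <- hp
  sp$walk_noise <- FALSE
  sp$threshold <- world$ctrl_cfg$resp_threshold
  sp$gain <- world$ctrl_cfg$resp_gain
  ctrl <- clone_controller(trained_template(world))
  ctrl$obs_par <- hp
  ar <- arena(200, 200, target = c(180, 20))   # force turning
  tel <- run_trial(ctrl, sp, ar, duration = 40, dt = 0.1, seed = 5,
                   retarget = FALSE, start = plant_state(heading = 135))
  s <- tel$steps
  expect_gt(max(s$H_s), 0.005)  # habituation actually moved
  err <- abs((s$H_s + s$H_l) - s$H_obs)
  expect_lt(max(err), 0.02)
  expect_true(all(s$H_obs >= 0 & s$H_obs <= 1))
})

test_that("all-silent rule base emits none and grows at the state", {
  cfg <- world$ctrl_cfg
  cfg$rule_bounds <- c(1, 10); cfg$rule_target <- 5; cfg$seed_batch <- 50
  ctrl <- build_controller(cfg, seed = 2)
  # shrink every width so nothing fires away from the centers
  for (i in seq_along(ctrl$model$inputs)) {
    for (j in seq_along(ctrl$model$inputs[[i]]$mfs)) {
      m <- ctrl$model$inputs[[i]]$mfs[[j]]
      m$sigma1 <- 1e-3; m$sigma2 <- 1e-3
      ctrl$model$inputs[[i]]$mfs[[j]] <- m
    }
  }
  ctrl$model <- anfishab:::anfis_compile(ctrl$model)
  n0 <- n_rules(ctrl)
  out <- control_step(ctrl, fixture_sensors(err = 137.3), 0)
  expect_null(out$command)
  expect_identical(ctrl$n_no_active, 1L)
  expect_gt(n_rules(ctrl), n0 - 1L)  # grew (or pruned-and-grew at cap)
})

test_that("checkpoint serialization writes a complete document", {
  ctrl <- clone_controller(trained_template(world))
  path <- tempfile(fileext = ".json")
  controller_save(ctrl, path)
  doc <- jsonlite::read_json(path)
  expect_named(doc, c("model", "observer", "chirp", "ibi"))
  expect_identical(length(doc$model$rules), n_rules(ctrl))
  unlink(path)
})
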