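# recursive least squares, damped Gauss-Newton premise refinement, and the
# dual-timescale schedule

test_that("scalar RLS update reproduces the hand-worked values", {
  st <- rls_init(1, lambda = 1, p0 = 1000)
  st2 <- rls_update(st, 1, 2)
  expect_equal(drop(st2$theta), 1000 / 1001 * 2, tolerance = 1e-12)
  expect_equal(drop(st2$P), 1000 / 1001, tolerance = 1e-12)
  # printed-precision values
  expect_equal(drop(st2$theta), 1.998002, tolerance = 1e-6)
  expect_equal(drop(st2$P), 0.999001, tolerance = 1e-6)
})

test_that("zero regressor carries no information", {
  st <- rls_init(3, lambda = 0.9, p0 = 10)
  st2 <- rls_update(st, c(0, 0, 0), 5)
  expect_equal(st2$theta, st$theta)
  expect_equal(st2$P, st$P / 0.9, tolerance = 1e-12)
})

test_that("RLS with lambda = 1 matches batch ordinary least squares", {
  set.seed(1)
  for (rep in 1:5) {
    n <- 50; d <- 4
    A <- matrix(rnorm(n * d), n)
    theta_true <- rnorm(d)
    y <- A %*% theta_true + 0.1 * rnorm(n)
    st <- rls_init(d, lambda = 1, p0 = 1e6)
    for (t in seq_len(n)) st <- rls_update(st, A[t, ], y[t])
    expect_equal(drop(st$theta), drop(oracle_ols(A, y)), tolerance = 1e-6)
  }
})

test_that("covariance stays bounded under forgetting with persistent excitation", {
  set.seed(2)
  st <- rls_init(3, lambda = 0.995, p0 = 1e3)
  tr <- numeric(100)
  for (t in 1:10000) {
    a <- rnorm(3)
    st <- rls_update(st, a, sum(a) + rnorm(1, sd = 0.1))
    if (t %% 100 == 0) tr[t / 100] <- sum(diag(st$P))
  }
  expect_true(all(is.finite(tr)))
  expect_lt(max(tr[50:100]), 100)  # no blow-up over the second half
  # P remains symmetric positive definite
  ev <- eigen(st$P, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
})

test_that("LMA lands exactly on a linear residual and rejects at zero residual", {
  # residual r(alpha) = alpha - 3, Jacobian 1: one Gauss-Newton step solves it
  st <- lma_step(function(a) a - 3, alpha = 10, damping = 1e-12)
  expect_equal(st$alpha, 3, tolerance = 1e-9)
  expect_true(st$accepted)
  # zero residual: nothing to do
  st0 <- lma_step(function(a) 0 * a, alpha = 2, damping = 1e-2)
  expect_equal(st0$alpha, 2)
  expect_false(st0$accepted)
  expect_equal(st0$rmse, 0)
})

test_that("LMA escalates damping and signals no-progress instead of failing", {
  # residual independent of alpha but nonzero: no step can improve
  st <- lma_step(function(a) c(1, 1), alpha = 0, damping = 1e-2)
  expect_true(st$no_progress)
  expect_equal(st$alpha, 0)
})

sin_toy <- function() {
  inputs <- list(input_spec("x", 0, pi, list(
    mf("asym_gaussian", c = 0.6, sigma1 = 0.7, sigma2 = 0.7),
    mf("asym_gaussian", c = 1.6, sigma1 = 0.7, sigma2 = 0.7),
    mf("asym_gaussian", c = 2.6, sigma1 = 0.7, sigma2 = 0.7))))
  rules <- lapply(1:3, function(k) anfis_rule(k, matrix(0, 1, 2)))
  anfis_model(inputs, rules, 1)
}

test_that("accepted premise steps never increase batch RMSE", {
  set.seed(3)
  model <- sin_toy()
  X <- matrix(seq(0, pi, length.out = 60))
  Y <- matrix(sin(X))
  model <- anfishab:::fit_consequents_rls(model, X, Y)
  opt <- premise_opt_init(model)
  rmse_prev <- sqrt(mean(anfishab:::batch_residuals(model, X, Y)^2))
  improved <- FALSE
  for (it in 1:20) {
    st <- premise_step(model, opt, X, Y, mode = "lma")
    if (st$accepted) {
      expect_lte(st$rmse, rmse_prev + 1e-12)
      rmse_prev <- st$rmse
      improved <- TRUE
    }
    model <- st$model; opt <- st$opt
    model <- anfishab:::fit_consequents_rls(model, X, Y)
    rmse_prev <- sqrt(mean(anfishab:::batch_residuals(model, X, Y)^2))
  }
  expect_true(improved)
  # 20 refinement iterations with RLS re-fits beat the initialization
  init <- anfishab:::fit_consequents_rls(sin_toy(), X, Y)
  rmse0 <- sqrt(mean(anfishab:::batch_residuals(init, X, Y)^2))
  expect_lt(rmse_prev, rmse0)
})

test_that("gradient-descent premise mode with momentum also reduces RMSE", {
  set.seed(4)
  model <- sin_toy()
  X <- matrix(seq(0, pi, length.out = 60))
  Y <- matrix(sin(X))
  model <- anfishab:::fit_consequents_rls(model, X, Y)
  opt <- premise_opt_init(model, lr = 0.01, momentum = 0.9)
  rmse0 <- sqrt(mean(anfishab:::batch_residuals(model, X, Y)^2))
  for (it in 1:10) {
    st <- premise_step(model, opt, X, Y, mode = "gd_momentum")
    model <- st$model; opt <- st$opt
  }
  rmse1 <- sqrt(mean(anfishab:::batch_residuals(model, X, Y)^2))
  expect_lt(rmse1, rmse0)
})

test_that("dual-timescale schedule: premise refinements count and RLS tracks", {
  set.seed(5)
  model <- sin_toy()
  X <- matrix(runif(500, 0, pi))
  Y <- matrix(0.5 + 0.2 * X)
  out <- dual_timescale_update(model, X, Y, lambda = 1, n_premise = 50,
                               window = 100)
  expect_identical(out$n_premise_steps, 10L)
  # a stationary affine target inside one rule's support is exactly
  # representable: the RLS residual collapses to the floor
  inputs2 <- list(
    input_spec("x1", -1, 1, lapply(c(-0.5, 0, 0.5), function(c)
      mf("asym_gaussian", c = c, sigma1 = 10, sigma2 = 10))),
    input_spec("x2", -1, 1, lapply(c(-0.5, 0, 0.5), function(c)
      mf("asym_gaussian", c = c, sigma1 = 10, sigma2 = 10))))
  m2 <- anfis_model(inputs2, list(anfis_rule(c(2, 2), matrix(0, 1, 3))), 1)
  X2 <- matrix(runif(1000, -1, 1), ncol = 2)
  Y2 <- matrix(3 + 2 * X2[, 1] - X2[, 2])
  out2 <- dual_timescale_update(m2, X2, Y2, lambda = 1, n_premise = Inf)
  expect_lt(mean(out2$history$sq_error[450:500], na.rm = TRUE), 1e-8)
})

test_that("forgetting tracks a drifting target better than lambda = 1", {
  # single always-on rule: pure recursive regression y = p0 + p1 x with a
  # sign flip at t = 250
  one_rule <- function() {
    inputs <- list(input_spec("x", -1, 1, list(
      mf("asym_gaussian", c = 0, sigma1 = 10, sigma2 = 10),
      mf("asym_gaussian", c = -0.5, sigma1 = 10, sigma2 = 10),
      mf("asym_gaussian", c = 0.5, sigma1 = 10, sigma2 = 10))))
    anfis_model(inputs, list(anfis_rule(1, matrix(0, 1, 2))), 1)
  }
  set.seed(6)
  X <- matrix(runif(500, -1, 1))
  Y <- matrix(ifelse(seq_len(500) <= 250, 2 * X, -2 * X))
  err_for <- function(lambda) {
    out <- dual_timescale_update(one_rule(), X, Y, lambda = lambda,
                                 n_premise = Inf)
    mean(out$history$sq_error[300:500], na.rm = TRUE)
  }
  expect_lt(err_for(0.995), err_for(1))
})

test_that("k-fold validation runs and reports both RMSEs", {
  set.seed(8)
  model <- sin_toy()
  X <- matrix(runif(100, 0, pi))
  Y <- matrix(sin(X) + 0.05 * rnorm(100))
  out <- kfold_validate(model, X, Y, k = 5, epochs = 3, patience = 2)
  expect_identical(nrow(out), 5L)
  expect_true(all(is.finite(out$train_rmse)))
  expect_true(all(is.finite(out$test_rmse)))
})
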