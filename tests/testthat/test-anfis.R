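# fuzzification, rule firing, normalization, forward pass

test_that("membership degrees match hand-evaluated forms", {
  m <- mf("asym_gaussian", c = 0.5, sigma1 = 0.1, sigma2 = 0.1)
  expect_identical(membership_degree(m, 0.5), 1)
  m2 <- mf("asym_gaussian", c = 0, sigma1 = 1, sigma2 = 2)
  expect_equal(membership_degree(m2, -1), exp(-0.5), tolerance = 1e-12)
  # right branch uses sigma2
  expect_equal(membership_degree(m2, 2), exp(-4 / 8), tolerance = 1e-12)
  g <- mf("gbell", c = 0, a = 1, b = 1)
  expect_equal(membership_degree(g, 1), 0.5, tolerance = 1e-12)
  expect_identical(membership_degree(g, 0), 1)
})

test_that("membership is bounded, continuous at the center, flushed on underflow", {
  set.seed(1)
  for (i in 1:20) {
    m <- mf("asym_gaussian", c = runif(1, -1, 1),
            sigma1 = runif(1, 0.05, 1), sigma2 = runif(1, 0.05, 1))
    x <- runif(50, -5, 5)
    mu <- membership_degree(m, x)
    expect_true(all(mu >= 0 & mu <= 1))
    eps <- 1e-10
    expect_equal(membership_degree(m, m$c - eps),
                 membership_degree(m, m$c + eps), tolerance = 1e-8)
  }
  tiny <- mf("asym_gaussian", c = 0, sigma1 = 0.01, sigma2 = 0.01)
  expect_identical(membership_degree(tiny, 5), 0)  # flushed, not denormal
})

test_that("invalid membership parameters are rejected", {
  expect_error(mf("asym_gaussian", c = 0, sigma1 = 0, sigma2 = 1), "sigma1")
  expect_error(mf("asym_gaussian", c = 0, sigma1 = 1, sigma2 = -1), "sigma2")
  expect_error(mf("gbell", c = 0, a = 0, b = 1), "'a'")
  expect_error(mf("gbell", c = 0, a = 1, b = 0), "'b'")
})

make_two_input <- function(cons = list(matrix(c(1, 2, 0), 1))) {
  inputs <- list(
    input_spec("x1", 0, 1, lapply(c(0.2, 0.5, 0.8), function(c)
      mf("asym_gaussian", c = c, sigma1 = 0.2, sigma2 = 0.2))),
    input_spec("x2", 0, 1, lapply(c(0.2, 0.5, 0.8), function(c)
      mf("asym_gaussian", c = c, sigma1 = 0.2, sigma2 = 0.2))))
  rules <- lapply(seq_along(cons), function(k)
    anfis_rule(c((k - 1) %% 3 + 1, (k - 1) %% 3 + 1), cons[[k]]))
  anfis_model(inputs, rules, n_outputs = nrow(cons[[1]]))
}

test_that("firing strengths are the product T-norm", {
  m <- make_two_input()
  # at an MF center of both inputs the matching rule fires with strength 1
  w <- firing_strengths(m, c(0.2, 0.2))
  expect_equal(w[1], 1, tolerance = 1e-12)
  # hand product: degrees 0.5 and 0.4 give w = 0.2
  mu1 <- membership_degree(m$inputs[[1]]$mfs[[1]], 0.4)
  mu2 <- membership_degree(m$inputs[[2]]$mfs[[1]], 0.6)
  expect_equal(firing_strengths(m, c(0.4, 0.6))[1], mu1 * mu2,
               tolerance = 1e-12)
  expect_error(firing_strengths(m, c(0.5)), "length")
})

test_that("normalization sums to one and flags the degenerate case", {
  expect_equal(normalize_strengths(c(2, 2)), c(0.5, 0.5))
  expect_equal(normalize_strengths(c(0, 3)), c(0, 1))
  expect_error(normalize_strengths(c(0, 0)),
               class = "anfishab_no_active_rule")
  expect_error(normalize_strengths(c(-1, 1)), "non-negative")
})

test_that("forward pass matches hand-worked Sugeno cases", {
  # single rule, wbar = 1, consequent (1, 2): y = 1 + 2*0.9 at x = 0.9... use x=3 clipped
  inputs <- list(input_spec("x1", 0, 5, lapply(c(1, 2.5, 4), function(c)
    mf("asym_gaussian", c = c, sigma1 = 1, sigma2 = 1))))
  m1 <- anfis_model(inputs, list(anfis_rule(2, matrix(c(1, 2), 1))), 1)
  expect_equal(anfis_forward(m1, 3)$y, 7, tolerance = 1e-12)
  # two equally firing rules with constant consequents 4 and 6 average to 5
  m2 <- make_two_input(cons = list(matrix(c(4, 0, 0), 1),
                                   matrix(c(6, 0, 0), 1)))
  m2$rules[[2]]$antecedent <- c(1L, 1L)  # same antecedent -> equal firing
  m2 <- anfishab:::anfis_compile(m2)
  expect_equal(anfis_forward(m2, c(0.3, 0.3))$y, 5, tolerance = 1e-12)
})

test_that("forward pass equals the brute-force oracle on random models", {
  set.seed(42)
  for (rep in 1:20) {
    m <- random_model(n_in = 2, n_mf = 2, n_out = 2)
    for (j in 1:5) {
      x <- runif(2)
      got <- anfis_forward(m, x)$y
      expect_equal(got, oracle_forward(m, x), tolerance = 1e-12)
    }
  }
})

test_that("output is linear in consequents and convex for constant consequents", {
  set.seed(7)
  m <- random_model(n_in = 2, n_mf = 2, n_out = 1)
  m2 <- m
  for (k in seq_along(m2$rules))
    m2$rules[[k]]$consequent <- matrix(rnorm(3), 1)
  m2 <- anfishab:::anfis_compile(m2)
  msum <- m
  for (k in seq_along(msum$rules)) {
    msum$rules[[k]]$consequent <- m$rules[[k]]$consequent +
      m2$rules[[k]]$consequent
  }
  msum <- anfishab:::anfis_compile(msum)
  for (j in 1:20) {
    x <- runif(2)
    expect_equal(anfis_forward(msum, x)$y,
                 anfis_forward(m, x)$y + anfis_forward(m2, x)$y,
                 tolerance = 1e-10)
  }
  # convexity with constant consequents
  mc <- m
  consts <- rnorm(length(mc$rules))
  for (k in seq_along(mc$rules))
    mc$rules[[k]]$consequent <- matrix(c(consts[k], 0, 0), 1)
  mc <- anfishab:::anfis_compile(mc)
  for (j in 1:20) {
    y <- anfis_forward(mc, runif(2))$y
    expect_gte(y, min(consts) - 1e-12)
    expect_lte(y, max(consts) + 1e-12)
  }
})

test_that("partition of unity holds whenever any rule fires", {
  set.seed(11)
  m <- random_model(n_in = 3, n_mf = 2, n_out = 1)
  for (j in 1:50) {
    tr <- anfis_forward(m, runif(3))$trace
    expect_equal(sum(tr$normalized), 1, tolerance = 1e-12)
  }
})

test_that("double-weighting compatibility flag reproduces the non-convex variant", {
  m <- make_two_input(cons = list(matrix(c(4, 0, 0), 1),
                                  matrix(c(6, 0, 0), 1)))
  m$rules[[2]]$antecedent <- c(1L, 1L)
  m <- anfishab:::anfis_compile(m)
  # equal firing: single weighting gives 5, double weighting 0.25*4+0.25*6 = 2.5
  expect_equal(anfis_forward(m, c(0.3, 0.3), compat_double_weight = TRUE)$y,
               2.5, tolerance = 1e-12)
})

test_that("regressor layout matches the stacked consequents exactly", {
  expect_equal(build_regressor(1, c(2, 3)), c(1, 2, 3))
  expect_equal(build_regressor(c(0.5, 0.5), 2), c(0.5, 1.0, 0.5, 1.0))
  set.seed(5)
  for (rep in 1:20) {
    m <- random_model(n_in = 2, n_mf = 2, n_out = 1)
    for (j in 1:5) {
      x <- runif(2)
      fw <- anfis_forward(m, x)
      a <- build_regressor(fw$trace$normalized, x)
      theta <- anfishab:::consequent_theta(m, 1)
      expect_equal(sum(a * theta), fw$y, tolerance = 1e-12)
    }
  }
})

test_that("model serialization round-trips losslessly", {
  set.seed(3)
  m <- random_model(n_in = 2, n_mf = 2, n_out = 3)
  path <- tempfile(fileext = ".json")
  anfis_save(m, path)
  m2 <- anfis_load(path)
  for (j in 1:20) {
    x <- runif(2)
    expect_identical(anfis_forward(m, x)$y, anfis_forward(m2, x)$y)
  }
  expect_identical(m$rules[[2]]$consequent, m2$rules[[2]]$consequent)
  unlink(path)
})

test_that("input_spec enforces MF count and center bounds", {
  mfs2 <- lapply(c(0.2, 0.8), function(c)
    mf("asym_gaussian", c = c, sigma1 = 0.2, sigma2 = 0.2))
  expect_error(input_spec("x", 0, 1, mfs2), "between 3 and 5")
  mfs_bad <- lapply(c(0.2, 0.5, 1.4), function(c)
    mf("asym_gaussian", c = c, sigma1 = 0.2, sigma2 = 0.2))
  expect_error(input_spec("x", 0, 1, mfs_bad), "outside")
})
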