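# Independent brute-force oracles and small model builders used across the
# suite.  The oracle code deliberately shares nothing with the package's
# vectorized forward pass: plain loops, scalar membership evaluation.

oracle_membership <- function(m, x) {
  if (m$kind == "gbell") return(1 / (1 + abs((x - m$c) / m$a)^(2 * m$b)))
  s <- if (x <= m$c) m$sigma1 else m$sigma2
  exp(-(x - m$c)^2 / (2 * s^2))
}

# straight-line weighted-average Sugeno evaluator
oracle_forward <- function(model, x) {
  x <- pmin(pmax(x, model$lo), model$hi)
  nr <- length(model$rules)
  w <- numeric(nr)
  f <- matrix(0, nr, model$n_outputs)
  for (k in seq_len(nr)) {
    r <- model$rules[[k]]
    wk <- 1
    for (i in seq_along(model$inputs)) {
      wk <- wk * oracle_membership(model$inputs[[i]]$mfs[[r$antecedent[i]]], x[i])
    }
    w[k] <- wk
    for (o in seq_len(model$n_outputs)) {
      f[k, o] <- r$consequent[o, 1] + sum(r$consequent[o, -1] * x)
    }
  }
  if (sum(w) == 0) return(NULL)
  wbar <- w / sum(w)
  drop(crossprod(f, wbar))
}

# random small model: full antecedent grid, random Gaussian partitions and
# consequents
random_model <- function(n_in = 2, n_mf = 2, n_out = 1) {
  inputs <- lapply(seq_len(n_in), function(i) {
    centers <- sort(stats::runif(max(n_mf, 3), 0, 1))[seq_len(max(n_mf, 3))]
    # input_spec requires >= 3 MFs; build 3 and use the first n_mf in rules
    input_spec(paste0("x", i), 0, 1, lapply(centers, function(c)
      mf("asym_gaussian", c = c, sigma1 = stats::runif(1, 0.15, 0.5),
         sigma2 = stats::runif(1, 0.15, 0.5))))
  })
  grid <- expand.grid(rep(list(seq_len(n_mf)), n_in))
  rules <- lapply(seq_len(nrow(grid)), function(k) {
    anfis_rule(as.integer(grid[k, ]),
               matrix(stats::rnorm(n_out * (n_in + 1)), n_out))
  })
  anfis_model(inputs, rules, n_outputs = n_out)
}

# batch least squares via the normal equations, for RLS cross-checks
oracle_ols <- function(A, y) solve(crossprod(A), crossprod(A, y))

# compact world used by closed-loop tests: 10x-compressed habituation and
# matching scheduler scaling via the config layer
test_world <- function(speedup = 10, seed_batch = 1500) {
  cfgl <- default_config()
  cfgl$habituation$speedup <- speedup
  cfgl$controller$seed_batch <- seed_batch
  config_objects(cfgl)
}

# one shared trained controller template (built lazily, reused across
# closed-loop tests to keep the suite inside its time budget)
trained_template <- local({
  cache <- NULL
  function(world) {
    if (is.null(cache)) {
      tpl <- build_controller(world$ctrl_cfg, seed = 11L)
      train_controller(tpl, seed = 12L)
      cache <<- tpl
    }
    cache
  }
})
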