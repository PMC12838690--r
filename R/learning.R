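#' Recursive least squares with forgetting
#'
#' State for estimating the stacked consequent parameters of all rules.
#' The three output channels share one regressor, so a single covariance
#' matrix serves all channels and `theta` is a `d x n_channels` matrix; the
#' per-channel updates are algebraically identical to running independent
#' RLS filters per channel.
#'
#' @param d regressor dimension (`n_rules * (n_inputs + 1)`).
#' @param n_channels number of output channels sharing the regressor.
#' @param lambda forgetting factor in `(0, 1]`; 0.995 geometrically
#'   down-weights old samples for drift tracking.
#' @param p0 initial covariance scale (`P0 = p0 * I`).
#' @return an object of class `rls_state`.
#' @export
rls_init <- function(d, n_channels = 1L, lambda = 0.995, p0 = 1e3) {
  stopifnot(d >= 1L, lambda > 0, lambda <= 1, p0 > 0)
  structure(list(theta = matrix(0, d, n_channels),
                 P = diag(p0, d), lambda = lambda),
            class = "rls_state")
}

#' One RLS update
#'
#' \deqn{K = P a / (\lambda + a^\top P a), \quad
#'       \theta' = \theta + K (y - a^\top \theta), \quad
#'       P' = (P - K a^\top P)/\lambda}
#' `P'` is re-symmetrized after the update to keep it positive definite
#' under rounding.
#'
#' @param state an [rls_init()] state.
#' @param a regressor vector.
#' @param y target(s), one per channel.
#' @return updated `rls_state`.
#' @export
rls_update <- function(state, a, y) {
  if (length(a) != nrow(state$theta)) stop("rls_update: regressor dimension mismatch")
  if (length(y) != ncol(state$theta)) stop("rls_update: target dimension mismatch")
  if (any(!is.finite(a)) || any(!is.finite(y))) stop("rls_update: non-finite input")
  Pa <- state$P %*% a
  denom <- state$lambda + sum(a * Pa)
  K <- Pa / denom
  err <- y - drop(crossprod(a, state$theta))
  state$theta <- state$theta + K %*% rbind(err)
  P <- (state$P - K %*% crossprod(a, state$P)) / state$lambda
  state$P <- (P + t(P)) / 2
  state
}

#' One damped Gauss-Newton (Levenberg-Marquardt) step on a residual function
#'
#' Solves \eqn{(J^\top J + \lambda_{lm}\,\mathrm{diag}(J^\top J))\,\Delta\alpha
#' = J^\top e} with \eqn{e = -r(\alpha)} and accepts the step only if the
#' residual norm decreases; damping is divided by 10 on acceptance and
#' multiplied by 10 on rejection.  Diagonal entries are floored at 1e-12 so
#' a parameter with (locally) no effect cannot make the system singular.
#'
#' @param residual_fn function `alpha -> residual vector` (driven to zero).
#' @param alpha current parameter vector.
#' @param damping current damping factor.
#' @param jac_fn optional Jacobian function; defaults to forward finite
#'   differences with relative step 1e-6.
#' @param lower optional elementwise lower bound, enforced by projection.
#' @return list `alpha`, `damping`, `accepted`, `rmse`, `no_progress`
#'   (`TRUE` once damping exceeds 1e12).
#' @export
lma_step <- function(residual_fn, alpha, damping = 1e-2, jac_fn = NULL,
                     lower = NULL) {
  r0 <- residual_fn(alpha)
  rmse0 <- sqrt(mean(r0^2))
  if (rmse0 == 0)
    return(list(alpha = alpha, damping = damping, accepted = FALSE,
                rmse = 0, no_progress = FALSE))
  J <- if (is.null(jac_fn)) fd_jacobian(residual_fn, alpha, r0) else jac_fn(alpha)
  JtJ <- crossprod(J)
  g <- -crossprod(J, r0)
  D <- pmax(diag(JtJ), 1e-12)
  while (damping <= 1e12) {
    M <- JtJ + damping * diag(D, nrow = length(alpha))
    delta <- tryCatch(drop(solve(M, g)), error = function(e) NULL)
    if (!is.null(delta)) {
      cand <- alpha + delta
      if (!is.null(lower)) cand <- pmax(cand, lower)
      r1 <- residual_fn(cand)
      rmse1 <- sqrt(mean(r1^2))
      if (is.finite(rmse1) && rmse1 < rmse0) {
        return(list(alpha = cand, damping = max(damping / 10, 1e-12),
                    accepted = TRUE, rmse = rmse1, no_progress = FALSE))
      }
    }
    damping <- damping * 10
  }
  list(alpha = alpha, damping = damping, accepted = FALSE, rmse = rmse0,
       no_progress = TRUE)
}

fd_jacobian <- function(residual_fn, alpha, r0 = NULL, rel_step = 1e-6) {
  if (is.null(r0)) r0 <- residual_fn(alpha)
  J <- matrix(0, length(r0), length(alpha))
  for (k in seq_along(alpha)) {
    h <- rel_step * max(1, abs(alpha[k]))
    ak <- alpha; ak[k] <- ak[k] + h
    J[, k] <- (residual_fn(ak) - r0) / h
  }
  J
}

# ---- premise (membership) parameter optimization --------------------------

# flatten all MF shape parameters of a model into one alpha vector, with a
# parallel lower-bound vector keeping widths strictly positive
premise_pack <- function(model) {
  alpha <- c(); lower <- c()
  for (s in model$inputs) for (m in s$mfs) {
    if (m$kind == "gbell") {
      alpha <- c(alpha, m$a, m$b, m$c); lower <- c(lower, 1e-6, 1e-6, -Inf)
    } else {
      alpha <- c(alpha, m$c, m$sigma1, m$sigma2)
      lower <- c(lower, -Inf, 1e-6, 1e-6)
    }
  }
  list(alpha = alpha, lower = lower)
}

premise_unpack <- function(model, alpha) {
  k <- 0L
  for (i in seq_along(model$inputs)) {
    for (j in seq_along(model$inputs[[i]]$mfs)) {
      m <- model$inputs[[i]]$mfs[[j]]
      if (m$kind == "gbell") {
        m$a <- max(alpha[k + 1L], 1e-6); m$b <- max(alpha[k + 2L], 1e-6)
        m$c <- alpha[k + 3L]
      } else {
        m$c <- alpha[k + 1L]
        m$sigma1 <- max(alpha[k + 2L], 1e-6)
        m$sigma2 <- max(alpha[k + 3L], 1e-6)
      }
      model$inputs[[i]]$mfs[[j]] <- m
      k <- k + 3L
    }
  }
  anfis_compile(model)
}

batch_residuals <- function(model, X, Y) {
  n <- nrow(X)
  R <- matrix(0, n, model$n_outputs)
  for (t in seq_len(n)) {
    y <- tryCatch(anfis_forward(model, X[t, ])$y,
                  anfishab_no_active_rule = function(e) rep(0, model$n_outputs))
    R[t, ] <- Y[t, ] - y
  }
  as.vector(R)
}

#' Premise-optimization state
#'
#' Holds the slow-timescale optimizer state: LMA damping, and the momentum
#' buffer / learning rate for the gradient-descent alternative (Table-style
#' defaults: learning rate 0.01, momentum 0.9).
#'
#' @param model an [anfis_model()] (used for sizing).
#' @param damping initial LMA damping.
#' @param lr,momentum gradient-descent hyper-parameters.
#' @return an object of class `premise_opt_state`.
#' @export
premise_opt_init <- function(model, damping = 1e-2, lr = 0.01, momentum = 0.9) {
  p <- premise_pack(model)
  structure(list(damping = damping, lr = lr, momentum = momentum,
                 buffer = numeric(length(p$alpha))),
            class = "premise_opt_state")
}

#' One slow-timescale premise refinement step
#'
#' Consequent parameters are held fixed; membership parameters are refined
#' against a batch either by damped Gauss-Newton (`mode = "lma"`, with
#' accept/reject guaranteeing non-increasing batch RMSE) or by gradient
#' descent with momentum (`mode = "gd_momentum"`).  Jacobian and gradients
#' use forward finite differences.
#'
#' @param model an [anfis_model()].
#' @param opt a [premise_opt_init()] state.
#' @param X,Y batch inputs (rows) and targets.
#' @param mode `"lma"` or `"gd_momentum"`.
#' @return list `model`, `opt`, `rmse`, `accepted`.
#' @export
premise_step <- function(model, opt, X, Y, mode = c("lma", "gd_momentum")) {
  mode <- match.arg(mode)
  X <- as.matrix(X); Y <- as.matrix(Y)
  p <- premise_pack(model)
  resfn <- function(alpha) batch_residuals(premise_unpack(model, alpha), X, Y)
  if (mode == "lma") {
    st <- lma_step(resfn, p$alpha, damping = opt$damping, lower = p$lower)
    opt$damping <- st$damping
    if (st$accepted) model <- premise_unpack(model, st$alpha)
    return(list(model = model, opt = opt, rmse = st$rmse,
                accepted = st$accepted))
  }
  # gd_momentum: gradient of mean squared residual by finite differences
  r0 <- resfn(p$alpha)
  f0 <- mean(r0^2)
  grad <- numeric(length(p$alpha))
  for (k in seq_along(p$alpha)) {
    h <- 1e-6 * max(1, abs(p$alpha[k]))
    ak <- p$alpha; ak[k] <- ak[k] + h
    grad[k] <- (mean(resfn(ak)^2) - f0) / h
  }
  opt$buffer <- opt$momentum * opt$buffer - opt$lr * grad
  alpha <- pmax(p$alpha + opt$buffer, p$lower)
  model <- premise_unpack(model, alpha)
  list(model = model, opt = opt, rmse = sqrt(mean(resfn(alpha)^2)),
       accepted = TRUE)
}

#' Dual-timescale update over a sample stream
#'
#' Per-sample RLS on the consequents (fast timescale) and a premise
#' refinement every `n_premise` samples on a sliding window of the last
#' `window` samples (slow timescale).  The per-sample order follows the
#' controller's computational sequence: forward pass, output, RLS update,
#' then (on schedule) premise refinement.
#'
#' @param model an [anfis_model()].
#' @param X,Y sample stream, one row per step.
#' @param lambda RLS forgetting factor.
#' @param n_premise premise refinement period in samples (`Inf` disables).
#' @param window sliding-window length for premise batches.
#' @param mode premise mode, `"lma"` or `"gd_momentum"`.
#' @param p0 initial RLS covariance scale.
#' @return list `model`, `rls`, `opt`, `history` (data.frame with per-step
#'   squared error and premise events), `n_premise_steps`.
#' @export
dual_timescale_update <- function(model, X, Y, lambda = 0.995,
                                  n_premise = 50L, window = 500L,
                                  mode = "lma", p0 = 1e3) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  d <- length(model$rules) * (length(model$inputs) + 1L)
  rls <- rls_init(d, n_channels = model$n_outputs, lambda = lambda, p0 = p0)
  # seed the filter from the model's current consequents
  for (o in seq_len(model$n_outputs)) rls$theta[, o] <- consequent_theta(model, o)
  opt <- premise_opt_init(model)
  err2 <- numeric(n)
  n_refine <- 0L
  for (t in seq_len(n)) {
    fw <- tryCatch(anfis_forward(model, X[t, ]),
                   anfishab_no_active_rule = function(e) NULL)
    if (is.null(fw)) { err2[t] <- NA_real_; next }
    err2[t] <- mean((Y[t, ] - fw$y)^2)
    a <- build_regressor(fw$trace$normalized, clip(X[t, ], model$lo, model$hi))
    rls <- rls_update(rls, a, Y[t, ])
    for (o in seq_len(model$n_outputs)) model <- set_consequent_theta(model, o, rls$theta[, o])
    if (is.finite(n_premise) && t %% n_premise == 0L) {
      idx <- max(1L, t - window + 1L):t
      ps <- premise_step(model, opt, X[idx, , drop = FALSE],
                         Y[idx, , drop = FALSE], mode = mode)
      model <- ps$model; opt <- ps$opt
      n_refine <- n_refine + 1L
    }
  }
  list(model = model, rls = rls, opt = opt,
       history = data.frame(step = seq_len(n), sq_error = err2),
       n_premise_steps = n_refine)
}

#' Offline hybrid training
#'
#' Epoch-based hybrid estimation: each epoch re-fits the consequents by a
#' full RLS sweep over the data (lambda = 1, so the sweep equals batch least
#' squares in the limit of large initial covariance) and then applies one
#' premise refinement step.  Stops early when the epoch RMSE plateaus.
#'
#' @param model an [anfis_model()].
#' @param X,Y training data.
#' @param epochs maximum epochs (default 250).
#' @param mode premise mode.
#' @param tol relative RMSE-improvement threshold for early stopping.
#' @param patience epochs without improvement tolerated before stopping.
#' @return list `model`, `history` (epoch, rmse, accepted, damping), `rmse`.
#' @export
train_anfis <- function(model, X, Y, epochs = 250L, mode = "lma",
                        tol = 1e-9, patience = 10L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  opt <- premise_opt_init(model)
  hist <- data.frame(epoch = integer(), rmse = numeric(),
                     accepted = logical(), damping = numeric())
  best <- Inf; stall <- 0L
  for (ep in seq_len(epochs)) {
    model <- fit_consequents_rls(model, X, Y, lambda = 1)
    r <- batch_residuals(model, X, Y)
    rmse_c <- sqrt(mean(r^2))
    ps <- premise_step(model, opt, X, Y, mode = mode)
    model <- ps$model; opt <- ps$opt
    rmse <- min(rmse_c, ps$rmse)
    hist <- rbind(hist, data.frame(epoch = ep, rmse = rmse,
                                   accepted = ps$accepted,
                                   damping = opt$damping))
    if (best - rmse > tol * max(1, best)) { best <- rmse; stall <- 0L }
    else stall <- stall + 1L
    if (stall >= patience) break
  }
  # final consequent re-fit after the last premise move
  model <- fit_consequents_rls(model, X, Y, lambda = 1)
  r <- batch_residuals(model, X, Y)
  list(model = model, history = hist, rmse = sqrt(mean(r^2)))
}

# one RLS sweep over a batch, writing the solution into the consequents
fit_consequents_rls <- function(model, X, Y, lambda = 1, p0 = 1e10) {
  d <- length(model$rules) * (length(model$inputs) + 1L)
  rls <- rls_init(d, n_channels = model$n_outputs, lambda = lambda, p0 = p0)
  for (t in seq_len(nrow(X))) {
    fw <- tryCatch(anfis_forward(model, X[t, ]),
                   anfishab_no_active_rule = function(e) NULL)
    if (is.null(fw)) next
    a <- build_regressor(fw$trace$normalized, clip(X[t, ], model$lo, model$hi))
    rls <- rls_update(rls, a, Y[t, ])
  }
  for (o in seq_len(model$n_outputs)) model <- set_consequent_theta(model, o, rls$theta[, o])
  model
}

#' k-fold validation of hybrid training on a dataset
#'
#' @param model template model (re-trained per fold from this start).
#' @param X,Y dataset.
#' @param k number of folds (default 5).
#' @param ... passed to [train_anfis()].
#' @return data.frame with per-fold train/test RMSE.
#' @export
kfold_validate <- function(model, X, Y, k = 5L, ...) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  fold <- rep_len(seq_len(k), n)
  out <- data.frame(fold = seq_len(k), train_rmse = NA_real_,
                    test_rmse = NA_real_)
  for (f in seq_len(k)) {
    tr <- fold != f
    fit <- train_anfis(model, X[tr, , drop = FALSE], Y[tr, , drop = FALSE], ...)
    r <- batch_residuals(fit$model, X[!tr, , drop = FALSE],
                         Y[!tr, , drop = FALSE])
    out$train_rmse[f] <- fit$rmse
    out$test_rmse[f] <- sqrt(mean(r^2))
  }
  out
}
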