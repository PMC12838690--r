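#' Input specification for a fuzzy input variable
#'
#' @param name identifier of the input.
#' @param lo,hi admissible range; values outside are clipped before
#'   fuzzification (angular inputs must be wrapped by the caller first).
#' @param mfs ordered list of [mf()] objects; between 3 and 5 per input,
#'   with every center inside `[lo, hi]`.
#' @return an object of class `input_spec`.
#' @export
input_spec <- function(name, lo, hi, mfs) {
  stopifnot(is.character(name), lo < hi, is.list(mfs))
  if (length(mfs) < 3L || length(mfs) > 5L)
    stop("input '", name, "': between 3 and 5 membership functions required")
  for (m in mfs) {
    stopifnot(inherits(m, "mf"))
    if (m$c < lo || m$c > hi)
      stop("input '", name, "': MF center ", m$c, " outside [", lo, ", ", hi, "]")
  }
  structure(list(name = name, lo = lo, hi = hi, mfs = mfs),
            class = "input_spec")
}

#' Fuzzy rule of a first-order Sugeno system
#'
#' @param antecedent integer vector, one MF index per input.
#' @param consequent numeric matrix `n_outputs x (n_inputs + 1)`; column 1
#'   is the constant term, the remaining columns multiply the inputs.
#' @return an object of class `anfis_rule`.
#' @export
anfis_rule <- function(antecedent, consequent) {
  stopifnot(is.numeric(antecedent), is.matrix(consequent))
  if (ncol(consequent) != length(antecedent) + 1L)
    stop("consequent must have n_inputs + 1 columns")
  structure(list(antecedent = as.integer(antecedent), consequent = consequent),
            class = "anfis_rule")
}

#' Assemble a first-order Sugeno ANFIS model
#'
#' The model is the static rule base: per-input fuzzy partitions and rules
#' with affine consequents.  The forward pass ([anfis_forward()]) is the
#' standard five-layer computation: fuzzification, product-T-norm rule
#' firing, normalization, affine consequent evaluation, and weighted-average
#' aggregation.
#'
#' @param inputs list of [input_spec()] objects.
#' @param rules list of [anfis_rule()] objects.
#' @param n_outputs number of output channels.
#' @return an object of class `anfis_model`.
#' @export
anfis_model <- function(inputs, rules, n_outputs = 1L) {
  stopifnot(length(inputs) >= 1L, length(rules) >= 1L, n_outputs >= 1L)
  n_in <- length(inputs)
  n_mf <- vapply(inputs, function(s) length(s$mfs), integer(1))
  for (r in rules) {
    if (length(r$antecedent) != n_in) stop("rule antecedent length mismatch")
    if (any(r$antecedent < 1L) || any(r$antecedent > n_mf))
      stop("rule antecedent index out of range for its input")
    if (nrow(r$consequent) != n_outputs)
      stop("rule consequent must have n_outputs rows")
  }
  m <- structure(list(inputs = inputs, rules = rules,
                      n_outputs = as.integer(n_outputs)),
                 class = "anfis_model")
  anfis_compile(m)
}

# Precompute flattened arrays used by the vectorized forward pass: the MF
# table, the rule->flat-MF index matrix A, and per-output consequent
# matrices (n_rules x (n_in+1)).  Called by every constructor/mutator.
anfis_compile <- function(model) {
  inputs <- model$inputs
  n_in <- length(inputs)
  n_mf <- vapply(inputs, function(s) length(s$mfs), integer(1))
  offset <- cumsum(c(0L, n_mf))[seq_len(n_in)]
  nr <- length(model$rules)
  A <- matrix(0L, nr, n_in)
  for (k in seq_len(nr)) A[k, ] <- model$rules[[k]]$antecedent + offset
  Cons <- vector("list", model$n_outputs)
  for (o in seq_len(model$n_outputs)) {
    Cons[[o]] <- t(vapply(model$rules, function(r) r$consequent[o, ],
                          numeric(n_in + 1L)))
    if (nr == 1L) Cons[[o]] <- matrix(Cons[[o]], nrow = 1L)
  }
  model$flat <- mf_flatten(inputs)
  model$A <- A
  model$Cons <- Cons
  model$lo <- vapply(inputs, `[[`, numeric(1), "lo")
  model$hi <- vapply(inputs, `[[`, numeric(1), "hi")
  model
}

#' Rule firing strengths (product T-norm)
#'
#' Layer-2 output: \eqn{w_k = \prod_i \mu_{A_{i,k}}(x_i)}.
#'
#' @param model an [anfis_model()].
#' @param x numeric input vector (one value per input; clipped to each
#'   input's admissible range).
#' @return vector of firing strengths, each in `[0, 1]`.
#' @export
firing_strengths <- function(model, x) {
  if (length(x) != length(model$inputs))
    stop("input vector length ", length(x), " != number of inputs ",
         length(model$inputs))
  if (any(!is.finite(x))) stop("firing_strengths: x must be finite")
  x <- clip(x, model$lo, model$hi)
  mu <- mf_eval_flat(model$flat, x)
  w <- mu[model$A[, 1L]]
  for (j in seq_len(ncol(model$A))[-1L]) w <- w * mu[model$A[, j]]
  w
}

#' Normalize firing strengths
#'
#' Layer-3 output: \eqn{\bar w_i = w_i / \sum_j w_j}.  Signals a
#' `anfishab_no_active_rule` condition when all strengths are zero; the
#' fallback policy is the caller's (see [control_step()]).
#'
#' @param w non-negative firing strengths.
#' @return normalized strengths summing to 1.
#' @export
normalize_strengths <- function(w) {
  if (any(w < 0)) stop("firing strengths must be non-negative")
  s <- sum(w)
  if (s == 0) stop_no_active_rule()
  w / s
}

#' ANFIS forward pass
#'
#' Computes the first-order Sugeno output
#' \deqn{y_o = \sum_i \bar w_i \,(p_{i0} + \sum_j p_{ij} x_j)}
#' per output channel, with a single normalization of the firing strengths
#' (standard weighted-average defuzzification).  `compat_double_weight`
#' applies the normalized weight twice (rule outputs pre-multiplied by
#' \eqn{\bar w_i} and aggregated with weights \eqn{\bar w_i} again); this
#' non-convex variant is provided for comparison only.
#'
#' @param model an [anfis_model()].
#' @param x numeric input vector.
#' @param compat_double_weight logical; see above.
#' @return list with `y` (length `n_outputs`) and `trace`
#'   (`memberships`, `firing`, `normalized`, `rule_outputs`, `y`).
#' @export
anfis_forward <- function(model, x, compat_double_weight = FALSE) {
  x <- clip(x, model$lo, model$hi)
  mu <- mf_eval_flat(model$flat, x)
  w <- mu[model$A[, 1L]]
  for (j in seq_len(ncol(model$A))[-1L]) w <- w * mu[model$A[, j]]
  s <- sum(w)
  if (s == 0) stop_no_active_rule()
  wbar <- w / s
  xa <- c(1, x)
  nr <- length(w)
  rule_out <- matrix(0, nr, model$n_outputs)
  y <- numeric(model$n_outputs)
  for (o in seq_len(model$n_outputs)) {
    f <- drop(model$Cons[[o]] %*% xa)
    if (compat_double_weight) f <- wbar * f
    rule_out[, o] <- f
    y[o] <- sum(wbar * f)
  }
  list(y = y,
       trace = list(memberships = mu, firing = w, normalized = wbar,
                    rule_outputs = rule_out, y = y))
}

#' Regressor vector for consequent least squares
#'
#' Lays out, rule by rule, \eqn{\bar w_i \cdot (1, x_1, \dots, x_n)} so that
#' the forward output of each channel equals `a %*% theta_channel` exactly,
#' with `theta_channel` the stacked consequent rows.
#'
#' @param wbar normalized firing strengths (must sum to 1).
#' @param x input vector.
#' @return numeric vector of length `n_rules * (n_inputs + 1)`.
#' @export
build_regressor <- function(wbar, x) {
  if (abs(sum(wbar) - 1) > 1e-8)
    stop("build_regressor: wbar must be normalized")
  as.vector(t(outer(wbar, c(1, x))))
}

# stacked consequent vector per output channel, matching build_regressor()
consequent_theta <- function(model, o) as.vector(t(model$Cons[[o]]))

# write a stacked theta vector back into the rule consequents
set_consequent_theta <- function(model, o, theta) {
  n_in <- length(model$inputs)
  M <- matrix(theta, ncol = n_in + 1L, byrow = TRUE)
  for (k in seq_along(model$rules)) model$rules[[k]]$consequent[o, ] <- M[k, ]
  anfis_compile(model)
}

#' Serialize / restore an ANFIS model
#'
#' Writes the full rule base (MF kinds and parameters, rule antecedents and
#' consequents) as structured JSON text.  The round trip is lossless to full
#' double precision.
#'
#' @param model an [anfis_model()].
#' @param path file path.
#' @return `anfis_save` returns `path` invisibly; `anfis_load` returns the
#'   restored model.
#' @export
anfis_save <- function(model, path) {
  doc <- list(
    n_outputs = model$n_outputs,
    inputs = lapply(model$inputs, function(s) {
      list(name = s$name, lo = s$lo, hi = s$hi,
           mfs = lapply(s$mfs, function(m) unclass(m)))
    }),
    rules = lapply(model$rules, function(r) {
      list(antecedent = r$antecedent, consequent = r$consequent)
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname anfis_save
#' @export
anfis_load <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  inputs <- lapply(doc$inputs, function(s) {
    mfs <- lapply(s$mfs, function(m) {
      if (m$kind == "gbell") mf("gbell", c = m$c, a = m$a, b = m$b)
      else mf("asym_gaussian", c = m$c, sigma1 = m$sigma1, sigma2 = m$sigma2)
    })
    input_spec(s$name, s$lo, s$hi, mfs)
  })
  rules <- lapply(doc$rules, function(r) {
    cons <- do.call(rbind, lapply(r$consequent, function(row) unlist(row)))
    anfis_rule(unlist(r$antecedent), cons)
  })
  anfis_model(inputs, rules, n_outputs = doc$n_outputs)
}

#' @export
print.anfis_model <- function(x, ...) {
  cat("ANFIS model: ", length(x$inputs), " inputs, ",
      length(x$rules), " rules, ", x$n_outputs, " outputs\n", sep = "")
  invisible(x)
}
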