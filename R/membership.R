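#' Membership functions
#'
#' Two membership-function families are supported: the generalized bell
#' \deqn{\mu(x) = \frac{1}{1 + |(x-c)/a|^{2b}}}
#' and a two-sided (asymmetric) Gaussian with independent left and right
#' widths,
#' \deqn{\mu(x) = \exp\{-(x-c)^2 / 2\sigma_1^2\} \; (x \le c), \qquad
#'       \mu(x) = \exp\{-(x-c)^2 / 2\sigma_2^2\} \; (x > c).}
#' Both attain 1 at the center and are continuous everywhere (the two
#' Gaussian branches agree at \eqn{x = c}).  With \eqn{\sigma_1 = \sigma_2}
#' the asymmetric form reduces to the classic Gaussian bell.
#'
#' @param kind `"gbell"` or `"asym_gaussian"`.
#' @param c center (input units).
#' @param a,b generalized-bell width and steepness (both `> 0`).
#' @param sigma1,sigma2 left/right standard deviations (both `> 0`).
#' @return an object of class `mf`.
#' @examples
#' m <- mf("asym_gaussian", c = 0, sigma1 = 1, sigma2 = 2)
#' membership_degree(m, -1)  # exp(-0.5)
#' @export
mf <- function(kind = c("asym_gaussian", "gbell"), c, a = NULL, b = NULL,
               sigma1 = NULL, sigma2 = NULL) {
  kind <- match.arg(kind)
  if (!is_scalar_num(c)) stop("mf center must be a finite scalar")
  if (kind == "gbell") {
    if (!is_scalar_num(a) || a <= 0) stop("gbell width 'a' must be > 0")
    if (!is_scalar_num(b) || b <= 0) stop("gbell steepness 'b' must be > 0")
    obj <- list(kind = kind, c = c, a = a, b = b)
  } else {
    if (is.null(sigma2)) sigma2 <- sigma1
    if (!is_scalar_num(sigma1) || sigma1 <= 0) stop("sigma1 must be > 0")
    if (!is_scalar_num(sigma2) || sigma2 <= 0) stop("sigma2 must be > 0")
    obj <- list(kind = kind, c = c, sigma1 = sigma1, sigma2 = sigma2)
  }
  structure(obj, class = "mf")
}

#' Evaluate a membership function
#'
#' @param m an [mf()] object.
#' @param x numeric vector of input values.
#' @return membership degrees in `[0, 1]`.  Degrees below `1e-300` are
#'   flushed to exact zero so that products over many inputs cannot
#'   underflow to denormals.
#' @export
membership_degree <- function(m, x) {
  stopifnot(inherits(m, "mf"))
  if (any(!is.finite(x))) stop("membership_degree: x must be finite")
  d <- x - m$c
  if (m$kind == "gbell") {
    mu <- 1 / (1 + abs(d / m$a)^(2 * m$b))
  } else {
    s <- ifelse(d <= 0, m$sigma1, m$sigma2)
    mu <- exp(-d^2 / (2 * s^2))
  }
  mu[mu < 1e-300] <- 0
  mu
}

# Flattened membership evaluation used on the hot control path: all MFs of a
# model are stored column-wise (kind code, center, p1, p2) and evaluated for
# one state vector in a single vectorized sweep.
mf_flatten <- function(inputs) {
  kind <- c(); cc <- c(); p1 <- c(); p2 <- c(); input_of <- c()
  for (i in seq_along(inputs)) {
    for (m in inputs[[i]]$mfs) {
      input_of <- c(input_of, i)
      if (m$kind == "gbell") {
        kind <- c(kind, 1L); cc <- c(cc, m$c); p1 <- c(p1, m$a); p2 <- c(p2, m$b)
      } else {
        kind <- c(kind, 0L); cc <- c(cc, m$c); p1 <- c(p1, m$sigma1); p2 <- c(p2, m$sigma2)
      }
    }
  }
  list(kind = kind, c = cc, p1 = p1, p2 = p2, input_of = input_of,
       n_mf = length(kind))
}

mf_eval_flat <- function(flat, x) {
  xv <- x[flat$input_of]
  d <- xv - flat$c
  mu <- numeric(flat$n_mf)
  g <- flat$kind == 1L
  if (any(g)) mu[g] <- 1 / (1 + abs(d[g] / flat$p1[g])^(2 * flat$p2[g]))
  if (any(!g)) {
    s <- ifelse(d[!g] <= 0, flat$p1[!g], flat$p2[!g])
    mu[!g] <- exp(-d[!g]^2 / (2 * s^2))
  }
  mu[mu < 1e-300] <- 0
  mu
}
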