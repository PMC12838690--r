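#' @keywords internal
"_PACKAGE"

#' Clip values to a closed interval
#'
#' @param x numeric vector.
#' @param lo,hi interval bounds.
#' @return `x` with out-of-range values replaced by the nearest bound.
#' @keywords internal
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Wrap an angle in degrees to (-180, 180]
#'
#' @param a angle(s) in degrees.
#' @return wrapped angle(s).
#' @export
wrap_angle <- function(a) {
  w <- (a + 180) %% 360 - 180
  # map the -180 representative onto +180 so the interval is half-open
  w[w == -180] <- 180
  w
}

# condition constructor for the degenerate all-rules-silent case; callers
# (the controller) decide the fallback policy
no_active_rule <- function(msg = "no rule fires at this input (sum of firing strengths is zero)") {
  structure(
    class = c("anfishab_no_active_rule", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
}

stop_no_active_rule <- function() stop(no_active_rule())

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
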