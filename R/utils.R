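#' @import methods
NULL

# classed conditions so callers can distinguish bad inputs from I/O failures
validationError <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("validationError", "canopyYieldError", "error")))
}

ioError <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("ioError", "canopyYieldError", "error")))
}

assertNumeric <- function(x, what, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    validationError("%s must be finite numeric", what)
  if (positive && any(x <= 0)) validationError("%s must be > 0", what)
  if (nonneg && any(x < 0)) validationError("%s must be >= 0", what)
  invisible(x)
}

# truncated normal via inverse-CDF so draw count per tree is fixed
rtruncnorm <- function(n, mean, sd, lower) {
  if (any(sd < 0)) validationError("sd must be >= 0")
  if (all(sd == 0)) return(pmax(rep_len(mean, n), lower))
  p0 <- stats::pnorm(lower, mean, sd)
  u <- stats::runif(n, p0, 1)
  pmin(pmax(stats::qnorm(u, mean, sd), lower), Inf)
}

# round half up, as image software does for 8-bit conversions
roundHalfUp <- function(x) floor(x + 0.5)
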