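# Small shared helpers.

#' Round half away from zero
#'
#' Base `round()` rounds half to even; printed clinical summary tables use
#' conventional half-up rounding, so rates and percentages go through this.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` places, ties away from zero.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Relative equality for machine-entered doses/rates. `tol` is relative to the
# larger magnitude; doses are strictly positive so no zero-denominator guard
# is needed beyond the floor.
rel_eq <- function(a, b, tol = 1e-6) {
  abs(a - b) <= tol * pmax(abs(a), abs(b), .Machine$double.eps)
}

# Minutes between two POSIXct timestamps (b - a).
mins_between <- function(a, b) {
  as.numeric(difftime(b, a, units = "mins"))
}

# Parse "YYYY-mm-dd HH:MM" (or POSIXct pass-through) as UTC at minute grain.
as_utc_minute <- function(x) {
  if (inherits(x, "POSIXct")) {
    out <- x
  } else {
    out <- as.POSIXct(x, tz = "UTC")
  }
  out <- as.POSIXct(floor(as.numeric(out) / 60) * 60, tz = "UTC",
                    origin = "1970-01-01")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
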