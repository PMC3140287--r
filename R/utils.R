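#' Round half away from zero
#'
#' Commercial rounding used at the reporting layer: halves round up
#' (2888.5 -> 2889), unlike [base::round()]'s round-half-even. Internal model
#' quantities are never rounded; this applies only when printing counts or
#' dollars.
#'
#' @param x numeric vector
#' @param digits integer, decimal places to keep
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Round to the nearest multiple of a unit
#'
#' Used for break-even points, which are reported to the nearest $1000.
#'
#' @param x numeric vector
#' @param unit positive number, the rounding granularity
#' @return rounded numeric vector
#' @export
round_to_unit <- function(x, unit = 1000) {
  stopifnot(unit > 0)
  round_half_up(x / unit) * unit
}

# internal: stop with a consistent message prefix
abort_tf <- function(...) stop(..., call. = FALSE)

# internal: scalar checks
is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x >= 0 && x == floor(x)
is_prob <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x >= 0 && x <= 1
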