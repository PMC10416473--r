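#' Round half-up
#'
#' Commercial-style rounding where ties go away from zero (`2.345` -> `2.35`
#' at 2 digits), as used in regulatory tables, rather than R's banker's
#' rounding. A small guard absorbs binary representation error so values that
#' are exactly representable halves round up.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(c(2.345, 2.344, -2.345), 2)
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  guard <- sqrt(.Machine$double.eps)
  sign(x) * trunc(abs(x) * scale + 0.5 + guard) / scale
}

#' Percentage of a count over a denominator
#'
#' Returns `100 * numerator / denominator` rounded half-up to `digits`
#' decimals. A zero denominator yields `NA` (an explicit undefined marker),
#' never a silent zero.
#'
#' @param numerator,denominator Non-negative counts (vectorised).
#' @param digits Decimal places (default 2).
#' @return Numeric vector of percentages.
#' @export
#' @examples
#' percent(6428, 6730)
percent <- function(numerator, denominator, digits = 2) {
  stopifnot(is.numeric(numerator), is.numeric(denominator))
  if (any(numerator < 0, na.rm = TRUE) || any(denominator < 0, na.rm = TRUE)) {
    stop("`numerator` and `denominator` must be non-negative", call. = FALSE)
  }
  out <- ifelse(denominator == 0, NA_real_,
                round_half_up(100 * numerator / denominator, digits))
  as.numeric(out)
}

# Internal: stop with a validation message.
abort_bad_arg <- function(msg) stop(msg, call. = FALSE)

# Internal: check a scalar fraction lies in [lo, hi).
check_fraction <- function(x, name, lo = 0, hi = 1, closed_hi = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && !is.na(x) &&
    x >= lo && (if (closed_hi) x <= hi else x < hi)
  if (!ok) {
    abort_bad_arg(sprintf("`%s` must be a single number in [%s, %s%s", name, lo,
                          hi, if (closed_hi) "]" else ")"))
  }
  invisible(x)
}
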