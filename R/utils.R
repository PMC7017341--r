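#' Round half away from zero
#'
#' Commercial rounding: ties go away from zero, so `round_half_away(1.45, 1)`
#' is 1.5 and `round_half_away(-1.45, 1)` is -1.5. Used when formatting
#' one-decimal summary tables, where base R's round-half-to-even would
#' disagree with the usual printed convention.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector of the same length as `x`.
#' @export
#' @examples
#' round_half_away(c(1.45, 2.5, -1.45), 1)
round_half_away <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Internal: assert a single finite numeric value
.check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stop(sprintf(
      "`%s` = %g is outside the valid range %s%g, %g%s", name, x,
      if (strict_lower) "(" else "[", lower, upper,
      if (strict_upper) ")" else "]"
    ), call. = FALSE)
  }
  invisible(x)
}
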