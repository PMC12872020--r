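#' Round half away from zero
#'
#' Commercial rounding used for all reported figures (planting budgets,
#' percent improvements, whole-CAD values); base `round()` rounds half to
#' even, which is not how the reported tables are rounded.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 0).
#' @return Rounded numeric vector.
#' @export
#' @examples
#' roundHalfAway(18.15, 1)  # 18.2
roundHalfAway <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# linear-interpolation percentile between order statistics (quantile type 7)
.percentile <- function(x, p) {
  unname(stats::quantile(x, probs = p / 100, type = 7, names = FALSE))
}

.assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf,
                                open_lower = FALSE, open_upper = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    (if (open_lower) x > lower else x >= lower) &&
    (if (open_upper) x < upper else x <= upper)
  if (!ok)
    stop(sprintf("'%s' must be a single finite number in %s%s, %s%s",
                 name, if (open_lower) "(" else "[", format(lower),
                 format(upper), if (open_upper) ")" else "]"), call. = FALSE)
  invisible(x)
}
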