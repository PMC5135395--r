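#' Moment-estimator skewness
#'
#' Third standardized moment, `mean(((x - mean(x)) / sd(x))^3)`, using the
#' sample standard deviation (denominator n - 1). Zero indicates a symmetric
#' distribution; a positive value a right tail.
#'
#' Degenerate samples (fewer than 3 finite values, or zero variance) return
#' 0 with attribute `degenerate = TRUE` rather than an error, so that
#' population summaries over many units never abort on a pathological unit.
#'
#' @param x numeric sample.
#' @param na.rm drop non-finite values first.
#' @return numeric scalar; attribute `degenerate` is `TRUE` when the sample
#'   could not support the estimator.
#' @examples
#' skewness(c(-1, 0, 1))      # 0
#' skewness(rexp(1e4))        # ~ 2
#' @export
skewness <- function(x, na.rm = TRUE) {
  if (na.rm) x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3) return(structure(0, degenerate = TRUE))
  s <- stats::sd(x)
  # treat variation at floating-point noise level as no variation
  if (!is.finite(s) || s <= 1e-12 * max(abs(mean(x)), 1))
    return(structure(0, degenerate = TRUE))
  structure(mean(((x - mean(x)) / s)^3), degenerate = FALSE)
}

#' @keywords internal
is_degenerate <- function(x) isTRUE(attr(x, "degenerate"))
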