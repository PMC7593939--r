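#' Moments of a correlation distribution
#'
#' Mean, standard deviation, skewness and excess kurtosis of a vector of
#' correlation coefficients. The default uses population (method-of-moments)
#' definitions: with central moments m2, m3, m4 about the mean,
#' skewness = m3 / m2^1.5 and kurtosis = m4 / m2^2 - 3 (excess, so a normal
#' distribution scores 0). The `"sample"` estimator applies the usual
#' bias corrections (n-1 SD, adjusted Fisher-Pearson skewness and kurtosis).
#'
#' Template expected moments ([template_moments()]) are derived with the
#' same population convention, so observed and expected values entering the
#' template distance are always commensurate.
#'
#' When the values are (numerically) constant the SD is 0 and skewness and
#' kurtosis are undefined; they are reported as 0 with `degenerate = TRUE`
#' so the template distance remains computable, and callers surface the
#' flag.
#'
#' @param x Numeric vector, length >= 2 (>= 3 for sample skewness, >= 4 for
#'   sample kurtosis).
#' @param estimator `"population"` (default) or `"sample"`.
#' @return List with `mean`, `sd`, `skewness`, `kurtosis`, `degenerate`.
#' @examples
#' corr_moments(c(-1, 0, 1))         # symmetric: skewness 0
#' corr_moments(c(0.5, 0.5, 0.5))    # constant: degenerate
#' @export
corr_moments <- function(x, estimator = c("population", "sample")) {
  estimator <- match.arg(estimator)
  n <- length(x)
  if (n < 2L) stop("at least two values are required")
  if (anyNA(x) || any(!is.finite(x))) stop("values must be finite")
  if (estimator == "sample" && n < 4L)
    stop("sample-corrected skewness/kurtosis need at least 4 values")
  m <- mean(x)
  d <- x - m
  m2 <- mean(d^2)
  if (m2 < 1e-28) {
    return(list(mean = m, sd = 0, skewness = 0, kurtosis = 0,
                degenerate = TRUE))
  }
  m3 <- mean(d^3)
  m4 <- mean(d^4)
  if (estimator == "population") {
    list(mean = m, sd = sqrt(m2),
         skewness = m3 / m2^1.5,
         kurtosis = m4 / m2^2 - 3,
         degenerate = FALSE)
  } else {
    g1 <- m3 / m2^1.5
    g2 <- m4 / m2^2 - 3
    list(mean = m,
         sd = sqrt(sum(d^2) / (n - 1)),
         skewness = g1 * sqrt(n * (n - 1)) / (n - 2),
         kurtosis = ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3)),
         degenerate = FALSE)
  }
}
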