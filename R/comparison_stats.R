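#' Within-subject coefficient of variation for repeated measures
#'
#' Test-retest reproducibility from paired replicate measurements of the
#' same kidneys. The default is the root-mean-square within-subject CV,
#' \deqn{CV\% = 100 \sqrt{\frac{1}{n}\sum_i \frac{d_i^2}{2 m_i^2}}}
#' with \eqn{d_i = x_i - y_i} and \eqn{m_i = (x_i + y_i)/2}; the pooled
#' alternative \eqn{100\,\sqrt{\sum d_i^2 / 2n} / \bar m} is available via
#' `method = "pooled"`. Both are zero for identical replicates and
#' invariant to rescaling all measurements.
#'
#' @param x,y paired replicate measurements (same kidneys, same order).
#' @param method `"rms"` (default) or `"pooled"`.
#' @return CV in percent.
#' @export
cv_repeated_measures <- function(x, y, method = c("rms", "pooled")) {
  method <- match.arg(method)
  if (length(x) != length(y) || length(x) < 1)
    stop("x and y must be paired and non-empty")
  d <- x - y
  m <- (x + y) / 2
  if (any(m <= 0)) stop("pair means must be positive")
  if (method == "rms") 100 * sqrt(mean(d^2 / (2 * m^2)))
  else 100 * sqrt(sum(d^2) / (2 * length(d))) / mean(m)
}

#' Bland-Altman agreement summary
#'
#' Mean and SD of paired differences with 95% limits of agreement
#' (mean +- 1.96 SD), plus the plot payload (pair means vs differences).
#'
#' @param x reference-method values.
#' @param y comparison-method values, paired with `x`.
#' @param percent if `TRUE`, differences are `100 * (y - x) / x`.
#' @return List with `mean_diff`, `sd_diff`, `lower`, `upper`, `means`,
#'   `diffs`, `percent`.
#' @export
bland_altman <- function(x, y, percent = FALSE) {
  if (length(x) != length(y) || length(x) < 2)
    stop("need at least two pairs")
  d <- if (percent) {
    if (any(x <= 0)) stop("percent differences need positive reference values")
    100 * (y - x) / x
  } else y - x
  md <- mean(d); sdd <- stats::sd(d)
  list(mean_diff = md, sd_diff = sdd,
       lower = md - 1.96 * sdd, upper = md + 1.96 * sdd,
       means = (x + y) / 2, diffs = d, percent = percent)
}

#' Root mean squared error against the reference method
#'
#' \eqn{RMSE = \sqrt{\frac1n \sum (y_i - x_i)^2}} in ml, or on percentage
#' errors \eqn{e_i = 100 (y_i - x_i)/x_i} when `percent = TRUE`.
#'
#' @param x reference-method values (planimetry, by convention).
#' @param y comparison-method values.
#' @param percent use percentage errors.
#' @return RMSE (ml or %).
#' @export
rmse <- function(x, y, percent = FALSE) {
  if (length(x) != length(y) || length(x) < 1) stop("x, y must be paired")
  e <- if (percent) {
    if (any(x <= 0)) stop("percent mode needs positive reference values")
    100 * (y - x) / x
  } else y - x
  sqrt(mean(e^2))
}

#' Pearson correlation with p-value
#'
#' Product-moment correlation with the two-sided p-value from the usual t
#' transform (via [stats::cor.test()]).
#'
#' @param x,y paired values, n >= 3, non-degenerate.
#' @return List with `r`, `p`, `n`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) stop("need >= 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in one of the series")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
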