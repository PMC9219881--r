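#' Compare two groups of measurements
#'
#' Two-sided comparison of two sample vectors with the Welch
#' unequal-variance t-test by default; Student's t-test and the
#' Mann-Whitney rank test are available through `method`.  Significance
#' stars follow the usual CEST-figure convention: `*` for p < 0.05 and
#' `**` for p < 0.001.  Two constant samples with equal means compare as
#' p = 1; two different constants as p = 0.
#'
#' @param a,b Numeric vectors with at least 2 finite values each.
#' @param method `"welch"`, `"student"` or `"mannwhitney"`.
#' @return A list with `statistic`, `p_value`, `stars` (`""`, `"*"` or
#'   `"**"`) and `method`.
#' @examples
#' compare_groups(rnorm(9), rnorm(9, 1))
#' @export
compare_groups <- function(a, b, method = c("welch", "student", "mannwhitney")) {
  method <- match.arg(method)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) stop("each group needs at least 2 values")
  if (!all(is.finite(a)) || !all(is.finite(b))) stop("group values must be finite")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    p <- if (mean(a) == mean(b)) 1 else 0
    stat <- if (p == 1) 0 else Inf
  } else if (method == "mannwhitney") {
    ht <- stats::wilcox.test(a, b, exact = FALSE)
    stat <- unname(ht$statistic); p <- ht$p.value
  } else {
    ht <- stats::t.test(a, b, var.equal = (method == "student"))
    stat <- unname(ht$statistic); p <- ht$p.value
  }
  stars <- if (p < 0.001) "**" else if (p < 0.05) "*" else ""
  list(statistic = stat, p_value = p, stars = stars, method = method)
}

#' Ordinary least-squares concentration regression
#'
#' Fits `y = intercept + slope * x` by ordinary least squares, as used to
#' relate AREX AUCs (percent per second times ppm) to cholesterol
#' concentration (mM).  `R^2 = 1 - SS_res / SS_tot`; a constant response
#' is reported with slope 0 and `R^2 = 0`.
#'
#' @param x Predictor values (e.g. concentration in mM); not all equal.
#' @param y Response values, same length as `x`.
#' @return An object of class `regression_fit` with fields `slope`,
#'   `intercept` and `r_squared`.
#' @examples
#' fit_regression(0:2, 2 * (0:2) + 1)
#' @export
fit_regression <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 2L) {
    stop("x and y must have equal length >= 2")
  }
  if (stats::sd(x) == 0) stop("degenerate predictor: all x values are equal")
  fit <- stats::lm(y ~ x)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("<regression_fit> slope %.4g, intercept %.4g, R^2 %.4f\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}
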