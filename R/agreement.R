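#' Pearson correlation with Fisher-transform confidence interval
#'
#' @param method_values,reference_values Paired numeric series, equal length
#'   of at least 3, no missing values.
#' @param alpha Two-sided type-1 error for the interval (default 0.05).
#' @return A list `r`, `ci_low`, `ci_high`.  The interval uses the inverse
#'   hyperbolic tangent transform with standard error `1/sqrt(n-3)` and a
#'   normal quantile; for `|r| = 1` the transform is unbounded and the
#'   interval is returned as `NA`.
#' @export
pearson_r_ci <- function(method_values, reference_values, alpha = 0.05) {
  check_pairs(method_values, reference_values)
  if (stats::sd(method_values) == 0 || stats::sd(reference_values) == 0)
    stop("degenerate series", call. = FALSE)
  n <- length(method_values)
  r <- stats::cor(method_values, reference_values)
  if (abs(r) >= 1 - 1e-15)
    return(list(r = r, ci_low = NA_real_, ci_high = NA_real_))
  z <- atanh(r)
  half <- stats::qnorm(1 - alpha / 2) / sqrt(n - 3)
  list(r = r, ci_low = tanh(z - half), ci_high = tanh(z + half))
}

#' Lin's concordance correlation coefficient with confidence interval
#'
#' `ccc = 2*s_xy / (s_x^2 + s_y^2 + (mean_x - mean_y)^2)` with population
#' (1/n) moments, following Lin's original definition.  The interval applies
#' the Fisher z-transform with Lin's large-sample variance.
#'
#' @inheritParams pearson_r_ci
#' @return A list `ccc`, `ci_low`, `ci_high`.
#' @export
lins_ccc_ci <- function(method_values, reference_values, alpha = 0.05) {
  check_pairs(method_values, reference_values)
  x <- method_values
  y <- reference_values
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2)
  sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  denom <- sx2 + sy2 + (mx - my)^2
  if (denom == 0) stop("degenerate", call. = FALSE)
  ccc <- 2 * sxy / denom
  if (sx2 == 0 || sy2 == 0 || abs(ccc) >= 1 - 1e-15)
    return(list(ccc = ccc, ci_low = NA_real_, ci_high = NA_real_))
  r <- sxy / sqrt(sx2 * sy2)
  u <- (mx - my) / (sx2 * sy2)^0.25
  var_z <- ((1 - r^2) * ccc^2 / ((1 - ccc^2) * r^2) +
              4 * ccc^3 * (1 - ccc) * u^2 / (r * (1 - ccc^2)^2) -
              2 * ccc^4 * u^4 / (r^2 * (1 - ccc^2)^2)) / (n - 2)
  # the large-sample variance degenerates for perfectly correlated series
  if (!is.finite(var_z) || var_z < 0)
    return(list(ccc = ccc, ci_low = NA_real_, ci_high = NA_real_))
  se_z <- sqrt(var_z)
  z <- atanh(ccc)
  half <- stats::qnorm(1 - alpha / 2) * se_z
  list(ccc = ccc, ci_low = tanh(z - half), ci_high = tanh(z + half))
}

#' Ordinary least-squares regression of a method on the reference
#'
#' Fits `method = intercept + slope * reference` and reports t-quantile
#' confidence intervals for both coefficients.  The orientation is fixed:
#' the candidate method is always the response, the reference the predictor.
#'
#' @inheritParams pearson_r_ci
#' @return A list `slope`, `intercept`, `slope_ci`, `intercept_ci`.
#' @export
simple_linear_regression <- function(method_values, reference_values,
                                     alpha = 0.05) {
  check_pairs(method_values, reference_values)
  if (stats::sd(reference_values) == 0)
    stop("degenerate predictor", call. = FALSE)
  fit <- stats::lm(method_values ~ reference_values)
  # an exactly linear relation is a legitimate input; the interval collapses
  ci <- suppressWarnings(stats::confint(fit, level = 1 - alpha))
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       slope_ci = unname(ci[2, ]),
       intercept_ci = unname(ci[1, ]))
}

#' Bland-Altman agreement analysis
#'
#' Differences are always `method - reference`.  Bias is the mean
#' difference, spread the sample (n-1) standard deviation, and the limits of
#' agreement `bias +/- multiplier * sd`.  The multiplier defaults to 2
#' (limits printed as "+/- 2 SD"); 1.96 is available through the argument.
#'
#' @inheritParams pearson_r_ci
#' @param loa_multiplier Width of the limits of agreement in SD units.
#' @return A list `bias`, `sd`, `loa_low`, `loa_high`, and `points`, a
#'   tibble of per-pair `(average, difference)` coordinates for plotting.
#' @export
bland_altman <- function(method_values, reference_values,
                         loa_multiplier = 2.0) {
  check_pairs(method_values, reference_values)
  d <- method_values - reference_values
  a <- (method_values + reference_values) / 2
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, sd = s,
       loa_low = bias - loa_multiplier * s,
       loa_high = bias + loa_multiplier * s,
       points = tibble::tibble(average = a, difference = d))
}

#' Proportional-bias regression from Bland-Altman coordinates
#'
#' Regresses the per-pair difference (method - reference) on the per-pair
#' average of the two measurements and reports the slope, intercept, and the
#' two-sided t-test p-value on the slope.  A negative slope means the method
#' increasingly overestimates relative to the reference as the measured
#' quantity falls -- equivalently, underestimates at high values.
#'
#' @inheritParams pearson_r_ci
#' @return A list `slope`, `intercept`, `p_value`.
#' @export
proportional_bias <- function(method_values, reference_values) {
  check_pairs(method_values, reference_values)
  d <- method_values - reference_values
  a <- (method_values + reference_values) / 2
  if (stats::sd(a) == 0) stop("degenerate averages", call. = FALSE)
  fit <- stats::lm(d ~ a)
  # zero-residual fits (e.g. identical series) are valid; p is then undefined
  sm <- suppressWarnings(summary(fit))$coefficients
  p <- if (nrow(sm) < 2 || is.nan(sm[2, 4])) NA_real_ else sm[2, 4]
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       p_value = p)
}

#' Paired t-test on two measurement series
#'
#' Classical paired t statistic with `df = n - 1` and a two-sided p-value.
#' Two degenerate cases are handled explicitly rather than producing a
#' division by zero: identical series give `t = 0, p = 1`, and a constant
#' non-zero difference is flagged (`constant-nonzero-difference`) with the
#' p-value reported at the machine floor.
#'
#' @inheritParams pearson_r_ci
#' @return A list `t`, `df`, `p`, `flag` (`NA` when no special case).
#' @export
paired_t_test <- function(method_values, reference_values) {
  check_pairs(method_values, reference_values, min_n = 2L)
  d <- method_values - reference_values
  n <- length(d)
  s <- stats::sd(d)
  m <- mean(d)
  if (s == 0) {
    if (m == 0) return(list(t = 0, df = n - 1, p = 1, flag = NA_character_))
    return(list(t = sign(m) * Inf, df = n - 1, p = .Machine$double.xmin,
                flag = "constant-nonzero-difference"))
  }
  t <- m / (s / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), df = n - 1),
       flag = NA_character_)
}

#' Sample size for detecting a correlation
#'
#' Number of participants needed to detect a correlation of at least `rho`
#' against a null of zero correlation, via the Fisher-transform formula
#' `ceil(((z_{1-alpha/2} + z_{power}) / atanh(rho))^2 + 3)`.
#'
#' @param rho Expected correlation, in (0, 1).
#' @param alpha Two-sided type-1 error rate.
#' @param power Desired power (1 - type-2 error rate).
#' @return Required number of participants (integer).
#' @examples
#' sample_size_for_correlation(0.90)  # 7
#' @export
sample_size_for_correlation <- function(rho, alpha = 0.05, power = 0.80) {
  if (!is.finite(rho) || rho <= 0 || rho >= 1)
    stop("rho must lie strictly in (0, 1)", call. = FALSE)
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  as.integer(ceiling((z / atanh(rho))^2 + 3))
}

check_pairs <- function(x, y, min_n = 3L) {
  if (length(x) != length(y))
    stop("paired series must have equal length", call. = FALSE)
  if (length(x) < min_n)
    stop("at least ", min_n, " pairs required", call. = FALSE)
  if (anyNA(x) || anyNA(y))
    stop("paired series must not contain missing values", call. = FALSE)
  invisible(NULL)
}
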