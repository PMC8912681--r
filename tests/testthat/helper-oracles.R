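# Independent direct-summation oracles for the agreement statistics, kept
# free of stats:: model-fitting so they check the implementation from a
# different route.

oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- 0; sy <- 0
  for (i in 1:n) { sx <- sx + x[i]; sy <- sy + y[i] }
  mx <- sx / n; my <- sy / n
  sxx <- 0; syy <- 0; sxy <- 0
  for (i in 1:n) {
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
  }
  sxy / sqrt(sxx * syy)
}

oracle_ccc <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sx2 <- 0; sy2 <- 0; sxy <- 0
  for (i in 1:n) {
    sx2 <- sx2 + (x[i] - mx)^2 / n
    sy2 <- sy2 + (y[i] - my)^2 / n
    sxy <- sxy + (x[i] - mx) * (y[i] - my) / n
  }
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

# OLS of response on predictor via the normal equations.
oracle_ols <- function(response, predictor) {
  n <- length(response)
  sx <- sum(predictor); sy <- sum(response)
  sxx <- sum(predictor^2); sxy <- sum(predictor * response)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  c(slope = slope, intercept = intercept)
}

oracle_ols_slope_p <- function(response, predictor) {
  n <- length(response)
  co <- oracle_ols(response, predictor)
  resid <- response - co["intercept"] - co["slope"] * predictor
  s2 <- sum(resid^2) / (n - 2)
  se <- sqrt(s2 / sum((predictor - mean(predictor))^2))
  t <- co["slope"] / se
  unname(2 * stats::pt(-abs(t), df = n - 2))
}

oracle_bland_altman <- function(method, reference, mult = 2) {
  d <- method - reference
  n <- length(d)
  bias <- sum(d) / n
  s <- sqrt(sum((d - bias)^2) / (n - 1))
  list(bias = bias, sd = s, loa_low = bias - mult * s,
       loa_high = bias + mult * s)
}

oracle_paired_t <- function(method, reference) {
  d <- method - reference
  n <- length(d)
  m <- sum(d) / n
  s <- sqrt(sum((d - m)^2) / (n - 1))
  t <- m / (s / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), df = n - 1))
}

# Step-by-step evaluation of the plateau dilution formula.
oracle_tbw_kg <- function(dose_g, ap_post, ap_pre, conc = 99.9) {
  step1 <- dose_g * (conc / 20)
  step2 <- step1 * 18.02
  step3 <- step2 / (ap_post - ap_pre)
  step4 <- step3 * 1e-3
  step4 / 1.04
}

# Brute-force enumeration of all reading pairs for the ADP selection rule.
oracle_select_volume <- function(v, thr = 0.150) {
  best <- NULL
  best_gap <- Inf
  for (i in seq_along(v)) for (j in seq_along(v)) if (i < j) {
    gap <- abs(v[i] - v[j])
    if (gap <= thr && gap < best_gap) {
      best_gap <- gap
      best <- mean(c(v[i], v[j]))
    }
  }
  best
}

# Tiny tidy-estimates fixture: one method column pair per participant.
make_estimates <- function(values_by_method, sex = NULL, age_group = NULL) {
  n <- length(values_by_method[[1]])
  if (is.null(sex)) sex <- rep("female", n)
  if (is.null(age_group)) age_group <- rep("children", n)
  rows <- lapply(names(values_by_method), function(m) {
    tibble::tibble(
      participant_id = sprintf("P%03d", seq_len(n)),
      sex = sex, age_years = ifelse(age_group == "children", 8, 14),
      age_group = age_group, weight_kg = 40,
      method = m, fm_kg = values_by_method[[m]],
      ffm_kg = 40 - values_by_method[[m]],
      pct_fat = values_by_method[[m]] / 40 * 100,
      hydration_pct = NA_real_, flags = NA_character_
    )
  })
  dplyr::bind_rows(rows)
}

# Scenario helpers used across the synthetic-data and acceptance tests.
zeroed_errors <- function(errors) {
  errors$constant_bias_kg <- 0
  errors$proportional_slope <- 0
  errors$residual_sd_kg <- 0
  errors
}

single_method_errors <- function(errors, method, bias = 0, slope = 0,
                                 sd = 0) {
  errors <- zeroed_errors(errors)
  i <- errors$method == method
  errors$constant_bias_kg[i] <- bias
  errors$proportional_slope[i] <- slope
  errors$residual_sd_kg[i] <- sd
  errors
}
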