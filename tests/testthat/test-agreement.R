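test_that("Pearson correlation handles exact and hand-computed cases", {
  x <- 1:10
  expect_equal(pearson_r_ci(2 * x + 1, x)$r, 1)
  expect_equal(pearson_r_ci(-x, x)$r, -1)
  expect_equal(pearson_r_ci(c(1, 2, 3), c(1, 3, 2))$r, 0.5)
  expect_error(pearson_r_ci(rep(1, 5), 1:5), "degenerate")
  expect_error(pearson_r_ci(1:4, 1:5), "equal length")
})

test_that("Pearson interval uses the Fisher transform", {
  set.seed(2)
  x <- rnorm(30); y <- x + rnorm(30)
  got <- pearson_r_ci(x, y)
  z <- atanh(oracle_pearson(x, y))
  half <- qnorm(0.975) / sqrt(30 - 3)
  expect_equal(got$ci_low, tanh(z - half), tolerance = 1e-12)
  expect_equal(got$ci_high, tanh(z + half), tolerance = 1e-12)
})

test_that("Lin's concordance penalizes location shifts", {
  x <- c(4, 7, 9, 12)
  expect_equal(lins_ccc_ci(x, x)$ccc, 1)
  expect_equal(lins_ccc_ci(c(1, 2, 3), c(2, 3, 4))$ccc, 4 / 7)
  expect_lt(lins_ccc_ci(x, x + 2)$ccc, 1)
  expect_error(lins_ccc_ci(rep(3, 4), rep(3, 4)), "degenerate")
})

test_that("concordance never exceeds correlation in magnitude", {
  set.seed(9)
  for (i in 1:200) {
    n <- sample(4:40, 1)
    x <- rnorm(n, sd = runif(1, 0.5, 3))
    y <- runif(1, -1, 1.5) * x + rnorm(n, runif(1, -2, 2))
    cc <- lins_ccc_ci(x, y)$ccc
    r <- pearson_r_ci(x, y)$r
    expect_lte(abs(cc), abs(r) + 1e-12)
    expect_equal(cc, oracle_ccc(x, y), tolerance = 1e-12)
  }
})

test_that("regression of method on reference solves the normal equations", {
  x <- c(1, 4, 9, 11)
  exact <- simple_linear_regression(0.5 * x + 3, x)
  expect_equal(exact$slope, 0.5)
  expect_equal(exact$intercept, 3)
  got <- simple_linear_regression(c(0, 1, 1), c(0, 1, 2))
  expect_equal(got$slope, 0.5)
  expect_equal(got$intercept, 1 / 6)
  expect_equal(simple_linear_regression(x, x)$slope, 1)
  expect_error(simple_linear_regression(1:3, rep(2, 3)),
               "degenerate predictor")
  # t-quantile confidence interval against the direct formula
  set.seed(4)
  xr <- rnorm(12); yr <- 0.8 * xr + rnorm(12, sd = 0.5)
  ci <- simple_linear_regression(yr, xr)
  fit <- oracle_ols(yr, xr)
  expect_equal(ci$slope, unname(fit["slope"]), tolerance = 1e-12)
  expect_equal(mean(ci$slope_ci), ci$slope, tolerance = 1e-12)
})

test_that("Bland-Altman bias, SD and limits follow the definitions", {
  x <- c(3, 5, 8, 13)
  same <- bland_altman(x, x)
  expect_equal(c(same$bias, same$sd, same$loa_low, same$loa_high),
               c(0, 0, 0, 0))
  off <- bland_altman(x + 1, x)
  expect_equal(c(off$bias, off$sd), c(1, 0))
  ex <- bland_altman(c(2, 4, 6), c(1, 2, 3))
  expect_equal(ex$points$difference, c(1, 2, 3))
  expect_equal(c(ex$bias, ex$sd, ex$loa_low, ex$loa_high), c(2, 1, 0, 4))
  # limits widen by the exact multiplier ratio and bracket symmetrically
  set.seed(5)
  a <- rnorm(20); b <- a + rnorm(20)
  w2 <- bland_altman(a, b, 2.0)
  w196 <- bland_altman(a, b, 1.96)
  expect_equal((w2$loa_high - w2$loa_low) / (w196$loa_high - w196$loa_low),
               2.0 / 1.96, tolerance = 1e-12)
  expect_equal(w2$loa_high - w2$bias, w2$bias - w2$loa_low,
               tolerance = 1e-12)
  orc <- oracle_bland_altman(a, b)
  expect_equal(w2$bias, orc$bias, tolerance = 1e-12)
  expect_equal(w2$sd, orc$sd, tolerance = 1e-12)
})

test_that("proportional bias regresses differences on averages", {
  r <- c(2, 5, 9, 14)
  expect_equal(proportional_bias(r + 3, r)$slope, 0, tolerance = 1e-12)
  expect_equal(proportional_bias(1.2 * r, r)$slope, 0.2 / 1.1,
               tolerance = 1e-12)
  # a method that under-reads high values trends negative
  expect_lt(proportional_bias(0.9 * r, r)$slope, 0)
  set.seed(6)
  a <- rnorm(25, 10, 3); b <- a + rnorm(25)
  got <- proportional_bias(a, b)
  expect_equal(got$p_value, oracle_ols_slope_p(a - b, (a + b) / 2),
               tolerance = 1e-10)
  expect_error(proportional_bias(c(1, -1, 2), c(1, 3, 0)),
               "degenerate averages")
})

test_that("paired t-test matches the classical statistic and stats::t.test", {
  x <- c(2, 4, 7, 9)
  same <- paired_t_test(x, x)
  expect_equal(c(same$t, same$p), c(0, 1))
  const <- paired_t_test(x + 1, x)
  expect_equal(const$flag, "constant-nonzero-difference")
  expect_lte(const$p, .Machine$double.xmin)
  got <- paired_t_test(c(2, 4, 6), c(1, 2, 3))
  expect_equal(got$t, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(got$df, 2)
  set.seed(8)
  a <- rnorm(15); b <- a + rnorm(15, 0.3)
  mine <- paired_t_test(a, b)
  ref <- stats::t.test(a, b, paired = TRUE)
  expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  expect_error(paired_t_test(1, 1), "at least 2")
})

test_that("the correlation sample-size formula behaves", {
  expect_identical(sample_size_for_correlation(0.90, 0.05, 0.80), 7L)
  # near-perfect correlation floors at ceil(3 + eps) = 4
  expect_identical(sample_size_for_correlation(0.999999), 4L)
  rhos <- c(0.3, 0.5, 0.7, 0.9)
  ns <- vapply(rhos, sample_size_for_correlation, integer(1))
  expect_true(all(diff(ns) < 0))
  expect_error(sample_size_for_correlation(1), "strictly")
  expect_error(sample_size_for_correlation(0), "strictly")
})
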