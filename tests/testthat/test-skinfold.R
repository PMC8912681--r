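test_that("site means average the available replicates", {
  expect_equal(mean_skinfold_site(c(10, 10, 10, 10)), 10)
  expect_equal(mean_skinfold_site(c(8, 9, 10, 13)), 10)
  expect_equal(mean_skinfold_site(12.2), 12.2)
  expect_warning(mean_skinfold_site(c(10, 11), warn_incomplete = TRUE),
                 "fewer than 4")
})

test_that("site means reject empty and out-of-range readings", {
  expect_error(mean_skinfold_site(numeric(0)), "no readings")
  expect_error(mean_skinfold_site(c(10, 81)), "caliper range")
  expect_error(mean_skinfold_site(c(0, 10)), "caliper range")
  expect_error(mean_skinfold_site(rep(10, 5)), "at most 4")
})

test_that("Slaughter equations evaluate the printed sex-specific lines", {
  # group-mean skinfold sums, percent fat rounded to one decimal
  expect_equal(round(slaughter_percent_fat("female", 32.3, 0), 1), 24.8)
  expect_equal(round(slaughter_percent_fat("male", 22.1, 0), 1), 17.2)
  expect_equal(slaughter_percent_fat("male", 0, 0), 1.0)
  expect_equal(slaughter_percent_fat("female", 10, 0), 0.610 * 10 + 5.1)
  expect_error(slaughter_percent_fat("female", -1, 5), "non-negative")
  expect_error(slaughter_percent_fat("other", 10, 10), "sex must be")
})

test_that("Slaughter lines are affine, increasing, and cross at 32.8 mm", {
  s <- seq(0, 60, by = 2.5)
  f <- slaughter_percent_fat(rep("female", length(s)), s, 0)
  m <- slaughter_percent_fat(rep("male", length(s)), s, 0)
  expect_true(all(diff(f) > 0) && all(diff(m) > 0))
  # affine: second differences vanish
  expect_equal(diff(diff(f)), rep(0, length(s) - 2))
  # the male and female lines intersect where 0.735s + 1 = 0.610s + 5.1
  expect_equal(slaughter_percent_fat("male", 32.8, 0),
               slaughter_percent_fat("female", 32.8, 0))
})

test_that("the skinfold-sum inversion is the exact inverse", {
  for (sex in c("female", "male")) {
    pct <- slaughter_percent_fat(sex, 13.7, 9.2)
    expect_equal(bodycomp4c:::slaughter_sum_from_percent(sex, pct),
                 13.7 + 9.2)
  }
})

test_that("fat mass from percent fat is the weight fraction", {
  expect_equal(fat_mass_from_percent(0, 50), 0)
  expect_equal(fat_mass_from_percent(50, 40), 20)
  expect_equal(fat_mass_from_percent(24.8, 51.2), 24.8 / 100 * 51.2)
  expect_error(fat_mass_from_percent(101, 50), "\\[0, 100\\]")
  expect_error(fat_mass_from_percent(10, 0), "positive")
})

test_that("bmi divides weight by squared height in metres", {
  expect_equal(bmi(50, 200), 12.5)
  expect_equal(bmi(81, 90), 100)
  expect_equal(bmi(26.1, 123.5), 26.1 / 1.235^2)
  expect_error(bmi(0, 150), "positive")
})
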