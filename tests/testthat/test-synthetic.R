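test_that("the default scenario encodes the four-stratum study design", {
  sc <- default_scenario()
  expect_equal(nrow(sc$strata), 4L)
  expect_equal(sum(sc$strata$n), 288L)
  expect_setequal(sc$errors$method, c("SF", "ADP", "DXA", "D2O", "MRI"))
})

test_that("cohort generation is deterministic under a fixed seed", {
  a <- generate_cohort(default_scenario(), seed = 5)
  b <- generate_cohort(default_scenario(), seed = 5)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$truth, b$truth)
  c2 <- generate_cohort(default_scenario(), seed = 6)
  expect_false(identical(a$cohort, c2$cohort))
})

test_that("a zero-SD stratum collapses to its means", {
  st <- stratum_spec("female", "children", n = 5, age_mean = 8, age_sd = 0,
                     weight_mean = 26, weight_sd = 0, height_mean = 124,
                     height_sd = 0, fatfrac_mean = 0.20, fatfrac_sd = 0)
  tr <- generate_truth(st, seed = 1)
  expect_equal(nrow(tr), 5L)
  expect_equal(unique(tr$weight_kg), 26)
  expect_equal(unique(tr$true_fm_kg), 0.20 * 26)
  expect_equal(length(unique(tr$true_bv_L)), 1L)
})

test_that("truth inputs reproduce the generated fat mass through the model", {
  tr <- generate_truth(default_scenario()$strata, seed = 2)
  fm <- fourc_fat_mass(tr$true_bv_L, tr$true_tbw_L, tr$true_bmc_g,
                       tr$weight_kg)
  expect_equal(fm, tr$true_fm_kg, tolerance = 1e-9)
  expect_equal(tr$true_fm_kg + tr$true_ffm_kg, tr$weight_kg,
               tolerance = 1e-12)
})

test_that("a zero-error cohort is recovered exactly by every estimator", {
  sc <- default_scenario()
  sc$errors <- zeroed_errors(sc$errors)
  sim <- generate_cohort(sc, seed = 7)
  est <- estimate_composition(sim$cohort)
  merged <- dplyr::left_join(
    est, dplyr::select(sim$truth, participant_id = id, true_fm_kg),
    by = "participant_id")
  tol <- c(SF = 1e-9, ADP = 1e-9, DXA = 1e-9, D2O = 1e-9,
           MRI = 1e-4, FOURC = 1e-9)
  for (m in names(tol)) {
    sub <- merged[merged$method == m, ]
    expect_false(anyNA(sub$fm_kg))
    expect_equal(sub$fm_kg, sub$true_fm_kg, tolerance = tol[[m]])
  }
})

test_that("generated raw records satisfy every measurement invariant", {
  sim <- generate_cohort(default_scenario(), seed = 13)
  co <- sim$cohort
  sf <- as.matrix(co[, c(paste0("tri_sf_", 1:4), paste0("calf_sf_", 1:4))])
  expect_true(all(sf > 0 & sf <= 80))
  expect_true(all(co$adp_vol1_L > 0 & co$adp_vol2_L > 0))
  expect_true(all(abs(co$adp_vol1_L - co$adp_vol2_L) <= 0.150))
  dens <- co$adp_mass_kg / ((co$adp_vol1_L + co$adp_vol2_L) / 2)
  expect_true(all(dens > 0.9 & dens < 1.15))
  expect_true(all(co$dxa_lm_kg >= 0 & co$dxa_bmc_g >= 0 &
                    co$dxa_fm_kg >= 0))
  expect_true(all(co$d2o_bottle_d2o_g >= co$d2o_bottle_empty_g))
  expect_true(all(co$d2o_bottle_d2o_water_g >= co$d2o_bottle_d2o_g))
  expect_true(all(co$d2o_ap_post_pct > co$d2o_ap_pre_pct))
  expect_true(all(co$mri_n_voxels >= 0 & co$mri_voxel_vol_L > 0))
  # no generated deuterium session trips the outlier screen
  flags <- vapply(seq_len(nrow(co)), function(i)
    length(dose_outlier_flags(co$d2o_bottle_empty_g[i],
                              co$d2o_bottle_d2o_g[i],
                              co$d2o_bottle_drunk_g[i],
                              co$weight_kg[i])), integer(1))
  expect_true(all(flags == 0L))
})

test_that("an injected constant offset on a free-standing method recovers", {
  sc <- default_scenario()
  sc$errors <- single_method_errors(sc$errors, "DXA", bias = 2.0, sd = 1.5)
  sim <- generate_cohort(sc, seed = 21)
  tab <- comparison_table(estimate_composition(sim$cohort),
                          group_by = "total")
  got <- tab$ba_bias[tab$method == "DXA"]
  expect_lt(abs(got - 2.0), 3 * 1.5 / sqrt(288))
})
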