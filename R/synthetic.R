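#' Stratum specification for the synthetic cohort
#'
#' One row per age-sex stratum: sample size, truncated-normal means and SDs
#' for age, weight (kg), height (cm) and the true (four-component) fat
#' fraction, plus the within-stratum correlation between body size and
#' fatness and between weight and height.
#'
#' @param sex `"female"` or `"male"`.
#' @param age_group `"children"` (4-10 years) or `"adolescents"` (11-18).
#' @param n Number of participants, at least 3.
#' @param age_mean,age_sd,weight_mean,weight_sd,height_mean,height_sd
#'   Marginal moments before truncation.
#' @param fatfrac_mean,fatfrac_sd True fat fraction moments; the mean must
#'   lie in (0.03, 0.55).
#' @param cor_weight_fatfrac Correlation between weight and fat fraction
#'   (default 0.5).
#' @param cor_weight_height Correlation between weight and height
#'   (default 0.8).
#' @return A one-row tibble.
#' @export
stratum_spec <- function(sex, age_group, n, age_mean, age_sd,
                         weight_mean, weight_sd, height_mean, height_sd,
                         fatfrac_mean, fatfrac_sd,
                         cor_weight_fatfrac = 0.5, cor_weight_height = 0.8) {
  stopifnot(n >= 3, age_sd >= 0, weight_sd >= 0, height_sd >= 0,
            fatfrac_sd >= 0, fatfrac_mean > 0.03, fatfrac_mean < 0.55,
            age_group %in% c("children", "adolescents"))
  tibble::tibble(
    sex = validate_sex(sex), age_group = age_group, n = as.integer(n),
    age_mean = age_mean, age_sd = age_sd,
    weight_mean = weight_mean, weight_sd = weight_sd,
    height_mean = height_mean, height_sd = height_sd,
    fatfrac_mean = fatfrac_mean, fatfrac_sd = fatfrac_sd,
    cor_weight_fatfrac = cor_weight_fatfrac,
    cor_weight_height = cor_weight_height
  )
}

#' Per-method measurement-error specification
#'
#' Each method's observed fat mass is modelled as
#' `observed = true + constant_bias + proportional_slope * true + e`,
#' `e ~ Normal(0, residual_sd)`, before the raw instrument readings are
#' back-solved from the observed value.
#'
#' @param method Method code (`SF`, `ADP`, `DXA`, `D2O`, `MRI`).
#' @param constant_bias_kg Constant additive bias in kg.
#' @param proportional_slope Bias per kg of true fat mass.
#' @param residual_sd_kg Residual SD in kg, non-negative.
#' @return A one-row tibble.
#' @export
error_model_spec <- function(method, constant_bias_kg = 0,
                             proportional_slope = 0, residual_sd_kg = 0) {
  stopifnot(residual_sd_kg >= 0)
  tibble::tibble(method = method, constant_bias_kg = constant_bias_kg,
                 proportional_slope = proportional_slope,
                 residual_sd_kg = residual_sd_kg)
}

#' Read a simulation scenario file
#'
#' A scenario is a YAML file with a `strata:` list (fields of
#' [stratum_spec()]) and an `errors:` list (fields of [error_model_spec()]).
#'
#' @param path Path to the YAML scenario.
#' @return A list with tibbles `strata` and `errors`.
#' @export
read_scenario <- function(path) {
  raw <- yaml::read_yaml(path)
  strata <- dplyr::bind_rows(lapply(raw$strata, function(s)
    do.call(stratum_spec, s)))
  errors <- dplyr::bind_rows(lapply(raw$errors, function(e)
    do.call(error_model_spec, e)))
  list(strata = strata, errors = errors)
}

#' The default study scenario
#'
#' Four age-sex strata (63 and 54 children, 92 and 79 adolescents, 288
#' participants in total) with means and SDs of a published pediatric
#' validation cohort, and a five-method error model whose bias, slope and
#' residual-SD values mirror that study's reported Bland-Altman structure.
#' Shipped as a YAML file under `extdata` and read with [read_scenario()].
#'
#' @return A list with tibbles `strata` and `errors`.
#' @export
default_scenario <- function() {
  read_scenario(system.file("extdata", "default_scenario.yaml",
                            package = "bodycomp4c"))
}

#' Generate the hidden-truth table for a synthetic cohort
#'
#' Draws per-participant age, weight, height and true fat fraction from
#' truncated normal marginals with the specified correlations (Gaussian
#' copula via multivariate-normal draws, out-of-bound rows redrawn), then
#' derives the remaining true quantities deterministically: fat mass, FFM,
#' total body water through the age-sex hydration coefficient, bone mineral
#' content as the configured fraction of FFM, and body volume by inverting
#' the four-component formula so that the forward model returns the
#' generated fat mass exactly.
#'
#' Truncation bounds: weight > 10 kg, height in (80, 210) cm, fat fraction
#' in (0.08, 0.55) -- the lower bound keeps every draw inside the domain of
#' all five estimators (the female Slaughter line has a 5.1% floor) -- and
#' age within the stratum's group band.
#'
#' @param strata Tibble of [stratum_spec()] rows.
#' @param constants A [load_constants()] object.
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @return Truth tibble, one row per participant.
#' @export
generate_truth <- function(strata, constants = load_constants(),
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", nrow(strata))
  id0 <- 0L
  for (k in seq_len(nrow(strata))) {
    s <- strata[k, ]
    draws <- draw_stratum(s)
    hc <- hydration_coefficient(rep(s$sex, s$n), draws$age, constants)
    band <- lookup_band(constants$hydration, rep(s$sex, s$n), draws$age)
    fm <- draws$fatfrac * draws$weight
    ffm <- draws$weight - fm
    tbw_kg <- hc * ffm
    tbw_L <- tbw_kg / 0.99371
    bmc_g <- band$bmc_frac * ffm * 1000
    bv <- fourc_body_volume(fm, tbw_L, bmc_g, draws$weight)
    if (any(bv <= 0))
      stop("infeasible stratum spec: non-positive implied body volume at ",
           "draw index ", which(bv <= 0)[1], " of stratum ", k)
    out[[k]] <- tibble::tibble(
      id = sprintf("P%04d", id0 + seq_len(s$n)),
      sex = s$sex, age_group = s$age_group,
      age_years = draws$age, weight_kg = draws$weight,
      height_cm = draws$height,
      true_fm_kg = fm, true_ffm_kg = ffm,
      true_tbw_kg = tbw_kg, true_tbw_L = tbw_L,
      true_bmc_g = bmc_g, true_bv_L = bv,
      hydration_coef = hc, bmc_frac = band$bmc_frac
    )
    id0 <- id0 + s$n
  }
  dplyr::bind_rows(out)
}

# Correlated truncated-normal draws for one stratum.  The height-fatness
# correlation is taken as the product of the two specified correlations,
# which keeps the 3x3 matrix positive definite for any pair in (-1, 1).
draw_stratum <- function(s) {
  rwf <- s$cor_weight_fatfrac
  rwh <- s$cor_weight_height
  sigma <- rbind(c(1, rwh, rwf),
                 c(rwh, 1, rwh * rwf),
                 c(rwf, rwh * rwf, 1))
  mu <- c(s$weight_mean, s$height_mean, s$fatfrac_mean)
  sd <- c(s$weight_sd, s$height_sd, s$fatfrac_sd)
  age_lo <- if (s$age_group == "children") 4 else 11
  age_hi <- if (s$age_group == "children") 11 else 19

  n <- s$n
  w <- h <- f <- rep(NA_real_, n)
  need <- rep(TRUE, n)
  for (tries in 1:1000) {
    m <- sum(need)
    if (m == 0L) break
    z <- MASS::mvrnorm(m, mu = rep(0, 3), Sigma = sigma)
    z <- matrix(z, ncol = 3)
    cand <- sweep(sweep(z, 2, sd, `*`), 2, mu, `+`)
    ok <- cand[, 1] > 10 & cand[, 2] > 80 & cand[, 2] < 210 &
      cand[, 3] > 0.08 & cand[, 3] < 0.55
    idx <- which(need)[ok]
    w[idx] <- cand[ok, 1]; h[idx] <- cand[ok, 2]; f[idx] <- cand[ok, 3]
    need[idx] <- FALSE
  }
  if (any(need))
    stop("could not draw within truncation bounds for stratum ", s$sex,
         "/", s$age_group)
  age <- rep(NA_real_, n)
  aneed <- rep(TRUE, n)
  for (tries in 1:1000) {
    m <- sum(aneed)
    if (m == 0L) break
    a <- stats::rnorm(m, s$age_mean, s$age_sd)
    ok <- a >= age_lo & a < age_hi
    age[which(aneed)[ok]] <- a[ok]
    aneed[which(aneed)[ok]] <- FALSE
  }
  if (any(aneed)) stop("could not draw ages within the group band")
  list(weight = w, height = h, fatfrac = f, age = age)
}

#' Apply per-method instrument errors and back-solve raw measurements
#'
#' For every method in the error model the intended observed fat mass is
#' drawn as `true + bias + slope*true + Normal(0, sd)`, then the raw
#' instrument readings are back-solved so that the estimation pipeline
#' reproduces that observed value: skinfold sums are inverted through the
#' Slaughter equations (with zero-sum replicate scatter so site means are
#' exact), body-volume readings through the density equation and the
#' two-compartment constants, bottle weights and saliva enrichments through
#' the dose and dilution formulas, DXA components by partitioning the
#' observed fat-free mass around the true bone mineral content, and MRI by
#' rounding to a whole fat-voxel count.
#'
#' A draw whose back-solved readings would violate a raw-measurement
#' invariant (e.g. a negative skinfold sum or a non-physiologic body
#' density) is redrawn, up to `max_retries` times per participant and
#' method, after which generation stops with an error.
#'
#' @param truth Truth table from [generate_truth()].
#' @param errors Tibble of [error_model_spec()] rows.
#' @param constants A [load_constants()] object.
#' @param seed Optional integer seed.
#' @param max_retries Redraw budget per participant and method.
#' @return A tibble in the raw participant-CSV schema (see
#'   [read_participants()]) with the hidden truth columns `true_fm_kg`,
#'   `true_ffm_kg`, `true_tbw_kg` appended.
#' @export
apply_instrument_errors <- function(truth, errors,
                                    constants = load_constants(),
                                    seed = NULL, max_retries = 20L) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(truth)
  w <- truth$weight_kg
  cohort <- tibble::tibble(
    id = truth$id, sex = truth$sex, age_years = truth$age_years,
    weight_kg = w, height_cm = truth$height_cm
  )

  observed_fm <- function(spec) {
    draw <- function(m) truth$true_fm_kg[m] + spec$constant_bias_kg +
      spec$proportional_slope * truth$true_fm_kg[m] +
      stats::rnorm(sum(m), 0, spec$residual_sd_kg)
    fm <- draw(rep(TRUE, n))
    list(fm = fm, redraw = draw)
  }
  resolve <- function(spec, valid_of, fm0, redraw) {
    fm <- fm0$fm
    bad <- !valid_of(fm)
    tries <- 0L
    while (any(bad)) {
      tries <- tries + 1L
      if (tries > max_retries)
        stop("back-solve for method ", spec$method, " failed after ",
             max_retries, " retries at participant ",
             truth$id[which(bad)[1]])
      fm[bad] <- fm0$redraw(bad)
      bad <- !valid_of(fm)
    }
    fm
  }
  spec_for <- function(m) {
    row <- errors[errors$method == m, ]
    if (nrow(row) == 0L) NULL else row
  }

  # Skinfolds: invert Slaughter, split the sum equally across sites, spread
  # each site mean over 4 replicates with zero-mean multiplicative scatter
  # (~4% replicate CV) so the site mean stays exact and readings stay in the
  # caliper range.
  sp <- spec_for("SF")
  if (!is.null(sp)) {
    z <- matrix(stats::rnorm(n * 4), n, 4)
    z <- 0.04 * (z - rowMeans(z))
    ok_sf <- function(fm) {
      s <- slaughter_sum_from_percent(truth$sex, 100 * fm / w)
      site <- s / 2
      reps_ok <- site * (1 + apply(z, 1, min)) > 0 &
        site * (1 + apply(z, 1, max)) <= 80
      !is.na(s) & s > 0.5 & s <= 160 & reps_ok
    }
    fm_sf <- resolve(sp, ok_sf, observed_fm(sp), NULL)
    site <- slaughter_sum_from_percent(truth$sex, 100 * fm_sf / w) / 2
    for (j in 1:4) {
      cohort[[paste0("tri_sf_", j)]] <- site * (1 + z[, j])
      cohort[[paste0("calf_sf_", j)]] <- site * (1 + z[, (j %% 4) + 1])
    }
  }

  # ADP: observed percent fat -> density via the band constants -> body
  # volume; two chamber readings straddle the target with zero-sum offsets
  # inside the 150 mL agreement window.
  sp <- spec_for("ADP")
  if (!is.null(sp)) {
    cc <- adp_constants(truth$sex, truth$age_years, constants)
    u <- stats::runif(n, 0, 0.07)
    ok_adp <- function(fm) {
      db <- adp_density_from_percent(100 * fm / w, cc$c1, cc$c2)
      db > 0.9 & db < 1.15
    }
    fm_adp <- resolve(sp, ok_adp, observed_fm(sp), NULL)
    db <- adp_density_from_percent(100 * fm_adp / w, cc$c1, cc$c2)
    bv <- w / db
    cohort$adp_mass_kg <- w
    cohort$adp_vol1_L <- bv + u
    cohort$adp_vol2_L <- bv - u
    cohort$adp_vol3_L <- NA_real_
    cohort$adp_tgv_L <- 0.045 * w + stats::rnorm(n, 0, 0.05)
  } else {
    # the reference model still needs a body volume: truth, unperturbed
    cohort$adp_mass_kg <- w
    cohort$adp_vol1_L <- truth$true_bv_L
    cohort$adp_vol2_L <- truth$true_bv_L
    cohort$adp_vol3_L <- NA_real_
    cohort$adp_tgv_L <- 0.045 * w
  }

  # DXA: fat mass observed directly; lean soft tissue partitions the
  # observed FFM around the true bone mineral content.
  sp <- spec_for("DXA")
  bmc_g <- truth$true_bmc_g
  cohort$dxa_bmc_g <- bmc_g
  if (!is.null(sp)) {
    ok_dxa <- function(fm) fm >= 0 & (w - fm - bmc_g / 1000) >= 0
    fm_dxa <- resolve(sp, ok_dxa, observed_fm(sp), NULL)
    cohort$dxa_fm_kg <- fm_dxa
    cohort$dxa_lm_kg <- w - fm_dxa - bmc_g / 1000
  } else {
    cohort$dxa_fm_kg <- truth$true_fm_kg
    cohort$dxa_lm_kg <- truth$true_ffm_kg - bmc_g / 1000
  }

  # Deuterium: observed FFM -> TBW through the band hydration coefficient;
  # bottle weights carry realistic dosing jitter that stays inside the
  # outlier rules, and the enrichment difference inverts the dilution
  # formula at the consumed dose.
  sp <- spec_for("D2O")
  empty <- stats::runif(n, 19.5, 20.5)
  target <- constants$d2o_target_dose_g_per_kg * w
  weighed <- target * stats::runif(n, 0.93, 1.07)
  water <- stats::runif(n, 49.5, 50.5)
  residual <- stats::runif(n, 0.05, 0.8)
  fm_d2o <- if (!is.null(sp)) {
    ok_d2o <- function(fm) fm >= 0 & fm < w - 1
    resolve(sp, ok_d2o, observed_fm(sp), NULL)
  } else truth$true_fm_kg
  hc <- truth$hydration_coef
  tbw_obs <- hc * (w - fm_d2o)
  cohort$d2o_bottle_empty_g <- empty
  cohort$d2o_bottle_d2o_g <- empty + weighed
  cohort$d2o_bottle_d2o_water_g <- empty + weighed + water
  cohort$d2o_bottle_drunk_g <- empty + residual
  consumed <- weighed * (weighed + water - residual) / (weighed + water)
  cohort$d2o_ap_pre_pct <- 0.0156
  cohort$d2o_ap_post_pct <- 0.0156 +
    dilution_delta_ap(consumed, tbw_obs, constants$d2o_concentration_pct)

  # MRI: whole-voxel count at a fixed voxel volume (1.5 x 1.5 x 6 mm).
  sp <- spec_for("MRI")
  voxvol <- 1.35e-5
  fm_mri <- if (!is.null(sp)) {
    ok_mri <- function(fm) fm >= 0
    resolve(sp, ok_mri, observed_fm(sp), NULL)
  } else truth$true_fm_kg
  cohort$mri_n_voxels <-
    round(fm_mri / (voxvol * constants$adipose_density_kg_per_L))
  cohort$mri_voxel_vol_L <- voxvol

  cohort$true_fm_kg <- truth$true_fm_kg
  cohort$true_ffm_kg <- truth$true_ffm_kg
  cohort$true_tbw_kg <- truth$true_tbw_kg
  cohort
}

#' Generate a complete synthetic cohort
#'
#' Convenience wrapper: [generate_truth()] then
#' [apply_instrument_errors()] under a single seed.
#'
#' @param scenario A list with `strata` and `errors` tibbles, e.g. from
#'   [default_scenario()] or [read_scenario()].
#' @param constants A [load_constants()] object.
#' @param seed Integer seed controlling all randomness.
#' @return A list with `cohort` (raw-measurement schema plus truth columns)
#'   and `truth` (the full truth table).
#' @export
generate_cohort <- function(scenario = default_scenario(),
                            constants = load_constants(), seed = 1L) {
  set.seed(seed)
  truth <- generate_truth(scenario$strata, constants, seed = NULL)
  cohort <- apply_instrument_errors(truth, scenario$errors, constants,
                                    seed = NULL)
  list(cohort = cohort, truth = truth)
}
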