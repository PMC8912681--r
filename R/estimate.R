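#' Estimate body composition by every available method
#'
#' Runs the five clinical estimators plus the four-component reference over
#' a validated participant table (see [read_participants()] for the column
#' schema) and returns one tidy row per participant per method.  Methods
#' with missing raw inputs yield rows with missing estimates and an
#' explanatory flag rather than being dropped, so exclusions stay auditable
#' -- deuterium sessions tripping a dose-outlier rule are treated the same
#' way.
#'
#' Method codes: `SF` (Slaughter skinfolds), `ADP` (air-displacement
#' plethysmography), `DXA`, `D2O` (deuterium dilution), `MRI` (fat-voxel
#' counting), `FOURC` (the reference model).  The four-component row also
#' carries the hydration of fat-free mass (TBW/FFM, percent).
#'
#' @param participants Tibble of raw measurements, one row per participant.
#' @param constants A [load_constants()] object.
#' @return Tidy tibble with columns `participant_id`, `sex`, `age_years`,
#'   `age_group`, `weight_kg`, `method`, `fm_kg`, `ffm_kg`, `pct_fat`,
#'   `hydration_pct`, `flags`.
#' @export
estimate_composition <- function(participants, constants = load_constants()) {
  p <- participants
  n <- nrow(p)
  if (n == 0L) return(empty_estimates())
  check_age_range(p$age_years)
  col <- function(nm) if (nm %in% names(p)) p[[nm]] else rep(NA_real_, n)

  sex <- validate_sex(p$sex)
  w <- p$weight_kg
  base <- tibble::tibble(
    participant_id = as.character(p$id), sex = sex,
    age_years = p$age_years, age_group = age_group_of(p$age_years),
    weight_kg = w
  )

  # --- skinfolds ---------------------------------------------------------
  tri <- site_means(p, "tri_sf_", n)
  calf <- site_means(p, "calf_sf_", n)
  sf_ok <- !is.na(tri) & !is.na(calf)
  sf_pct <- rep(NA_real_, n)
  sf_pct[sf_ok] <- slaughter_percent_fat(sex[sf_ok], tri[sf_ok], calf[sf_ok])
  sf <- method_rows(base, "SF", fm = sf_pct / 100 * w, weight = w,
                    flags = ifelse(sf_ok, NA, "missing-skinfolds"))

  # --- ADP ---------------------------------------------------------------
  adp_mass <- ifelse(is.na(col("adp_mass_kg")), w, col("adp_mass_kg"))
  bv <- rep(NA_real_, n)
  adp_flag <- rep(NA_character_, n)
  vols <- cbind(col("adp_vol1_L"), col("adp_vol2_L"), col("adp_vol3_L"))
  for (i in seq_len(n)) {
    vi <- vols[i, ][!is.na(vols[i, ])]
    if (length(vi) < 2L) {
      adp_flag[i] <- "missing-volumes"
      next
    }
    bv[i] <- tryCatch(select_body_volume(vi),
                      error = function(e) {
                        adp_flag[i] <<- conditionMessage(e)
                        NA_real_
                      })
  }
  adp_ok <- !is.na(bv)
  adp_pct <- rep(NA_real_, n)
  adp_fm <- rep(NA_real_, n)
  if (any(adp_ok)) {
    db <- body_density(adp_mass[adp_ok], bv[adp_ok])
    adp_pct[adp_ok] <- adp_percent_fat(db, sex[adp_ok],
                                       p$age_years[adp_ok], constants)
    adp_fm[adp_ok] <- adp_pct[adp_ok] / 100 * adp_mass[adp_ok]
  }
  adp <- method_rows(base, "ADP", fm = adp_fm, weight = adp_mass,
                     flags = adp_flag)

  # --- DXA ---------------------------------------------------------------
  dxa_lm <- col("dxa_lm_kg"); dxa_bmc <- col("dxa_bmc_g")
  dxa_fm <- col("dxa_fm_kg")
  dxa_ok <- !is.na(dxa_lm) & !is.na(dxa_bmc) & !is.na(dxa_fm)
  dxa <- tibble::tibble(
    base, method = "DXA",
    fm_kg = dxa_fm,
    ffm_kg = ifelse(dxa_ok, dxa_ffm(pmax(dxa_lm, 0), pmax(dxa_bmc, 0)),
                    NA_real_),
    pct_fat = 100 * dxa_fm / w,
    hydration_pct = NA_real_,
    flags = ifelse(dxa_ok, NA_character_, "missing-dxa")
  )

  # --- deuterium dilution ------------------------------------------------
  be <- col("d2o_bottle_empty_g"); bd <- col("d2o_bottle_d2o_g")
  bw <- col("d2o_bottle_d2o_water_g"); bk <- col("d2o_bottle_drunk_g")
  ap_pre <- col("d2o_ap_pre_pct"); ap_post <- col("d2o_ap_post_pct")
  tbw_kg <- rep(NA_real_, n)
  tbw_L <- rep(NA_real_, n)
  d2o_flag <- rep(NA_character_, n)
  target <- constants$d2o_target_dose_g_per_kg
  conc <- constants$d2o_concentration_pct
  for (i in seq_len(n)) {
    if (anyNA(c(be[i], bd[i], bw[i], bk[i], ap_pre[i], ap_post[i]))) {
      d2o_flag[i] <- "missing-d2o"
      next
    }
    fl <- dose_outlier_flags(be[i], bd[i], bk[i], w[i], target)
    if (length(fl)) {
      d2o_flag[i] <- paste(fl, collapse = ";")
      next
    }
    if (ap_post[i] <= ap_pre[i]) {
      d2o_flag[i] <- "NO_ENRICHMENT"
      next
    }
    dose <- d2o_dose_g(be[i], bd[i], bw[i], bk[i])
    tb <- tbw_from_dilution(dose, ap_post[i], ap_pre[i], conc)
    tbw_kg[i] <- tb$tbw_kg
    tbw_L[i] <- tb$tbw_L
  }
  d2o_ok <- !is.na(tbw_kg)
  d2o_ffm <- rep(NA_real_, n)
  if (any(d2o_ok))
    d2o_ffm[d2o_ok] <- ffm_from_tbw(tbw_kg[d2o_ok], sex[d2o_ok],
                                    p$age_years[d2o_ok], constants)
  d2o <- method_rows(base, "D2O", fm = w - d2o_ffm, weight = w,
                     flags = d2o_flag)

  # --- MRI ---------------------------------------------------------------
  nv <- col("mri_n_voxels"); vv <- col("mri_voxel_vol_L")
  mri_ok <- !is.na(nv) & !is.na(vv)
  mri_fm <- rep(NA_real_, n)
  if (any(mri_ok))
    mri_fm[mri_ok] <- mri_fat_mass(nv[mri_ok], vv[mri_ok],
                                   constants$adipose_density_kg_per_L)
  mri <- method_rows(base, "MRI", fm = mri_fm, weight = w,
                     flags = ifelse(mri_ok, NA, "missing-mri"))

  # --- four-component reference ------------------------------------------
  fourc_ok <- !is.na(bv) & !is.na(tbw_L) & !is.na(dxa_bmc)
  fc_fm <- rep(NA_real_, n)
  if (any(fourc_ok))
    fc_fm[fourc_ok] <- fourc_fat_mass(bv[fourc_ok], tbw_L[fourc_ok],
                                      dxa_bmc[fourc_ok], w[fourc_ok])
  fourc <- method_rows(base, "FOURC", fm = fc_fm, weight = w,
                       flags = ifelse(fourc_ok, NA, "incomplete-inputs"))
  hyd_ok <- fourc_ok & (w - fc_fm) > 0
  fourc$hydration_pct[hyd_ok] <-
    suppressWarnings(hydration_percent(tbw_kg[hyd_ok],
                                       w[hyd_ok] - fc_fm[hyd_ok]))

  dplyr::bind_rows(sf, adp, dxa, d2o, mri, fourc) |>
    dplyr::arrange(.data$participant_id)
}

# FM-only methods report FFM as the weight remainder, so fm + ffm equals the
# weight basis exactly.
method_rows <- function(base, method, fm, weight, flags) {
  tibble::tibble(
    base, method = method,
    fm_kg = fm, ffm_kg = weight - fm, pct_fat = 100 * fm / weight,
    hydration_pct = NA_real_,
    flags = as.character(flags)
  )
}

site_means <- function(p, prefix, n) {
  cols <- intersect(paste0(prefix, 1:4), names(p))
  if (!length(cols)) return(rep(NA_real_, n))
  m <- as.matrix(p[, cols, drop = FALSE])
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    r <- m[i, ][!is.na(m[i, ])]
    if (length(r)) out[i] <- mean_skinfold_site(r)
  }
  out
}

empty_estimates <- function() {
  tibble::tibble(
    participant_id = character(), sex = character(), age_years = numeric(),
    age_group = character(), weight_kg = numeric(), method = character(),
    fm_kg = numeric(), ffm_kg = numeric(), pct_fat = numeric(),
    hydration_pct = numeric(), flags = character()
  )
}
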