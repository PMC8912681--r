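#' Read a raw participant CSV
#'
#' One row per participant.  Mandatory columns: `id`, `sex`, `age_years`,
#' `weight_kg`, `height_cm`.  Optional per-method columns: `tri_sf_1..4`,
#' `calf_sf_1..4` (mm), `adp_mass_kg`, `adp_vol1_L..adp_vol3_L`, `adp_tgv_L`,
#' `dxa_lm_kg`, `dxa_bmc_g`, `dxa_fm_kg`, `d2o_bottle_empty_g`,
#' `d2o_bottle_d2o_g`, `d2o_bottle_d2o_water_g`, `d2o_bottle_drunk_g`,
#' `d2o_ap_pre_pct`, `d2o_ap_post_pct`, `mri_n_voxels`, `mri_voxel_vol_L`.
#' Empty cells mark methods not measured for that participant.
#'
#' Rows violating a raw-measurement invariant (non-positive weight or
#' height, unknown sex, caliper readings outside (0, 80] mm, non-positive
#' volumes, inconsistent bottle-weight ordering, negative voxel counts) are
#' not silently dropped: they are removed from the returned table and
#' collected in a rejects report attached as the `"rejects"` attribute
#' (columns `row`, `id`, `reason`), mirroring explicit exclusion accounting.
#'
#' @param path Path to the CSV file.
#' @return A tibble of accepted rows with attribute `"rejects"`.
#' @export
read_participants <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  p <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(
                         id = readr::col_character(),
                         sex = readr::col_character(),
                         .default = readr::col_double()
                       ))
  mandatory <- c("id", "sex", "age_years", "weight_kg", "height_cm")
  absent <- setdiff(mandatory, names(p))
  if (length(absent))
    stop("missing mandatory column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)

  rejects <- list()
  probs <- readr::problems(p)
  if (nrow(probs)) {
    for (i in seq_len(nrow(probs))) {
      r <- probs$row[i] - 1L  # header line
      rejects[[length(rejects) + 1L]] <- tibble::tibble(
        row = r, id = if (r >= 1 && r <= nrow(p)) p$id[r] else NA_character_,
        reason = paste0("unparseable cell in column ", probs$col[i],
                        ": expected ", probs$expected[i])
      )
    }
  }
  bad_parse <- unique(vapply(rejects, function(x) x$row, numeric(1)))

  reason <- rep(NA_character_, nrow(p))
  note <- function(rows, msg) {
    new <- which(rows) [is.na(reason[which(rows)])]
    reason[new] <<- msg
  }
  note(is.na(p$weight_kg) | p$weight_kg <= 0, "weight_kg must be positive")
  note(is.na(p$height_cm) | p$height_cm <= 0, "height_cm must be positive")
  note(is.na(p$age_years) | p$age_years <= 0, "age_years must be positive")
  note(!tolower(p$sex) %in% c("female", "male"), "unknown sex")
  for (nm in c(paste0("tri_sf_", 1:4), paste0("calf_sf_", 1:4)))
    if (nm %in% names(p))
      note(!is.na(p[[nm]]) & (p[[nm]] <= 0 | p[[nm]] > 80),
           paste0(nm, " outside the caliper range (0, 80] mm"))
  for (nm in c("adp_vol1_L", "adp_vol2_L", "adp_vol3_L", "adp_mass_kg",
               "mri_voxel_vol_L"))
    if (nm %in% names(p))
      note(!is.na(p[[nm]]) & p[[nm]] <= 0, paste0(nm, " must be positive"))
  if (all(c("d2o_bottle_empty_g", "d2o_bottle_d2o_g",
            "d2o_bottle_d2o_water_g") %in% names(p))) {
    note(!is.na(p$d2o_bottle_d2o_g) &
           p$d2o_bottle_d2o_g < p$d2o_bottle_empty_g,
         "bottle weight decreased when adding D2O")
    note(!is.na(p$d2o_bottle_d2o_water_g) &
           p$d2o_bottle_d2o_water_g < p$d2o_bottle_d2o_g,
         "bottle weight decreased when adding water")
  }
  if ("mri_n_voxels" %in% names(p))
    note(!is.na(p$mri_n_voxels) & p$mri_n_voxels < 0,
         "mri_n_voxels must be non-negative")

  bad <- which(!is.na(reason))
  for (i in bad)
    rejects[[length(rejects) + 1L]] <- tibble::tibble(
      row = i, id = p$id[i], reason = reason[i])
  drop <- union(bad, bad_parse[bad_parse >= 1 & bad_parse <= nrow(p)])
  out <- if (length(drop)) p[-drop, , drop = FALSE] else p
  rej <- if (length(rejects)) dplyr::bind_rows(rejects) else
    tibble::tibble(row = integer(), id = character(), reason = character())
  if (nrow(rej))
    message(nrow(rej), " row(s) rejected; see attr(x, 'rejects')")
  attr(out, "rejects") <- rej
  out
}

#' Write a participant or estimates table to CSV
#'
#' Full numeric precision is retained so that a write-read cycle is an
#' identity on the package's own tables.
#'
#' @param x A tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}

#' Read a tidy estimates CSV written by [write_table_csv()]
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_estimates <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    participant_id = readr::col_character(),
                    sex = readr::col_character(),
                    age_group = readr::col_character(),
                    method = readr::col_character(),
                    flags = readr::col_character(),
                    .default = readr::col_double()
                  ))
}
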