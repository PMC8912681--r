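#' Method-comparison table against the reference model
#'
#' Assembles the full comparison battery -- Pearson and Lin's concordance
#' correlations with 95% intervals, the regression of each method on the
#' reference, paired t-test, Bland-Altman bias, SD and limits of agreement,
#' and the proportional-bias regression -- for every method in a tidy
#' estimates table against the chosen reference method, for the total sample
#' and optionally for each sex-by-age-group cell.
#'
#' Pairing is per participant: only participants with a non-missing value
#' for both the method and the reference enter a cell.  Cells with fewer
#' than 3 complete pairs are still emitted, carrying an `insufficient-n`
#' flag and missing statistics, so that exclusions stay visible.
#'
#' @param estimates Tidy tibble as produced by [estimate_composition()]:
#'   columns `participant_id`, `sex`, `age_group`, `method`, `fm_kg`,
#'   `ffm_kg`, `pct_fat`.
#' @param value Which estimate column to compare (default `"fm_kg"`).
#' @param reference Method name used as reference (default `"FOURC"`).
#' @param group_by `"total"` for a single all-participants row per method,
#'   or `"sex_age"` for the total row plus one row per sex-by-age-group
#'   cell (5 rows per method in a fully crossed cohort).
#' @param loa_multiplier Limits-of-agreement width in SD units (default 2).
#' @param alpha Two-sided type-1 error for all intervals.
#' @return A tibble, one row per method per group, with an attached
#'   `"ba_points"` attribute holding the per-pair Bland-Altman coordinates
#'   (`method`, `group`, `average`, `difference`) for plotting.
#' @export
comparison_table <- function(estimates, value = "fm_kg",
                             reference = "FOURC",
                             group_by = c("total", "sex_age"),
                             loa_multiplier = 2.0, alpha = 0.05) {
  group_by <- match.arg(group_by)
  stopifnot(value %in% c("fm_kg", "ffm_kg", "pct_fat"))
  needed <- c("participant_id", "sex", "age_group", "method", value)
  missing_cols <- setdiff(needed, names(estimates))
  if (length(missing_cols))
    stop("estimates table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  wide <- estimates |>
    dplyr::select(dplyr::all_of(c("participant_id", "sex", "age_group",
                                  "method", value))) |>
    tidyr::pivot_wider(names_from = "method",
                       values_from = dplyr::all_of(value))
  if (!reference %in% names(wide))
    stop("reference method '", reference, "' absent from estimates",
         call. = FALSE)
  methods <- setdiff(intersect(unique(estimates$method), names(wide)),
                     reference)

  groups <- list(list(label = "total", rows = rep(TRUE, nrow(wide))))
  if (group_by == "sex_age") {
    cells <- unique(wide[, c("sex", "age_group")])
    cells <- cells[order(cells$sex, cells$age_group), ]
    for (i in seq_len(nrow(cells))) {
      groups[[length(groups) + 1L]] <- list(
        label = paste(cells$sex[i], cells$age_group[i], sep = "_"),
        rows = wide$sex == cells$sex[i] & wide$age_group == cells$age_group[i]
      )
    }
  }

  rows <- list()
  pts <- list()
  for (m in methods) {
    for (g in groups) {
      sub <- wide[g$rows, , drop = FALSE]
      ok <- !is.na(sub[[m]]) & !is.na(sub[[reference]])
      x <- sub[[m]][ok]
      y <- sub[[reference]][ok]
      if (length(x) < 3L) {
        rows[[length(rows) + 1L]] <- comparison_row(m, g$label, length(x))
        next
      }
      pr <- pearson_r_ci(x, y, alpha)
      cc <- lins_ccc_ci(x, y, alpha)
      rg <- simple_linear_regression(x, y, alpha)
      ba <- bland_altman(x, y, loa_multiplier)
      pb <- proportional_bias(x, y)
      tt <- paired_t_test(x, y)
      rows[[length(rows) + 1L]] <- comparison_row(
        m, g$label, length(x),
        pearson_r = pr$r, pearson_lo = pr$ci_low, pearson_hi = pr$ci_high,
        slope = rg$slope, slope_lo = rg$slope_ci[1], slope_hi = rg$slope_ci[2],
        intercept = rg$intercept, intercept_lo = rg$intercept_ci[1],
        intercept_hi = rg$intercept_ci[2],
        ccc = cc$ccc, ccc_lo = cc$ci_low, ccc_hi = cc$ci_high,
        ba_bias = ba$bias, ba_sd = ba$sd,
        ba_loa_low = ba$loa_low, ba_loa_high = ba$loa_high,
        prop_slope = pb$slope, prop_intercept = pb$intercept,
        prop_p = pb$p_value,
        paired_t = tt$t, paired_df = tt$df, paired_p = tt$p,
        flag = tt$flag
      )
      pts[[length(pts) + 1L]] <- tibble::tibble(
        method = m, group = g$label,
        average = ba$points$average, difference = ba$points$difference
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "ba_points") <- dplyr::bind_rows(pts)
  out
}

comparison_row <- function(method, group, n,
                           pearson_r = NA_real_, pearson_lo = NA_real_,
                           pearson_hi = NA_real_, slope = NA_real_,
                           slope_lo = NA_real_, slope_hi = NA_real_,
                           intercept = NA_real_, intercept_lo = NA_real_,
                           intercept_hi = NA_real_, ccc = NA_real_,
                           ccc_lo = NA_real_, ccc_hi = NA_real_,
                           ba_bias = NA_real_, ba_sd = NA_real_,
                           ba_loa_low = NA_real_, ba_loa_high = NA_real_,
                           prop_slope = NA_real_,
                           prop_intercept = NA_real_, prop_p = NA_real_,
                           paired_t = NA_real_, paired_df = NA_real_,
                           paired_p = NA_real_, flag = NA_character_) {
  if (n < 3L && is.na(flag)) flag <- "insufficient-n"
  tibble::tibble(
    method = method, group = group, n = as.integer(n),
    pearson_r = pearson_r, pearson_lo = pearson_lo, pearson_hi = pearson_hi,
    slope = slope, slope_lo = slope_lo, slope_hi = slope_hi,
    intercept = intercept, intercept_lo = intercept_lo,
    intercept_hi = intercept_hi,
    ccc = ccc, ccc_lo = ccc_lo, ccc_hi = ccc_hi,
    ba_bias = ba_bias, ba_sd = ba_sd,
    ba_loa_low = ba_loa_low, ba_loa_high = ba_loa_high,
    prop_slope = prop_slope, prop_intercept = prop_intercept,
    prop_p = prop_p,
    paired_t = paired_t, paired_df = paired_df, paired_p = paired_p,
    flag = flag
  )
}
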