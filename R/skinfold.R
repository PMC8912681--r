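#' Mean of replicate skinfold readings at one site
#'
#' The measurement protocol takes the triceps and medial-calf folds twice on
#' each body side with a 0-80 mm caliper and averages the four readings per
#' site.  Fewer replicates (1-3) are accepted -- real records are sometimes
#' incomplete -- and averaged as-is, with a warning below four.
#'
#' @param readings Numeric vector of 1-4 caliper readings in mm, each in
#'   `(0, 80]`.
#' @param warn_incomplete Warn when fewer than 4 replicates are supplied.
#' @return The arithmetic mean in mm.
#' @examples
#' mean_skinfold_site(c(8, 9, 10, 13))  # 10
#' @export
mean_skinfold_site <- function(readings, warn_incomplete = FALSE) {
  readings <- readings[!is.na(readings)]
  if (length(readings) == 0L) stop("no readings", call. = FALSE)
  if (length(readings) > 4L) stop("at most 4 replicate readings per site",
                                  call. = FALSE)
  if (any(readings <= 0 | readings > 80))
    stop("skinfold reading outside the caliper range (0, 80] mm",
         call. = FALSE)
  if (warn_incomplete && length(readings) < 4L)
    warning("fewer than 4 replicate readings at this site", call. = FALSE)
  mean(readings)
}

#' Percent body fat from the two-site Slaughter equations
#'
#' Sex-specific affine equations on the triceps + calf skinfold sum (mm):
#' males `0.735 * (triceps + calf) + 1.0`, females
#' `0.610 * (triceps + calf) + 5.1`.
#'
#' @param sex `"female"` or `"male"` (vectorised, recycled).
#' @param triceps_mm Mean triceps skinfold in mm, non-negative.
#' @param calf_mm Mean calf skinfold in mm, non-negative.
#' @return Percent body fat.
#' @examples
#' slaughter_percent_fat("female", 20, 12.3)  # sum 32.3 mm -> 24.803 %
#' @export
slaughter_percent_fat <- function(sex, triceps_mm, calf_mm) {
  sex <- validate_sex(sex)
  if (any(triceps_mm < 0 | calf_mm < 0, na.rm = TRUE))
    stop("skinfold site means must be non-negative", call. = FALSE)
  s <- triceps_mm + calf_mm
  ifelse(sex == "male", 0.735 * s + 1.0, 0.610 * s + 5.1)
}

# Inverse of the Slaughter equations: the skinfold sum that yields a given
# percent fat.  Used by the cohort simulator to back-solve raw readings.
slaughter_sum_from_percent <- function(sex, pct_fat) {
  sex <- validate_sex(sex)
  ifelse(sex == "male", (pct_fat - 1.0) / 0.735, (pct_fat - 5.1) / 0.610)
}
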