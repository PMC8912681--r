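#' Select the body-volume reading pair from an ADP session
#'
#' The chamber protocol takes body volume twice; if the first two readings
#' differ by more than the agreement threshold (150 mL), a third is taken and
#' the closest pair that meets the threshold is averaged.
#'
#' When two pairs in a three-reading session are equally close and both
#' agree, the pair containing the earliest reading is chosen, which makes the
#' rule deterministic.
#'
#' @param volume_readings_L Numeric vector of 2 or 3 raw body-volume
#'   readings in L, all positive.  `NA`s are dropped first.
#' @param agreement_threshold_L Maximum absolute difference for an agreeing
#'   pair, in L.  Default 0.150 (150 mL).
#' @return The mean of the selected pair, in L.
#' @examples
#' select_body_volume(c(20.000, 20.100))          # 20.05
#' select_body_volume(c(20.000, 20.300, 20.250))  # 20.275
#' @export
select_body_volume <- function(volume_readings_L,
                               agreement_threshold_L = 0.150) {
  v <- volume_readings_L[!is.na(volume_readings_L)]
  if (!length(v) %in% c(2L, 3L))
    stop("2 or 3 volume readings required", call. = FALSE)
  if (any(v <= 0)) stop("volume readings must be positive", call. = FALSE)

  if (length(v) == 2L) {
    if (abs(v[1] - v[2]) <= agreement_threshold_L) return(mean(v))
    stop("third reading required", call. = FALSE)
  }
  pairs <- rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  gaps <- abs(v[pairs[, 1]] - v[pairs[, 2]])
  ok <- gaps <= agreement_threshold_L
  if (!any(ok)) stop("no agreeing pair", call. = FALSE)
  best <- which(ok)[order(gaps[ok], pairs[ok, 1L], pairs[ok, 2L])][1L]
  mean(v[pairs[best, ]])
}

#' Whole-body density
#'
#' @param body_mass_kg Body mass in kg, positive.
#' @param body_volume_L Body volume in L, positive.
#' @return Density in kg/L.
#' @export
body_density <- function(body_mass_kg, body_volume_L) {
  stop_unless(all(body_mass_kg > 0, na.rm = TRUE),
              "body_mass_kg must be positive")
  stop_unless(all(body_volume_L > 0, na.rm = TRUE),
              "body_volume_L must be positive")
  body_mass_kg / body_volume_L
}

#' Percent fat from body density via two-compartment constants
#'
#' Evaluates `%FM = (c1 / Db - c2) * 100`.  The constants may be given
#' directly (e.g. the adult Siri pair 4.95/4.50) or looked up by sex and age
#' from a [load_constants()] table of child-specific values.
#'
#' @param density_kg_per_L Whole-body density in kg/L; a warning is issued
#'   outside the physiologic band (0.9, 1.15).
#' @param sex,age_years Used to resolve the constants band when `c1`/`c2`
#'   are not supplied.
#' @param constants A [load_constants()] object.
#' @param c1,c2 Optional explicit constants overriding the table lookup.
#' @return Percent body fat.
#' @examples
#' adp_percent_fat(1.0, c1 = 4.95, c2 = 4.50)  # 45 %
#' @export
adp_percent_fat <- function(density_kg_per_L, sex = NULL, age_years = NULL,
                            constants = load_constants(),
                            c1 = NULL, c2 = NULL) {
  if (is.null(c1) || is.null(c2)) {
    if (is.null(sex) || is.null(age_years))
      stop("supply either (c1, c2) or (sex, age_years, constants)",
           call. = FALSE)
    cc <- adp_constants(sex, age_years, constants)
    c1 <- cc$c1
    c2 <- cc$c2
  }
  if (any(density_kg_per_L <= 0.9 | density_kg_per_L >= 1.15, na.rm = TRUE))
    warning("body density outside the physiologic band (0.9, 1.15) kg/L",
            call. = FALSE)
  (c1 / density_kg_per_L - c2) * 100
}

# Inverse of the density equation: the whole-body density producing a given
# percent fat under constants (c1, c2).  Used by the cohort simulator.
adp_density_from_percent <- function(pct_fat, c1, c2) {
  c1 / (pct_fat / 100 + c2)
}
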