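#' Four-component model fat mass
#'
#' The reference fat mass combining body volume (ADP), total body water
#' (deuterium dilution), bone mineral content (DXA) and weight:
#'
#' `FM = 2.7474*BV - 0.7145*TBW + 1.4599*BMC/1000 - 2.0503*weight`
#'
#' with BV and TBW in litres, BMC in grams and weight in kg.  BMC enters in
#' grams and is divided by 1000 inside the formula, exactly as arranged
#' above.  TBW is taken in litres by default; set `tbw_in_kg = TRUE` to
#' supply kg and have the water-density conversion (0.99371 kg/L at 36 C)
#' applied internally, a switch intended for sensitivity checks.
#'
#' @param bv_L Body volume in L.
#' @param tbw_L Total body water in L (or kg when `tbw_in_kg = TRUE`).
#' @param bmc_g Bone mineral content in g.
#' @param weight_kg Body weight in kg.
#' @param tbw_in_kg Interpret `tbw_L` as kg and convert to L internally.
#' @param check Validate positivity and warn on implausible density; the
#'   linearity of the map is sometimes exercised on non-physiologic inputs
#'   (e.g. zeros), where `check = FALSE` skips validation.
#' @return Fat mass in kg.
#' @examples
#' fourc_fat_mass(49.1, 26.77, 1900, 51.2)
#' @export
fourc_fat_mass <- function(bv_L, tbw_L, bmc_g, weight_kg,
                           tbw_in_kg = FALSE, check = TRUE) {
  if (tbw_in_kg) tbw_L <- tbw_L / 0.99371
  if (check) {
    if (any(c(bv_L, tbw_L, bmc_g, weight_kg) <= 0, na.rm = TRUE))
      stop("all four-component inputs must be positive", call. = FALSE)
    dens <- weight_kg / bv_L
    if (any(dens <= 0.9 | dens >= 1.15, na.rm = TRUE))
      warning("implied body density outside (0.9, 1.15) kg/L", call. = FALSE)
  }
  2.7474 * bv_L - 0.7145 * tbw_L + 1.4599 * bmc_g / 1000 - 2.0503 * weight_kg
}

# Body volume (L) that makes the four-component model return fm_kg exactly,
# given the other components.  Used by the cohort simulator.
fourc_body_volume <- function(fm_kg, tbw_L, bmc_g, weight_kg) {
  (fm_kg + 0.7145 * tbw_L - 1.4599 * bmc_g / 1000 + 2.0503 * weight_kg) /
    2.7474
}

#' Hydration of fat-free mass
#'
#' Total body water as a percentage of fat-free mass, the quantity reported
#' as "Hydration (%)" alongside four-component results.  Values outside the
#' physiologic band (50, 90) trigger a warning.
#'
#' @param tbw_kg Total body water in kg.
#' @param ffm_kg Fat-free mass in kg, positive.
#' @return Hydration in percent.
#' @export
hydration_percent <- function(tbw_kg, ffm_kg) {
  stop_unless(all(ffm_kg > 0, na.rm = TRUE), "ffm_kg must be positive")
  h <- 100 * tbw_kg / ffm_kg
  if (any(h <= 50 | h >= 90, na.rm = TRUE))
    warning("hydration outside the physiologic band (50, 90) %",
            call. = FALSE)
  h
}
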