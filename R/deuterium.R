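#' Consumed deuterium-oxide dose from bottle weights
#'
#' The dose bottle is weighed four times: empty, after adding the D2O, after
#' adding the tap water, and after the participant drinks.  The consumed dose
#' is the weighed isotope multiplied by the fraction of the bottle content
#' actually drunk:
#' `(bottle_d2o - bottle_empty) * (bottle_d2o_water - bottle_drunk) /
#'  (bottle_d2o_water - bottle_empty)`.
#'
#' @param bottle_empty_g,bottle_d2o_g,bottle_d2o_water_g,bottle_drunk_g
#'   Bottle weights in g at the four stages.
#' @return Consumed D2O dose in g.
#' @examples
#' d2o_dose_g(20, 22.5, 72.5, 20)  # 2.5 g, everything consumed
#' @export
d2o_dose_g <- function(bottle_empty_g, bottle_d2o_g, bottle_d2o_water_g,
                       bottle_drunk_g) {
  denom <- bottle_d2o_water_g - bottle_empty_g
  if (any(denom <= 0, na.rm = TRUE))
    stop("empty bottle record", call. = FALSE)
  (bottle_d2o_g - bottle_empty_g) *
    (bottle_d2o_water_g - bottle_drunk_g) / denom
}

#' Outlier screening flags for a deuterium dosing session
#'
#' A session is unusable for total-body-water estimation when any of three
#' printed rules trips: the bottle weighs less after drinking than empty
#' (`IMPOSSIBLE_BOTTLE_WEIGHT`), more than 1 g of dose water remains
#' (`RESIDUAL_GT_1G`), or the weighed isotope deviates from the target of
#' 0.05 g per kg body weight by more than 15 percent relative
#' (`DOSE_OFF_TARGET`).
#'
#' @inheritParams d2o_dose_g
#' @param weight_kg Participant body weight in kg.
#' @param target_dose_g_per_kg Target dose, g of D2O per kg of body weight.
#' @return Character vector of flags; `character(0)` means a usable session.
#' @export
dose_outlier_flags <- function(bottle_empty_g, bottle_d2o_g, bottle_drunk_g,
                               weight_kg, target_dose_g_per_kg = 0.05) {
  flags <- character(0)
  if (bottle_drunk_g < bottle_empty_g)
    flags <- c(flags, "IMPOSSIBLE_BOTTLE_WEIGHT")
  if (bottle_drunk_g - bottle_empty_g > 1)
    flags <- c(flags, "RESIDUAL_GT_1G")
  target <- target_dose_g_per_kg * weight_kg
  weighed <- bottle_d2o_g - bottle_empty_g
  if (abs(weighed - target) / target > 0.15)
    flags <- c(flags, "DOSE_OFF_TARGET")
  flags
}

#' Total body water from deuterium dilution at plateau
#'
#' Implements the plateau dilution formula: with the consumed dose in g, the
#' atom-percent concentration of the supplied isotope, and the post- minus
#' pre-dose saliva enrichment difference,
#' `TBW(kg) = dose * (concentration/20) * 18.02 / (APpost - APpre) * 1e-3 / 1.04`
#' where 20 and 18.02 are the molecular weights of D2O and water, 1e-3
#' converts g to kg and 1.04 corrects for proton exchange with non-aqueous
#' hydrogen.  `TBW(L) = TBW(kg) / 0.99371`, the density of water at 36 C.
#'
#' @param dose_g Consumed D2O dose in g, positive.
#' @param ap_post_pct,ap_pre_pct Post- and pre-dose saliva enrichment, atom
#'   percent.
#' @param concentration_pct Atom percent of the supplied isotope (99.9).
#' @return A list with `tbw_kg` and `tbw_L`.
#' @export
tbw_from_dilution <- function(dose_g, ap_post_pct, ap_pre_pct,
                              concentration_pct = 99.9) {
  if (any(dose_g <= 0, na.rm = TRUE)) stop("dose must be positive",
                                           call. = FALSE)
  dap <- ap_post_pct - ap_pre_pct
  if (any(dap <= 0, na.rm = TRUE)) stop("no enrichment", call. = FALSE)
  tbw_kg <- dose_g * (concentration_pct / 20) * 18.02 / dap * 1e-3 / 1.04
  list(tbw_kg = tbw_kg, tbw_L = tbw_kg / 0.99371)
}

# Enrichment difference (atom %) that yields a given TBW for a given dose:
# exact inverse of tbw_from_dilution, used by the cohort simulator.
dilution_delta_ap <- function(dose_g, tbw_kg, concentration_pct = 99.9) {
  dose_g * (concentration_pct / 20) * 18.02 * 1e-3 / 1.04 / tbw_kg
}

#' Fat-free mass from total body water via a hydration coefficient
#'
#' Divides TBW (kg) by the assumed TBW/FFM hydration fraction for the
#' participant's sex and age band.
#'
#' @param tbw_kg Total body water in kg, positive.
#' @inheritParams hydration_coefficient
#' @param coefficient Optional explicit hydration fraction overriding the
#'   table lookup.
#' @return Fat-free mass in kg.
#' @export
ffm_from_tbw <- function(tbw_kg, sex = NULL, age_years = NULL,
                         constants = load_constants(), coefficient = NULL) {
  if (any(tbw_kg <= 0, na.rm = TRUE))
    stop("tbw_kg must be positive", call. = FALSE)
  if (is.null(coefficient))
    coefficient <- hydration_coefficient(sex, age_years, constants)
  tbw_kg / coefficient
}
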