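#' Body mass index
#'
#' Weight in kilograms divided by the square of height in metres.  Height is
#' taken in centimetres, as measured on a stadiometer.
#'
#' @param weight_kg Body weight in kg, positive.
#' @param height_cm Standing height in cm, positive.
#' @return BMI in kg/m^2.
#' @examples
#' bmi(50, 200)  # 12.5
#' @export
bmi <- function(weight_kg, height_cm) {
  stop_unless(all(weight_kg > 0), "weight_kg must be positive")
  stop_unless(all(height_cm > 0), "height_cm must be positive")
  weight_kg / (height_cm / 100)^2
}

#' Fat mass from percent fat and body weight
#'
#' @param pct_fat Percent body fat, in `[0, 100]`.
#' @param weight_kg Body weight in kg, positive.
#' @return Fat mass in kg.
#' @export
fat_mass_from_percent <- function(pct_fat, weight_kg) {
  stop_unless(all(pct_fat >= 0 & pct_fat <= 100, na.rm = TRUE),
              "pct_fat must lie in [0, 100]")
  stop_unless(all(weight_kg > 0), "weight_kg must be positive")
  pct_fat / 100 * weight_kg
}

#' Percent fat from fat mass and body weight
#'
#' @param fm_kg Fat mass in kg.
#' @param weight_kg Body weight in kg, positive.
#' @return Percent body fat.
#' @export
percent_fat <- function(fm_kg, weight_kg) {
  stop_unless(all(weight_kg > 0), "weight_kg must be positive")
  100 * fm_kg / weight_kg
}

#' Fat-free mass as the weight remainder
#'
#' FFM = weight - FM, the identity used wherever a method reports only fat
#' mass (skinfolds, ADP, deuterium dilution, the four-component model).
#'
#' @param weight_kg Body weight in kg, positive.
#' @param fm_kg Fat mass in kg.
#' @return Fat-free mass in kg (raw difference; not clamped).
#' @export
ffm_from_weight_fm <- function(weight_kg, fm_kg) {
  stop_unless(all(weight_kg > 0), "weight_kg must be positive")
  weight_kg - fm_kg
}

stop_unless <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# Age-group labels used throughout reporting: children are 4-10 years,
# adolescents 11-18 (half-open split at the 11th birthday).
age_group_of <- function(age_years) {
  ifelse(age_years < 11, "children", "adolescents")
}

check_age_range <- function(age_years) {
  out <- age_years < 4 | age_years >= 19
  if (any(out, na.rm = TRUE))
    warning("age_years outside the supported pediatric range [4, 19)",
            call. = FALSE)
  invisible(age_years)
}
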