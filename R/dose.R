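#' Active dose contained in an applied formulation mass
#'
#' Dose arithmetic for semisolid products labelled by strength:
#' applying `mass_mg` of a `strength_pct` % w/w formulation delivers
#' `mass_mg * 1000 * strength_pct / 100` micrograms of active ingredient
#' (500 mg of a 0.25 % product carries 1250 ug).
#'
#' @param formulation_mass_mg applied formulation mass (mg).
#' @param strength_pct label strength (% w/w).
#' @return active dose (ug).
#' @examples
#' api_dose(500, 0.25)  # 1250
#' @export
api_dose <- function(formulation_mass_mg = 500, strength_pct = 0.25) {
  check_positive(formulation_mass_mg, "formulation_mass_mg")
  check_positive(strength_pct, "strength_pct")
  formulation_mass_mg * 1000 * strength_pct / 100
}
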