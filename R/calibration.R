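#' Default per-diet calibration of the synthetic trial generator
#'
#' One row per experimental diet, holding the "true" generative parameters
#' targeted by the recovery tests: dietary composition, marker-kinetics
#' parameters (pool volumes, fractional passage rates, the negative
#' quadratic term of the solid-phase washout), and the treatment-level
#' means of the mineral-balance and rumen-chemistry variables.
#'
#' The three diets contrast an early harvested low-NDF grass silage
#' (`Fibre-`) against a late harvested high-NDF silage fed either with a
#' protein-balancing concentrate (`Fibre+CP`) or not (`Fibre+`), at a fixed
#' 80:20 forage-to-concentrate ratio. Quantities that are printed in the
#' source study (silage NDF, dietary Mg of 2.3 g/kg DM, urinary Mg
#' concentrations of 2.07/4.38/5.88 mmol/l, the 11.8 l/kg NDFi slope of
#' rumen liquid volume, the 0.10 g/day/l and 1.32 g/day/kg slopes of Mg
#' absorption) are encoded directly; treatment means that were not printed
#' (dry-matter intake, solid pool size, milk yield, urine volume, water
#' intake) are plausible values for lactating dairy cows at this production
#' level and are flagged as assumed in the attached `assumed` attribute.
#'
#' The two Mg-absorption slopes are encoded jointly: absorption is generated
#' as `mg_abs_intercept + mg_abs_vol_slope * Vol_L + mg_abs_ndfi_slope *
#' NDFi`, with the direct NDFi slope defaulting to `1.32 - 0.10 * 11.8 =
#' 0.14` g/day per kg NDFi so that both marginal regression slopes hold.
#'
#' @section Units:
#' Dietary concentrations in g/kg DM; intakes in kg DM/day; volumes in
#' litres (liquid) or kg DM (solid); fractional passage rates per hour; the
#' quadratic washout coefficient per hour squared (non-positive); rumen
#' liquid minerals in mmol/l; solid-phase minerals in g/kg DM; urine
#' concentrations in mmol/l; milk concentrations in g/kg; volumes/yields in
#' l/day or kg/day.
#'
#' @return A tibble with one row per diet and an `assumed` attribute naming
#'   the placeholder columns.
#' @seealso [trial_config()], [simulate_trial()]
#' @export
#' @examples
#' default_calibration()
default_calibration <- function() {
  cal <- tibble(
    diet = diet_levels(),
    ndf_diet = c(333, 515, 518),
    dmi_mean = c(20.8, 20.3, 19.8),
    mg_g_kg = c(2.3, 2.3, 2.3),
    k_g_kg = c(27.9, 26.8, 26.0),
    na_g_kg = c(2.2, 2.0, 1.9),
    ca_g_kg = c(6.1, 6.1, 6.1),
    p_g_kg = c(3.7, 3.7, 3.7),
    true_frac_kp_liquid = c(0.115, 0.105, 0.105),
    true_frac_kp_solid = c(0.035, 0.035, 0.035),
    quad_coeff_solid = c(-0.0006, -0.0006, -0.0006),
    vol_liquid_intercept = c(16.3, 16.3, 16.3),
    vol_liquid_ndfi_slope = c(11.8, 11.8, 11.8),
    vol_liquid_resid_sd = c(15, 15, 15),
    vol_solid_mean = c(7.2, 11.5, 12.0),
    rumen_ph_mean = c(5.95, 6.55, 6.61),
    liquid_mg_mmol_l = c(3.6, 1.2, 1.2),
    liquid_k_mmol_l = c(46, 40, 38.5),
    liquid_na_mmol_l = c(100, 112, 115),
    solid_mg_g_kg = c(1.25, 1.35, 1.00),
    solid_k_g_kg = c(10.5, 10.0, 10.0),
    mg_abs_intercept = c(-5.5, -5.5, -5.5),
    mg_abs_vol_slope = c(0.10, 0.10, 0.10),
    mg_abs_ndfi_slope = c(0.14, 0.14, 0.14),
    mg_abs_sd = c(1.8, 1.8, 1.8),
    urine_mg_conc_mean = c(2.07, 4.38, 5.88),
    urine_volume_mean = c(28, 22, 18),
    milk_mg_conc_mean = c(0.105, 0.105, 0.105),
    milk_yield_mean = c(29.5, 29.5, 27.0),
    water_intake_mean = c(94, 94.5, 86),
    k_absorbability_pct = c(94.0, 91.5, 91.0),
    na_absorbability_pct = c(85.4, 76.3, 72.5),
    ca_absorbability_pct = c(30, 30, 30),
    p_absorbability_pct = c(40, 40, 40),
    urine_k_mmol_l = c(460, 490, 560),
    urine_na_mmol_l = c(45, 47, 48),
    urine_ca_g_d = c(0.6, 0.6, 0.6),
    urine_p_g_d = c(0.25, 0.25, 0.25),
    milk_k_g_kg = c(1.55, 1.55, 1.55),
    milk_na_g_kg = c(0.40, 0.40, 0.40),
    milk_ca_g_kg = c(1.15, 1.15, 1.15),
    milk_p_g_kg = c(0.95, 0.95, 0.95)
  )
  attr(cal, "assumed") <- c(
    "ndf_diet", "dmi_mean", "vol_solid_mean", "milk_yield_mean",
    "urine_volume_mean", "water_intake_mean", "vol_liquid_intercept",
    "true_frac_kp_liquid", "true_frac_kp_solid", "quad_coeff_solid",
    "mg_abs_sd", "vol_liquid_resid_sd"
  )
  validate_calibration(cal)
  cal
}

#' Zero the noise parameters held in a calibration table
#'
#' Two noise SDs live in the calibration rather than the configuration
#' because they are diet-specific in general: the residual SD of liquid
#' volume around its NDF-intake line (`vol_liquid_resid_sd`) and the
#' residual SD of Mg absorption (`mg_abs_sd`). For exact-identifiability
#' checks, pair this with [noiseless_config()].
#'
#' @param calibration A calibration tibble.
#' @return The calibration with `vol_liquid_resid_sd` and `mg_abs_sd` set
#'   to zero.
#' @export
noiseless_calibration <- function(calibration = default_calibration()) {
  calibration$vol_liquid_resid_sd <- 0
  calibration$mg_abs_sd <- 0
  calibration
}

#' Diet labels of the crossover, in design order
#' @return Character vector of the three diet labels.
#' @export
diet_levels <- function() c("Fibre-", "Fibre+CP", "Fibre+")

#' Validate a calibration table
#'
#' Checks positivity of rates and volumes, the non-positive quadratic
#' washout coefficient, and the physiological range of dietary mineral
#' concentrations (0--100 g/kg DM).
#'
#' @param calibration A calibration tibble as returned by
#'   [default_calibration()] (possibly modified).
#' @return `calibration`, invisibly, or an error.
#' @export
validate_calibration <- function(calibration) {
  req <- c(
    "diet", "ndf_diet", "dmi_mean", "true_frac_kp_liquid",
    "true_frac_kp_solid", "quad_coeff_solid", "vol_liquid_intercept",
    "vol_liquid_ndfi_slope", "vol_solid_mean"
  )
  missing_cols <- setdiff(req, names(calibration))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "Calibration is missing column(s): %s", paste(missing_cols, collapse = ", ")
    ))
  }
  if (anyDuplicated(calibration$diet)) abort("Calibration diets must be unique.")
  pos <- c(
    "ndf_diet", "dmi_mean", "true_frac_kp_liquid", "true_frac_kp_solid",
    "vol_solid_mean", "urine_volume_mean", "milk_yield_mean",
    "water_intake_mean"
  )
  for (nm in intersect(pos, names(calibration))) {
    if (any(!is.finite(calibration[[nm]]) | calibration[[nm]] <= 0)) {
      abort(sprintf("Calibration column `%s` must be strictly positive.", nm))
    }
  }
  if (any(calibration$quad_coeff_solid > 0)) {
    abort("`quad_coeff_solid` must be <= 0 (decelerating washout).")
  }
  for (nm in intersect(c("mg_g_kg", "k_g_kg", "na_g_kg", "ca_g_kg", "p_g_kg"),
                       names(calibration))) {
    if (any(calibration[[nm]] < 0 | calibration[[nm]] > 100)) {
      abort(sprintf(
        "Calibration column `%s` outside the physiological 0-100 g/kg DM range.", nm
      ))
    }
  }
  invisible(calibration)
}
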