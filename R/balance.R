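#' Derive apparent absorption, absorbability and retention
#'
#' Adds the derived balance quantities to a long balance table, one row per
#' cow x period x element:
#' * `absorption_g_d = intake_g_d - faecal_g_d` (apparent absorption;
#'   endogenous faecal losses are not separated, so negative values are
#'   possible and flagged rather than removed);
#' * `absorbability_pct = 100 * absorption / intake` (undefined when
#'   intake is zero, reported as `NA` with a warning);
#' * `retention_g_d = absorption - urine_g_d - milk_g_d`.
#'
#' All three are exact arithmetic identities of the input columns.
#'
#' @param records A balance tibble with `intake_g_d`, `faecal_g_d`,
#'   `urine_g_d`, `milk_g_d` (plus identifiers), e.g.
#'   `simulate_trial(...)$balance`.
#' @return The input with `absorption_g_d`, `absorbability_pct`,
#'   `retention_g_d` and `negative_absorption` appended.
#' @export
#' @examples
#' trial <- simulate_trial(trial_config(seed = 4))
#' derive_balance(trial$balance)
derive_balance <- function(records) {
  req <- c("intake_g_d", "faecal_g_d", "urine_g_d", "milk_g_d")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols) > 0) {
    abort(sprintf("`records` is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (any(records$intake_g_d < 0 | records$faecal_g_d < 0 |
            records$urine_g_d < 0 | records$milk_g_d < 0, na.rm = TRUE)) {
    abort("Balance masses must be non-negative.")
  }
  out <- records |>
    dplyr::mutate(
      absorption_g_d = .data$intake_g_d - .data$faecal_g_d,
      absorbability_pct = dplyr::if_else(
        .data$intake_g_d > 0,
        100 * .data$absorption_g_d / .data$intake_g_d,
        NA_real_
      ),
      retention_g_d = .data$absorption_g_d - .data$urine_g_d - .data$milk_g_d,
      negative_absorption = .data$absorption_g_d < 0
    )
  if (any(out$intake_g_d == 0)) {
    warn("Records with zero intake: absorbability reported as missing.")
  }
  if (any(out$negative_absorption)) {
    warn(sprintf("%d record(s) with negative apparent absorption (faecal > intake).",
                 sum(out$negative_absorption)))
  }
  out
}

#' Magnesium absorbed per gram of potassium absorbed
#'
#' The ratio of apparent Mg absorption to apparent K absorption for the
#' same cow x period -- the quantity in which the fibre-driven depression
#' of Mg absorption shows up after normalising for the K supply. Undefined
#' (with a warning) when K absorption is not positive.
#'
#' @param derived A derived balance table from [derive_balance()]
#'   containing `Mg` and `K` rows.
#' @return A tibble per cow x period: `cow_id`, `period`, `diet`,
#'   `mg_absorption_g_d`, `k_absorption_g_d`, `mg_per_k_absorbed` (g/g).
#' @export
mg_per_k_absorbed <- function(derived) {
  need <- c("cow_id", "period", "diet", "element", "absorption_g_d")
  missing_cols <- setdiff(need, names(derived))
  if (length(missing_cols) > 0) {
    abort(sprintf("`derived` is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  wide <- derived |>
    dplyr::filter(.data$element %in% c("Mg", "K")) |>
    dplyr::select("cow_id", "period", "diet", "element", "absorption_g_d") |>
    tidyr::pivot_wider(names_from = "element", values_from = "absorption_g_d")
  if (!all(c("Mg", "K") %in% names(wide))) {
    abort("Both Mg and K rows are required.")
  }
  bad_k <- !is.na(wide$K) & wide$K <= 0
  if (any(bad_k)) {
    warn(sprintf("%d record(s) with non-positive K absorption: ratio set to NA.",
                 sum(bad_k)))
  }
  wide |>
    dplyr::mutate(
      mg_per_k_absorbed = dplyr::if_else(.data$K > 0, .data$Mg / .data$K,
                                         NA_real_)
    ) |>
    dplyr::rename(mg_absorption_g_d = "Mg", k_absorption_g_d = "K")
}

#' Rumen magnesium solubility
#'
#' The share of total rumen Mg residing in the liquid phase, computed from
#' the rumen chemistry and the marker-dilution pool estimates of the same
#' cow x diet:
#' liquid pool (g) = liquid Mg (mmol/l) x 24.305 (mg/mmol) x Vol_L (l) /
#' 1000; solid pool (g) = solid Mg (g/kg DM) x Vol_S (kg DM); solubility =
#' 100 x liquid / (liquid + solid). Undefined (with a warning) when both
#' pools are zero.
#'
#' @param chemistry A rumen chemistry tibble (`cow_id`, `diet`,
#'   `liquid_mg_mmol_l`, `solid_mg_g_kg`), e.g. `simulate_trial(...)$rumen`.
#' @param kinetics Kinetics estimates covering both phases, from
#'   [estimate_kinetics()] or [summarize_kinetics()].
#' @return A tibble per cow x diet: the two pools (g) and
#'   `mg_solubility_pct`.
#' @export
mg_solubility <- function(chemistry, kinetics) {
  vols <- kinetics |>
    dplyr::select("cow_id", "diet", "phase", "volume") |>
    tidyr::pivot_wider(names_from = "phase", values_from = "volume")
  if (!all(c("liquid", "solid") %in% names(vols))) {
    abort("`kinetics` must contain both liquid and solid phase estimates.")
  }
  if (any(vols$liquid <= 0 | vols$solid <= 0, na.rm = TRUE)) {
    abort("Pool volumes must be positive.")
  }
  out <- chemistry |>
    dplyr::inner_join(vols, by = c("cow_id", "diet")) |>
    dplyr::mutate(
      liquid_mg_pool_g = .data$liquid_mg_mmol_l * .MOLAR_MASS[["Mg"]] *
        .data$liquid / 1000,
      solid_mg_pool_g = .data$solid_mg_g_kg * .data$solid,
      total = .data$liquid_mg_pool_g + .data$solid_mg_pool_g,
      mg_solubility_pct = dplyr::if_else(
        .data$total > 0, 100 * .data$liquid_mg_pool_g / .data$total, NA_real_
      )
    ) |>
    dplyr::select(
      "cow_id", "period", "diet", "liquid_mg_pool_g", "solid_mg_pool_g",
      "mg_solubility_pct"
    )
  if (any(is.na(out$mg_solubility_pct))) {
    warn("Cow x diet cell(s) with both Mg pools zero: solubility undefined.")
  }
  out
}
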