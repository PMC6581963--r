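#' @title Synthetic-trial generator
#' @description
#' The generator draws a complete marker-dilution and mineral-balance trial
#' with known ground truth. The latent per-cow-by-period state (intake,
#' NDF intake, true pool volumes, realised passage rates, water intake) is
#' drawn once from a seed derived from the configuration, so
#' [generate_marker_profiles()] and [generate_balance()] are mutually
#' consistent: the liquid volume that shapes a cow's washout curve is the
#' same volume that drives her magnesium absorption.
#' @name synthetic-trial
NULL

# Deterministic sub-seeds so each generator stage is reproducible on its
# own and independent of call order. Kept below 2^31 - 1.
sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% (.Machine$integer.max - 1L))
}

# Latent cow and cow-by-period state shared by profiles and balance.
# Seeded by config$seed + 1: identical for every stage that needs it.
generate_states <- function(design, calibration, config) {
  validate_calibration(calibration)
  cows <- dplyr::distinct(design, .data$cow_id, .data$cannulated, .data$bw_kg)
  cells <- dplyr::left_join(design, calibration, by = "diet")

  withr::with_seed(sub_seed(config$seed, 1), {
    cow_re <- tibble(
      cow_id = cows$cow_id,
      a_liq = rnorm(nrow(cows), 0, config$cow_re_sd),
      a_sol = rnorm(nrow(cows), 0, config$cow_re_sd),
      dmi_dev = rnorm(nrow(cows), 0, config$cow_dmi_sd),
      mg_dev = rnorm(nrow(cows), 0, config$cow_mg_abs_sd)
    )
    st <- dplyr::left_join(cells, cow_re, by = "cow_id")
    n <- nrow(st)
    z_kp <- rnorm(n)
    rho <- config$water_kp_cor
    st <- st |>
      dplyr::mutate(
        dmi_kg_d = (.data$dmi_mean + .data$dmi_dev) *
          (1 + config$balance_cv * rnorm(n)),
        ndf_intake_kg_d = .data$dmi_kg_d * .data$ndf_diet / 1000,
        kp_liquid = .data$true_frac_kp_liquid * (1 + config$kp_jitter_cv * z_kp),
        kp_solid = .data$true_frac_kp_solid *
          (1 + config$kp_jitter_cv * rnorm(n)),
        vol_liquid = (.data$vol_liquid_intercept +
                        .data$vol_liquid_ndfi_slope * .data$ndf_intake_kg_d +
                        rnorm(n, 0, .data$vol_liquid_resid_sd)) *
          exp(-.data$a_liq),
        vol_solid = .data$vol_solid_mean * (1 + config$balance_cv * rnorm(n)) *
          exp(-.data$a_sol),
        water_l_d = .data$water_intake_mean *
          (1 + config$balance_cv * (rho * z_kp + sqrt(1 - rho^2) * rnorm(n)))
      )
  })

  bad <- with(st, !is.finite(vol_liquid) | vol_liquid <= 0 |
                !is.finite(vol_solid) | vol_solid <= 0 |
                kp_liquid <= 0 | kp_solid <= 0 | dmi_kg_d <= 0)
  if (any(bad)) {
    abort(sprintf(
      "Generated non-positive volume, rate or intake for %d cell(s); check the calibration.",
      sum(bad)
    ))
  }
  st
}

#' Generate pulse-dose marker washout profiles
#'
#' For every cannulated cow x period, emits a liquid-phase Co curve
#' (single-pool exponential washout: `log C(t) = log(D_Co / Vol_L) - k_L t`)
#' and a solid-phase Yb curve with a decelerating quadratic term
#' (`log C(t) = log(D_Yb / Vol_S) + b t + c t^2`, `c <= 0`), sampled at 1,
#' 2, 3, 5, 7, 10, 16 and 23 h after dosing plus a pre-dose record at t = 0
#' with concentration 0 (no marker background). Per-cow intercept effects
#' enter through the true volumes; residual log-concentration noise has SD
#' `config$noise_log_conc_sd`.
#'
#' @param design A design from [generate_design()].
#' @param calibration Per-diet calibration, see [default_calibration()].
#' @param config The [trial_config()] used for the design.
#' @return A tibble: `cow_id`, `period`, `diet`, `phase` (liquid/solid),
#'   `time_h`, `conc`, `conc_units` (g_per_l or g_per_kg_dm), `dose_g`
#'   (elemental marker mass).
#' @export
generate_marker_profiles <- function(design,
                                     calibration = default_calibration(),
                                     config = trial_config()) {
  st <- generate_states(design, calibration, config) |>
    dplyr::filter(.data$cannulated)
  d_co <- config$dose_co_edta_g * config$co_mass_fraction
  d_yb <- config$dose_yb_ndf_g * config$yb_mass_fraction
  tt <- .SAMPLING_HOURS

  withr::with_seed(sub_seed(config$seed, 2), {
    prof <- purrr::pmap(
      list(st$cow_id, st$period, st$diet, st$vol_liquid, st$vol_solid,
           st$kp_liquid, st$kp_solid, st$quad_coeff_solid),
      function(cow_id, period, diet, vol_l, vol_s, kp_l, kp_s, c_sol) {
        # solid linear term chosen so the steepest descending tangent over
        # the 1-23 h window (attained at 23 h for c < 0) equals kp_s
        b_sol <- -kp_s - 2 * c_sol * max(tt)
        log_liq <- log(d_co / vol_l) - kp_l * tt +
          rnorm(length(tt), 0, config$noise_log_conc_sd)
        log_sol <- log(d_yb / vol_s) + b_sol * tt + c_sol * tt^2 +
          rnorm(length(tt), 0, config$noise_log_conc_sd)
        tibble(
          cow_id = cow_id, period = period, diet = diet,
          phase = rep(c("liquid", "solid"), each = length(tt) + 1L),
          time_h = rep(c(0, tt), 2L),
          conc = c(0, exp(log_liq), 0, exp(log_sol)),
          conc_units = rep(c("g_per_l", "g_per_kg_dm"), each = length(tt) + 1L),
          dose_g = rep(c(d_co, d_yb), each = length(tt) + 1L)
        )
      }
    ) |> purrr::list_rbind()
  })
  dplyr::arrange(prof, .data$phase, .data$cow_id, .data$period, .data$time_h)
}

# one bounded-resample draw of the excretion triplet for a record;
# returns c(faecal, urine, milk) or NULL if max_resample exceeded
draw_nonneg <- function(draw_fn, max_resample) {
  for (i in seq_len(max_resample + 1L)) {
    x <- draw_fn()
    if (all(x >= 0)) return(x)
  }
  NULL
}

#' Generate mineral-balance and rumen-chemistry records
#'
#' Magnesium absorption is generated from the same latent liquid volume
#' that shapes the cow's marker curve:
#' `absorption = intercept + vol_slope * Vol_L + ndfi_slope * NDFi + cow
#' effect + noise`, with faecal Mg defined by conservation as
#' `intake - absorption`. Urinary excretion is urine volume times molar
#' concentration; milk excretion is yield times concentration. K, Na, Ca
#' and P follow the analogous structure with faecal output generated from a
#' diet-level apparent absorbability. Records with a negative generated
#' excretion are redrawn up to `config$max_resample` times, then the
#' generator aborts.
#'
#' @inheritParams generate_marker_profiles
#' @return A list with elements `balance` (one row per cow x period x
#'   element: intake and the faecal, urinary and milk routes, plus
#'   covariates) and `rumen` (pH and mineral concentrations of the liquid
#'   and solid phase per cow x period).
#' @export
generate_balance <- function(design,
                             calibration = default_calibration(),
                             config = trial_config()) {
  st <- generate_states(design, calibration, config)
  cv <- config$balance_cv
  elements <- c("Mg", "K", "Na", "Ca", "P")

  withr::with_seed(sub_seed(config$seed, 3), {
    records <- purrr::map(seq_len(nrow(st)), function(i) {
      s <- st[i, ]
      urine_vol <- s$urine_volume_mean * (1 + cv * rnorm(1))
      milk_yield <- s$milk_yield_mean * (1 + cv * rnorm(1))
      if (urine_vol <= 0 || milk_yield <= 0) {
        abort("Generated non-positive urine volume or milk yield; check the calibration.")
      }

      conc <- list(
        g_kg = c(Mg = s$mg_g_kg, K = s$k_g_kg, Na = s$na_g_kg,
                 Ca = s$ca_g_kg, P = s$p_g_kg),
        absb = c(K = s$k_absorbability_pct, Na = s$na_absorbability_pct,
                 Ca = s$ca_absorbability_pct, P = s$p_absorbability_pct),
        urine_mmol = c(Mg = s$urine_mg_conc_mean, K = s$urine_k_mmol_l,
                       Na = s$urine_na_mmol_l),
        urine_g_d = c(Ca = s$urine_ca_g_d, P = s$urine_p_g_d),
        milk_g_kg = c(Mg = s$milk_mg_conc_mean, K = s$milk_k_g_kg,
                      Na = s$milk_na_g_kg, Ca = s$milk_ca_g_kg,
                      P = s$milk_p_g_kg)
      )

      rows <- purrr::map(elements, function(el) {
        intake <- s$dmi_kg_d * conc$g_kg[[el]]
        trip <- draw_nonneg(function() {
          if (el == "Mg") {
            absorption <- s$mg_abs_intercept +
              s$mg_abs_vol_slope * s$vol_liquid +
              s$mg_abs_ndfi_slope * s$ndf_intake_kg_d +
              s$mg_dev + rnorm(1, 0, s$mg_abs_sd)
            faecal <- intake - absorption
          } else {
            faecal <- intake * (1 - conc$absb[[el]] / 100) * (1 + cv * rnorm(1))
          }
          urine <- if (el %in% names(conc$urine_mmol)) {
            urine_vol * conc$urine_mmol[[el]] * (1 + cv * rnorm(1)) *
              .MOLAR_MASS[[el]] / 1000
          } else {
            conc$urine_g_d[[el]] * (1 + cv * rnorm(1))
          }
          milk <- milk_yield * conc$milk_g_kg[[el]] * (1 + cv * rnorm(1))
          c(faecal, urine, milk)
        }, config$max_resample)
        if (is.null(trip)) {
          abort(sprintf(
            "Could not draw non-negative excretions for %s (cow %s, period %d) within %d resamples.",
            el, s$cow_id, s$period, config$max_resample
          ))
        }
        tibble(
          cow_id = s$cow_id, period = s$period, diet = s$diet,
          bw_kg = s$bw_kg, dmi_kg_d = s$dmi_kg_d,
          ndf_intake_kg_d = s$ndf_intake_kg_d, water_l_d = s$water_l_d,
          element = el, intake_g_d = intake, faecal_g_d = trip[1],
          urine_g_d = trip[2], milk_g_d = trip[3]
        )
      }) |> purrr::list_rbind()

      chem <- tibble(
        cow_id = s$cow_id, period = s$period, diet = s$diet,
        ph = min(13.9, max(0.1, s$rumen_ph_mean + rnorm(1, 0, config$rumen_ph_sd))),
        liquid_mg_mmol_l = s$liquid_mg_mmol_l * (1 + cv * rnorm(1)),
        liquid_k_mmol_l = s$liquid_k_mmol_l * (1 + cv * rnorm(1)),
        liquid_na_mmol_l = s$liquid_na_mmol_l * (1 + cv * rnorm(1)),
        solid_mg_g_kg = s$solid_mg_g_kg * (1 + cv * rnorm(1)),
        solid_k_g_kg = s$solid_k_g_kg * (1 + cv * rnorm(1))
      )
      list(balance = rows, rumen = chem)
    })
  })

  list(
    balance = purrr::list_rbind(purrr::map(records, "balance")),
    rumen = purrr::list_rbind(purrr::map(records, "rumen"))
  )
}

#' Simulate a complete trial
#'
#' Runs [generate_design()], [generate_marker_profiles()] and
#' [generate_balance()] and bundles the outputs together with the ground
#' truth (the latent per-cell volumes, passage rates and true Mg
#' absorption) used to generate them.
#'
#' @inheritParams generate_marker_profiles
#' @return An object of class `rumen_trial`: a list with `design`,
#'   `profiles`, `balance`, `rumen`, `truth`, and the `config` and
#'   `calibration` that produced them.
#' @export
#' @examples
#' trial <- simulate_trial(trial_config(seed = 3))
#' trial$truth
simulate_trial <- function(config = trial_config(),
                           calibration = default_calibration()) {
  validate_trial_config(config)
  validate_calibration(calibration)
  design <- generate_design(config)
  profiles <- generate_marker_profiles(design, calibration, config)
  bal <- generate_balance(design, calibration, config)
  st <- generate_states(design, calibration, config)
  truth <- st |>
    dplyr::mutate(
      mg_abs_expected = .data$mg_abs_intercept +
        .data$mg_abs_vol_slope * .data$vol_liquid +
        .data$mg_abs_ndfi_slope * .data$ndf_intake_kg_d + .data$mg_dev
    ) |>
    dplyr::select(
      "cow_id", "period", "diet", "cannulated", "bw_kg", "dmi_kg_d",
      "ndf_intake_kg_d", "water_l_d", "vol_liquid", "vol_solid",
      "kp_liquid", "kp_solid", "quad_coeff_solid", "mg_abs_expected"
    )
  structure(
    list(
      design = design, profiles = profiles, balance = bal$balance,
      rumen = bal$rumen, truth = truth,
      config = config, calibration = calibration
    ),
    class = "rumen_trial"
  )
}

#' @export
print.rumen_trial <- function(x, ...) {
  cat("<rumen_trial>\n")
  cat(sprintf(
    "  %d cows x %d periods (seed %d): %d marker samples, %d balance rows\n",
    x$config$n_cows, x$config$n_periods, x$config$seed,
    nrow(x$profiles), nrow(x$balance)
  ))
  invisible(x)
}
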