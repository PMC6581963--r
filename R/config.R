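#' Trial configuration
#'
#' Bundles the design constants and noise parameters of a simulated
#' marker-dilution / mineral-balance crossover trial. The defaults describe
#' the study conditions emulated by the generator: six lactating cows, four
#' of them ruminally cannulated, assigned to three diets over three periods
#' as two stacked 3x3 Latin squares.
#'
#' @param n_cows Number of cows (must be a multiple of `n_diets`).
#' @param n_cannulated Number of cannulated cows with marker profiles
#'   (`<= n_cows`).
#' @param n_diets,n_periods Crossover dimensions; must be equal so a Latin
#'   square is constructible.
#' @param seed Integer seed; the full generated trial is a deterministic
#'   function of the configuration, the calibration and this seed.
#' @param noise_log_conc_sd Residual SD of log marker concentration around
#'   the true washout curve (dimensionless, log scale). Captures assay error
#'   plus rumen grab-sample heterogeneity.
#' @param balance_cv Coefficient of variation applied to generated intakes,
#'   volumes, yields and concentrations on their native scale.
#' @param cow_re_sd SD of the per-cow random intercept on the
#'   log-concentration scale. Enters the true pool volumes multiplicatively
#'   (a cow with intercept `a` has volume scaled by `exp(-a)`), so the
#'   fitted `diet + cow` intercept decomposition is exactly identifiable.
#' @param cow_dmi_sd SD (kg DM/day) of the per-cow intake level.
#' @param cow_mg_abs_sd SD (g/day) of the per-cow Mg absorption level.
#' @param kp_jitter_cv CV of the cow-by-diet jitter on the realised
#'   fractional passage rates around their diet-level means.
#' @param rumen_ph_sd SD of rumen pH around the diet mean.
#' @param water_kp_cor Correlation between daily water intake and the
#'   realised liquid fractional passage rate.
#' @param dose_yb_ndf_g,yb_mass_fraction Mass of Yb-labelled fibre dosed
#'   into the rumen (g) and its elemental Yb fraction; the elemental dose is
#'   their product.
#' @param dose_co_edta_g,co_mass_fraction Mass of Co-EDTA dosed (g) and its
#'   elemental Co fraction (default 0.145, the usual value for the
#'   Uden-style preparation, giving a 7.25 g Co dose).
#' @param bw_mean,bw_sd Body-weight distribution (kg), truncated at
#'   +/- 3 SD.
#' @param max_resample Bounded number of redraws for a generated balance
#'   record with a negative excretion before the generator aborts.
#'
#' @return A list of class `trial_config`.
#' @seealso [noiseless_config()], [default_calibration()], [simulate_trial()]
#' @export
#' @examples
#' cfg <- trial_config(seed = 42)
#' design <- generate_design(cfg)
trial_config <- function(n_cows = 6,
                         n_cannulated = 4,
                         n_diets = 3,
                         n_periods = 3,
                         seed = 1L,
                         noise_log_conc_sd = 0.15,
                         balance_cv = 0.06,
                         cow_re_sd = 0.08,
                         cow_dmi_sd = 0.8,
                         cow_mg_abs_sd = 1.5,
                         kp_jitter_cv = 0.05,
                         rumen_ph_sd = 0.12,
                         water_kp_cor = 0.64,
                         dose_yb_ndf_g = 200,
                         yb_mass_fraction = 0.02,
                         dose_co_edta_g = 50,
                         co_mass_fraction = 0.145,
                         bw_mean = 697,
                         bw_sd = 61,
                         max_resample = 100) {
  cfg <- structure(
    list(
      n_cows = as.integer(n_cows),
      n_cannulated = as.integer(n_cannulated),
      n_diets = as.integer(n_diets),
      n_periods = as.integer(n_periods),
      seed = as.integer(seed),
      noise_log_conc_sd = noise_log_conc_sd,
      balance_cv = balance_cv,
      cow_re_sd = cow_re_sd,
      cow_dmi_sd = cow_dmi_sd,
      cow_mg_abs_sd = cow_mg_abs_sd,
      kp_jitter_cv = kp_jitter_cv,
      rumen_ph_sd = rumen_ph_sd,
      water_kp_cor = water_kp_cor,
      dose_yb_ndf_g = dose_yb_ndf_g,
      yb_mass_fraction = yb_mass_fraction,
      dose_co_edta_g = dose_co_edta_g,
      co_mass_fraction = co_mass_fraction,
      bw_mean = bw_mean,
      bw_sd = bw_sd,
      max_resample = as.integer(max_resample)
    ),
    class = "trial_config"
  )
  validate_trial_config(cfg)
  cfg
}

#' Validate a trial configuration
#'
#' Checks the structural invariants of a [trial_config()]: a constructible
#' Latin square, no more cannulated than total cows, and non-negative noise
#' parameters. Called internally by every generator entry point.
#'
#' @param config A `trial_config` object.
#' @return `config`, invisibly, or an error.
#' @export
validate_trial_config <- function(config) {
  if (!inherits(config, "trial_config")) {
    abort("`config` must be created by trial_config().")
  }
  if (config$n_diets != config$n_periods) {
    abort(sprintf(
      "n_diets (%d) must equal n_periods (%d): the crossover is a Latin square.",
      config$n_diets, config$n_periods
    ))
  }
  if (config$n_cows %% config$n_diets != 0) {
    abort(sprintf(
      "n_cows (%d) must be a multiple of n_diets (%d) so each diet x period cell is balanced.",
      config$n_cows, config$n_diets
    ))
  }
  if (config$n_cannulated > config$n_cows) {
    abort(sprintf(
      "n_cannulated (%d) cannot exceed n_cows (%d).",
      config$n_cannulated, config$n_cows
    ))
  }
  sds <- c(
    "noise_log_conc_sd", "balance_cv", "cow_re_sd", "cow_dmi_sd",
    "cow_mg_abs_sd", "kp_jitter_cv", "rumen_ph_sd", "bw_sd"
  )
  for (nm in sds) {
    if (!is.numeric(config[[nm]]) || is.na(config[[nm]]) || config[[nm]] < 0) {
      abort(sprintf("`%s` must be a non-negative number.", nm))
    }
  }
  if (abs(config$water_kp_cor) > 1) {
    abort("`water_kp_cor` must lie in [-1, 1].")
  }
  for (nm in c("dose_yb_ndf_g", "yb_mass_fraction", "dose_co_edta_g", "co_mass_fraction")) {
    if (config[[nm]] <= 0) abort(sprintf("`%s` must be positive.", nm))
  }
  invisible(config)
}

#' Switch every noise source of a configuration off
#'
#' Returns a copy of `config` with all SDs, CVs and jitters set to zero.
#' Under a noiseless configuration the generated data are an exact
#' deterministic function of the calibration, and every downstream
#' estimator recovers the generating volumes and rates to numerical
#' precision -- the basis of the identifiability tests. Two further noise
#' SDs live in the calibration table; zero them with
#' [noiseless_calibration()].
#'
#' @param config A [trial_config()].
#' @return A `trial_config` with all noise parameters zeroed.
#' @export
noiseless_config <- function(config = trial_config()) {
  validate_trial_config(config)
  for (nm in c(
    "noise_log_conc_sd", "balance_cv", "cow_re_sd", "cow_dmi_sd",
    "cow_mg_abs_sd", "kp_jitter_cv", "rumen_ph_sd", "bw_sd"
  )) {
    config[[nm]] <- 0
  }
  config$water_kp_cor <- 0
  config
}

#' Read a trial configuration from a flat YAML file
#'
#' Accepts a flat key-value file whose keys are arguments of
#' [trial_config()]; unknown keys are rejected so typos cannot silently
#' fall back to defaults.
#'
#' @param path Path to a YAML file.
#' @return A `trial_config`.
#' @export
read_trial_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(trial_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    abort(sprintf(
      "Unknown configuration key(s) in %s: %s", path, paste(bad, collapse = ", ")
    ))
  }
  do.call(trial_config, vals)
}

#' @export
print.trial_config <- function(x, ...) {
  cat("<trial_config>\n")
  cat(sprintf(
    "  %d cows (%d cannulated), %d diets x %d periods, seed %d\n",
    x$n_cows, x$n_cannulated, x$n_diets, x$n_periods, x$seed
  ))
  cat(sprintf(
    "  noise: log-conc SD %.3g, balance CV %.3g, cow RE SD %.3g\n",
    x$noise_log_conc_sd, x$balance_cv, x$cow_re_sd
  ))
  cat(sprintf(
    "  doses: %.3g g Co (liquid), %.3g g Yb (solid)\n",
    x$dose_co_edta_g * x$co_mass_fraction,
    x$dose_yb_ndf_g * x$yb_mass_fraction
  ))
  invisible(x)
}
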