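#' Run the full analysis pipeline
#'
#' Executes simulate -> fit-kinetics -> balance -> analyze -> report into
#' an output directory and returns a run manifest. Every stage reads its
#' inputs from the CSVs written by the previous stage (so measured data can
#' replace the simulated files), validates them, logs its record counts,
#' and is skipped if its outputs already exist (delete files or pass
#' `overwrite = TRUE` to recompute).
#'
#' Outputs: `profiles.csv`, `balance.csv`, `rumen.csv`, `truth.json`
#' (simulate); `kinetics.csv` (one row per cow x diet x phase) and
#' `kinetics_tests.csv`; `balance_derived.csv`; `tests.csv` and
#' `regressions.csv`; `report.md`; `manifest.json`.
#'
#' @param out_dir Output directory.
#' @param config A [trial_config()] or the path of a flat YAML config file.
#' @param calibration Per-diet calibration table.
#' @param seed Optional seed overriding `config$seed`.
#' @param overwrite Recompute stages whose outputs already exist.
#' @param quiet Suppress per-stage log messages.
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
#' @examples
#' \donttest{
#' out <- file.path(tempdir(), "trial-run")
#' run_pipeline(out, config = trial_config(seed = 11))
#' }
run_pipeline <- function(out_dir,
                         config = trial_config(),
                         calibration = default_calibration(),
                         seed = NULL,
                         overwrite = FALSE,
                         quiet = FALSE) {
  if (is.character(config)) config <- read_trial_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  validate_trial_config(config)
  validate_calibration(calibration)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  pth <- function(f) file.path(out_dir, f)
  log_msg <- function(stage, ...) {
    if (!quiet) inform(sprintf("[%s] %s", stage, sprintf(...)))
  }
  fresh <- function(files) overwrite || !all(file.exists(pth(files)))

  # -- simulate ------------------------------------------------------------
  sim_files <- c("profiles.csv", "balance.csv", "rumen.csv", "truth.json")
  if (fresh(sim_files)) {
    trial <- simulate_trial(config, calibration)
    write_trial(trial, out_dir)
    log_msg("simulate", "wrote %d marker samples, %d balance rows, %d rumen rows",
            nrow(trial$profiles), nrow(trial$balance), nrow(trial$rumen))
  } else {
    log_msg("simulate", "outputs present, skipped")
  }

  issues <- validate_inputs(pth("profiles.csv"), pth("balance.csv"), pth("rumen.csv"))
  if (any(issues$severity == "fatal")) {
    first <- issues[issues$severity == "fatal", ][1, ]
    abort(sprintf("Input validation failed (%s): %s", first$file, first$message),
          class = "validation_error")
  }

  # -- fit-kinetics --------------------------------------------------------
  if (fresh(c("kinetics.csv", "kinetics_tests.csv"))) {
    prof <- read_profiles(pth("profiles.csv"))
    est <- estimate_kinetics(prof)
    fits <- attr(est, "fits")
    readr::write_csv(est, pth("kinetics.csv"))
    ktests <- dplyr::bind_rows(
      dplyr::mutate(test_kinetics_effects(fits$liquid, est), phase = "liquid"),
      dplyr::mutate(test_kinetics_effects(fits$solid, est), phase = "solid")
    )
    readr::write_csv(ktests, pth("kinetics_tests.csv"))
    log_msg("fit-kinetics", "%d kinetics estimates, %d test rows",
            nrow(est), nrow(ktests))
  } else {
    log_msg("fit-kinetics", "outputs present, skipped")
  }

  # -- balance -------------------------------------------------------------
  if (fresh("balance_derived.csv")) {
    bal <- read_balance(pth("balance.csv"))
    der <- derive_balance(bal)
    readr::write_csv(der, pth("balance_derived.csv"))
    log_msg("balance", "%d derived balance rows", nrow(der))
  } else {
    log_msg("balance", "outputs present, skipped")
  }

  # -- analyze -------------------------------------------------------------
  if (fresh(c("tests.csv", "regressions.csv"))) {
    der <- readr::read_csv(pth("balance_derived.csv"), show_col_types = FALSE)
    kin <- readr::read_csv(pth("kinetics.csv"), show_col_types = FALSE)
    res <- analyze_trial(der, kin)
    readr::write_csv(res$tests, pth("tests.csv"))
    readr::write_csv(res$regressions, pth("regressions.csv"))
    log_msg("analyze", "%d test rows, %d regressions",
            nrow(res$tests), nrow(res$regressions))
  } else {
    log_msg("analyze", "outputs present, skipped")
  }

  # -- report --------------------------------------------------------------
  if (fresh("report.md")) {
    write_report(out_dir)
    log_msg("report", "report.md written")
  } else {
    log_msg("report", "outputs present, skipped")
  }

  manifest <- list(
    tool = "rumenkinetics",
    version = as.character(utils::packageVersion("rumenkinetics")),
    seed = config$seed,
    config = unclass(config),
    config_digest = unname(tools::md5sum(write_temp_yaml(config))),
    file_digests = as.list(tools::md5sum(
      pth(c("profiles.csv", "balance.csv", "rumen.csv", "kinetics.csv",
            "balance_derived.csv", "tests.csv", "regressions.csv"))
    ))
  )
  names(manifest$file_digests) <- basename(names(manifest$file_digests))
  jsonlite::write_json(manifest, pth("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

write_temp_yaml <- function(config) {
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(config), f)
  f
}

#' Crossover tests and the three diagnostic regressions
#'
#' The analyze stage of [run_pipeline()], callable directly on in-memory
#' tables. Crossover ANOVAs (diet + period, random animal) with Tukey
#' contrasts are run for the main Mg and K balance responses, and three
#' cow-adjusted regressions quantify the fibre-volume-absorption chain:
#' liquid volume on NDF intake and Mg absorption on liquid volume
#' (cannulated cows, pipeline-estimated volumes), and Mg absorption on NDF
#' intake (all cows).
#'
#' @param derived Derived balance table ([derive_balance()]).
#' @param kinetics Kinetics estimates ([estimate_kinetics()]).
#' @return A list: `tests` (response, effect/contrast rows with statistics
#'   and raw/adjusted p) and `regressions` (pair, slope, se, r2_marginal,
#'   r, df, p).
#' @export
analyze_trial <- function(derived, kinetics) {
  responses <- list(
    mg_absorption_g_d = c("Mg", "absorption_g_d"),
    mg_absorbability_pct = c("Mg", "absorbability_pct"),
    mg_retention_g_d = c("Mg", "retention_g_d"),
    mg_urine_g_d = c("Mg", "urine_g_d"),
    mg_faecal_g_d = c("Mg", "faecal_g_d"),
    k_absorbability_pct = c("K", "absorbability_pct")
  )
  tests <- purrr::imap(responses, function(sp, nm) {
    dat <- dplyr::filter(derived, .data$element == sp[1])
    fit <- rlang::inject(crossover_anova(dat, !!rlang::sym(sp[2])))
    dplyr::bind_rows(
      fit$anova |>
        dplyr::transmute(
          response = nm, effect = .data$term, contrast = NA_character_,
          statistic = .data$statistic, df1 = .data$df1, df2 = .data$df2,
          p_raw = .data$p_value, p_adj = NA_real_
        ),
      tukey_contrasts(fit) |>
        dplyr::transmute(
          response = nm, effect = "diet pairwise", contrast = .data$contrast,
          statistic = .data$t_ratio, df1 = NA_real_, df2 = .data$df,
          p_raw = .data$p_value, p_adj = .data$p_adj
        )
    )
  }) |> purrr::list_rbind()

  mg <- dplyr::filter(derived, .data$element == "Mg")
  vol_l <- kinetics |>
    dplyr::filter(.data$phase == "liquid") |>
    dplyr::select("cow_id", "diet", vol_liquid_l = "volume")
  mg_cann <- dplyr::inner_join(mg, vol_l, by = c("cow_id", "diet"))

  regs <- list(
    vol_liquid_vs_ndfi = list(
      data = mg_cann, y = "vol_liquid_l", x = "ndf_intake_kg_d"
    ),
    mg_absorption_vs_vol_liquid = list(
      data = mg_cann, y = "absorption_g_d", x = "vol_liquid_l"
    ),
    mg_absorption_vs_ndfi = list(
      data = mg, y = "absorption_g_d", x = "ndf_intake_kg_d"
    )
  )
  regressions <- purrr::imap(regs, function(sp, nm) {
    fit <- rlang::inject(cow_adjusted_regression(
      sp$data, !!rlang::sym(sp$y), !!rlang::sym(sp$x)
    ))
    pc <- rlang::inject(
      pearson_cor(sp$data, !!rlang::sym(sp$x), !!rlang::sym(sp$y))
    )
    tibble(
      pair = nm, slope = fit$slope, se = fit$se,
      intercept = fit$intercept, r2_marginal = fit$r2_marginal,
      r = pc$r, df = pc$df, p = fit$p_value, n = fit$n
    )
  }) |> purrr::list_rbind()

  list(tests = tests, regressions = regressions)
}

# Markdown report assembled from the stage CSVs already in out_dir
write_report <- function(out_dir) {
  pth <- function(f) file.path(out_dir, f)
  kin <- readr::read_csv(pth("kinetics.csv"), show_col_types = FALSE)
  der <- readr::read_csv(pth("balance_derived.csv"), show_col_types = FALSE)
  rum <- readr::read_csv(pth("rumen.csv"), show_col_types = FALSE)
  regs <- readr::read_csv(pth("regressions.csv"), show_col_types = FALSE)

  fmt_tbl <- function(df) {
    df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric),
                                          ~ signif(.x, 4)))
    header <- paste0("| ", paste(names(df), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
    rows <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
    paste(c(header, sep, rows), collapse = "\n")
  }

  kin_means <- kin |>
    dplyr::group_by(.data$diet, .data$phase) |>
    dplyr::summarise(
      volume = mean(.data$volume),
      frac_kp_per_h = mean(.data$frac_kp_per_h),
      abs_kp = mean(.data$abs_kp), .groups = "drop"
    )
  bal_means <- der |>
    dplyr::filter(.data$element %in% c("Mg", "K")) |>
    dplyr::group_by(.data$element, .data$diet) |>
    dplyr::summarise(
      intake_g_d = mean(.data$intake_g_d),
      faecal_g_d = mean(.data$faecal_g_d),
      urine_g_d = mean(.data$urine_g_d),
      milk_g_d = mean(.data$milk_g_d),
      absorption_g_d = mean(.data$absorption_g_d),
      absorbability_pct = mean(.data$absorbability_pct),
      retention_g_d = mean(.data$retention_g_d), .groups = "drop"
    )
  sol <- mg_solubility(rum, kin) |>
    dplyr::group_by(.data$diet) |>
    dplyr::summarise(mg_solubility_pct = mean(.data$mg_solubility_pct),
                     .groups = "drop")

  txt <- c(
    "# Trial report", "",
    "## Rumen passage kinetics (treatment means)", "",
    fmt_tbl(kin_means), "",
    "## Mineral balance (treatment means)", "",
    fmt_tbl(bal_means), "",
    "## Rumen Mg solubility (treatment means)", "",
    fmt_tbl(sol), "",
    "## Cow-adjusted regressions", "",
    fmt_tbl(regs), ""
  )
  writeLines(txt, pth("report.md"))
  invisible(pth("report.md"))
}
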