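#' Write a simulated trial to plain-text files
#'
#' Writes `profiles.csv`, `balance.csv`, `rumen.csv` and `truth.json`
#' (ground-truth per-cell state, calibration, configuration, and the names
#' of calibration values that are assumed placeholders rather than
#' published quantities) into `dir`. CSVs are comma-separated UTF-8 with a
#' header and `.` decimal; every concentration column travels with an
#' explicit units column.
#'
#' @param trial A [simulate_trial()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_trial <- function(trial, dir) {
  stopifnot(inherits(trial, "rumen_trial"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    profiles = file.path(dir, "profiles.csv"),
    balance = file.path(dir, "balance.csv"),
    rumen = file.path(dir, "rumen.csv"),
    truth = file.path(dir, "truth.json")
  )
  readr::write_csv(trial$profiles, paths["profiles"])
  readr::write_csv(trial$balance, paths["balance"])
  readr::write_csv(trial$rumen, paths["rumen"])
  jsonlite::write_json(
    list(
      config = unclass(trial$config),
      calibration = trial$calibration,
      assumed_calibration_values = attr(trial$calibration, "assumed"),
      truth = trial$truth
    ),
    paths["truth"],
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(paths)
}

profile_cols <- c("cow_id", "period", "diet", "phase", "time_h", "conc",
                  "conc_units", "dose_g")
balance_cols <- c("cow_id", "period", "diet", "bw_kg", "dmi_kg_d",
                  "ndf_intake_kg_d", "water_l_d", "element", "intake_g_d",
                  "faecal_g_d", "urine_g_d", "milk_g_d")
rumen_cols <- c("cow_id", "period", "diet", "ph", "liquid_mg_mmol_l",
                "liquid_k_mmol_l", "liquid_na_mmol_l", "solid_mg_g_kg",
                "solid_k_g_kg")

read_checked <- function(path, required, what) {
  if (!file.exists(path)) {
    abort(sprintf("%s file not found: %s", what, path), class = "validation_error")
  }
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(
      sprintf("%s (%s) is missing required column(s): %s",
              what, path, paste(missing_cols, collapse = ", ")),
      class = "validation_error"
    )
  }
  x
}

#' Read trial CSV files
#'
#' Schema-checked readers for the three trial tables; the same schemas
#' accept measured (non-simulated) data.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_profiles <- function(path) read_checked(path, profile_cols, "Profiles")

#' @rdname read_profiles
#' @export
read_balance <- function(path) read_checked(path, balance_cols, "Balance")

#' @rdname read_profiles
#' @export
read_rumen <- function(path) read_checked(path, rumen_cols, "Rumen chemistry")

#' Validate trial input files
#'
#' Checks the three trial CSVs for schema, unit labels, positivity and
#' crossover balance, distinguishing fatal errors from warnings. A cow
#' missing a period is fatal for the crossover ANOVA stage but only a
#' warning for the regression stage, which tolerates incomplete designs.
#'
#' @param profiles,balance,rumen Paths to the CSV files; any may be `NULL`
#'   to skip.
#' @return A tibble `file`, `stage`, `severity` (fatal/warning), `message`;
#'   zero rows means fully valid.
#' @export
validate_inputs <- function(profiles = NULL, balance = NULL, rumen = NULL) {
  issues <- list()
  add <- function(file, stage, severity, message) {
    issues[[length(issues) + 1]] <<- tibble(
      file = file, stage = stage, severity = severity, message = message
    )
  }

  if (!is.null(profiles)) {
    p <- tryCatch(read_profiles(profiles), error = function(e) e)
    if (inherits(p, "error")) {
      add(profiles, "all", "fatal", conditionMessage(p))
    } else {
      bad_units <- !p$conc_units %in% c("g_per_l", "g_per_kg_dm")
      if (any(bad_units)) {
        add(profiles, "fit-kinetics", "fatal",
            sprintf("Unknown conc_units at row %d.", which(bad_units)[1]))
      }
      neg <- p$time_h > 0 & (!is.finite(p$conc) | p$conc <= 0)
      if (any(neg)) {
        add(profiles, "fit-kinetics", "fatal",
            sprintf("Non-positive post-dose concentration at row %d.",
                    which(neg)[1]))
      }
      if (any(p$dose_g <= 0)) {
        add(profiles, "fit-kinetics", "fatal", "Non-positive marker dose.")
      }
    }
  }

  if (!is.null(balance)) {
    b <- tryCatch(read_balance(balance), error = function(e) e)
    if (inherits(b, "error")) {
      add(balance, "all", "fatal", conditionMessage(b))
    } else {
      for (col in c("intake_g_d", "faecal_g_d", "urine_g_d", "milk_g_d")) {
        neg <- b[[col]] < 0
        if (any(neg, na.rm = TRUE)) {
          add(balance, "balance", "fatal",
              sprintf("Negative %s at row %d.", col, which(neg)[1]))
        }
      }
      over <- b$ndf_intake_kg_d > b$dmi_kg_d + 1e-9
      if (any(over, na.rm = TRUE)) {
        add(balance, "balance", "fatal",
            sprintf("NDF intake exceeds DM intake at row %d.", which(over)[1]))
      }
      cells <- dplyr::distinct(b, .data$cow_id, .data$period)
      per_cow <- dplyr::count(cells, .data$cow_id)
      if (length(unique(per_cow$n)) > 1) {
        miss <- per_cow$cow_id[per_cow$n < max(per_cow$n)][1]
        add(balance, "analyze-anova", "fatal",
            sprintf("Cow %s does not appear in every period (incomplete crossover).", miss))
        add(balance, "analyze-regression", "warning",
            sprintf("Cow %s missing period(s): regressions proceed on available rows.", miss))
      }
    }
  }

  if (!is.null(rumen)) {
    r <- tryCatch(read_rumen(rumen), error = function(e) e)
    if (inherits(r, "error")) {
      add(rumen, "all", "fatal", conditionMessage(r))
    } else {
      if (any(r$ph <= 0 | r$ph >= 14, na.rm = TRUE)) {
        add(rumen, "balance", "fatal", "Rumen pH outside (0, 14).")
      }
      conc_cols <- setdiff(rumen_cols, c("cow_id", "period", "diet", "ph"))
      for (col in conc_cols) {
        if (any(r[[col]] < 0, na.rm = TRUE)) {
          add(rumen, "balance", "fatal", sprintf("Negative %s.", col))
        }
      }
    }
  }

  if (length(issues) == 0) {
    return(tibble(file = character(), stage = character(),
                  severity = character(), message = character()))
  }
  purrr::list_rbind(issues)
}
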