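#' Generate a balanced crossover design
#'
#' Assigns cows to diet sequences over periods as stacked cyclic Latin
#' squares (`n_cows / n_diets` squares), so that every cow receives every
#' diet exactly once and every diet appears in every period in exactly
#' `n_cows / n_diets` cows. Cow order, the diet permutation of each square
#' and the cannulated subset are randomised by the configuration seed; body
#' weights are drawn from a Normal truncated at three SD.
#'
#' @param config A [trial_config()].
#' @param diets Diet labels; defaults to [diet_levels()] for a 3-diet trial.
#' @return A tibble with one row per cow x period: `cow_id`, `period`,
#'   `diet`, `cannulated`, `bw_kg`.
#' @export
#' @examples
#' generate_design(trial_config(seed = 7))
generate_design <- function(config = trial_config(),
                            diets = NULL) {
  validate_trial_config(config)
  k <- config$n_diets
  if (is.null(diets)) {
    diets <- if (k == 3) diet_levels() else sprintf("Diet%d", seq_len(k))
  }
  if (length(diets) != k) {
    abort(sprintf("`diets` must supply %d labels, got %d.", k, length(diets)))
  }
  n_squares <- config$n_cows %/% k

  withr::with_seed(config$seed, {
    cow_order <- sample(config$n_cows)
    rows <- purrr::map(seq_len(n_squares), function(s) {
      perm <- sample(k) # random diet relabelling per square
      purrr::map(seq_len(k), function(i) {
        cow <- cow_order[(s - 1L) * k + i]
        tibble(
          cow_id = sprintf("cow%d", cow),
          period = seq_len(k),
          diet = diets[perm[((i + seq_len(k) - 2L) %% k) + 1L]]
        )
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()

    cann <- sort(sample(config$n_cows, config$n_cannulated))
    bw <- rnorm_truncated(config$n_cows, config$bw_mean, config$bw_sd, 3)
    cows <- tibble(
      cow_id = sprintf("cow%d", seq_len(config$n_cows)),
      cannulated = seq_len(config$n_cows) %in% cann,
      bw_kg = bw
    )
  })

  design <- rows |>
    dplyr::left_join(cows, by = "cow_id") |>
    dplyr::arrange(.data$period, .data$cow_id)
  validate_design(design, config)
  design
}

# Normal draw truncated at +/- k SD (redraw, exact for the narrow tails here)
rnorm_truncated <- function(n, mean, sd, k = 3) {
  if (sd == 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  bad <- abs(x - mean) > k * sd
  while (any(bad)) {
    x[bad] <- rnorm(sum(bad), mean, sd)
    bad <- abs(x - mean) > k * sd
  }
  x
}

# Structural checks: Latin-square balance over cows, diets and periods
validate_design <- function(design, config = NULL) {
  req <- c("cow_id", "period", "diet", "cannulated", "bw_kg")
  missing_cols <- setdiff(req, names(design))
  if (length(missing_cols) > 0) {
    abort(sprintf("Design is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  by_cow <- dplyr::count(design, .data$cow_id, .data$diet)
  if (any(by_cow$n != 1)) {
    abort("Each cow must receive each diet exactly once.")
  }
  per_cell <- dplyr::count(design, .data$period, .data$diet)
  if (length(unique(per_cell$n)) != 1) {
    abort("Each diet must occur equally often in every period.")
  }
  invisible(design)
}
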