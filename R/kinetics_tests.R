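#' Treatment effects on washout curves and passage rates
#'
#' Tests diet effects on the fitted washout model and on the absolute
#' passage rates:
#' * Type III Wald F tests (Satterthwaite denominator df) for diet
#'   differences in curve intercepts and time slopes (and quadratic terms
#'   for the solid phase), from a refit of the decay model in interaction
#'   coding;
#' * Tukey-adjusted pairwise diet contrasts of the extrapolated zero-time
#'   intercepts and of the fitted time slopes (evaluated at the end of the
#'   sampling window for the quadratic model, the steepest-tangent
#'   convention);
#' * a Friedman chi-square test of the absolute passage rate with animal
#'   as block and diet as factor.
#'
#' @param fit A [fit_decay()] object fitted with a random animal intercept
#'   and at least two diets.
#' @param estimates Kinetics estimates from [summarize_kinetics()] for the
#'   same phase; needed for the Friedman test on absolute Kp (omit to skip
#'   it).
#' @param exact_friedman Also compute the exact permutation p for the
#'   Friedman test (default `TRUE` when the block matrix is small).
#' @return A tibble with one row per test: `component` (intercept, slope,
#'   quad, abs_kp), `test`, `contrast`, `estimate`, `se`, `statistic`,
#'   `df1`, `df2`, `p_value`, `p_adj`.
#' @export
#' @examples
#' trial <- simulate_trial(trial_config(seed = 1))
#' fit <- fit_decay(trial$profiles, phase = "liquid")
#' test_kinetics_effects(fit, summarize_kinetics(fit))
test_kinetics_effects <- function(fit, estimates = NULL,
                                  exact_friedman = NULL) {
  stopifnot(inherits(fit, "decay_fit"))
  if (nrow(fit$coefficients) < 2) {
    abort("At least two diets are required to test treatment effects.")
  }
  if (!inherits(fit$model, "merMod")) {
    abort("Treatment tests need the mixed fit (>= 2 animals).")
  }

  dat <- fit$data
  fml <- if (fit$model_type == "quadratic") {
    log_conc ~ diet * time_h + diet * I(time_h^2) + (1 | cow_id)
  } else {
    log_conc ~ diet * time_h + (1 | cow_id)
  }
  m2 <- fit_lmer_quietly(fml, dat)

  at <- as.data.frame(anova(m2, type = 3))
  term_map <- c(
    diet = "intercept", `diet:time_h` = "slope",
    `diet:I(time_h^2)` = "quad"
  )
  keep <- rownames(at) %in% names(term_map)
  wald <- tibble(
    component = unname(term_map[rownames(at)[keep]]),
    test = "wald_F", contrast = NA_character_,
    estimate = NA_real_, se = NA_real_,
    statistic = at$`F value`[keep], df1 = at$NumDF[keep],
    df2 = at$DenDF[keep], p_value = at$`Pr(>F)`[keep],
    p_adj = NA_real_
  )

  tk <- function(grid, component) {
    adj <- as.data.frame(emmeans::contrast(grid, "pairwise", adjust = "tukey"))
    raw <- as.data.frame(emmeans::contrast(grid, "pairwise", adjust = "none"))
    tibble(
      component = component, test = "tukey",
      contrast = as.character(adj$contrast),
      estimate = adj$estimate, se = adj$SE, statistic = adj$t.ratio,
      df1 = NA_real_, df2 = adj$df, p_value = raw$p.value,
      p_adj = pmin(1, adj$p.value)
    )
  }
  # emmeans notes that diet is involved in interactions: intentional here
  # (intercepts are compared at t = 0, slopes at the window end)
  # Satterthwaite df: matches the Wald table and stays defined for
  # near-degenerate (noise-free) fits
  em_int <- suppressMessages(
    emmeans::emmeans(m2, "diet", at = list(time_h = 0),
                     lmer.df = "satterthwaite")
  )
  slope_t <- if (fit$model_type == "quadratic") max(fit$time_window) else 0
  em_slp <- suppressMessages(
    emmeans::emtrends(m2, "diet", var = "time_h",
                      at = list(time_h = slope_t),
                      lmer.df = "satterthwaite")
  )
  tukey <- dplyr::bind_rows(tk(em_int, "intercept"), tk(em_slp, "slope"))

  fr <- NULL
  if (!is.null(estimates)) {
    est <- dplyr::filter(estimates, .data$phase == fit$phase)
    cnt <- dplyr::count(est, .data$cow_id, .data$diet)
    n_cells <- dplyr::n_distinct(est$cow_id) * dplyr::n_distinct(est$diet)
    if (nrow(cnt) != n_cells || any(cnt$n != 1)) {
      abort("Unbalanced cow x diet matrix: Friedman needs one absolute Kp per cell.")
    }
    if (is.null(exact_friedman)) {
      exact_friedman <- nrow(cnt) <= 20
    }
    f <- friedman_test(est, response = abs_kp, treatment = diet,
                       block = cow_id, exact = exact_friedman)
    fr <- tibble(
      component = "abs_kp", test = "friedman", contrast = NA_character_,
      estimate = NA_real_, se = NA_real_, statistic = f$statistic,
      df1 = f$df, df2 = NA_real_,
      p_value = if (!is.na(f$p_exact)) f$p_exact else f$p_value,
      p_adj = NA_real_
    )
  }

  dplyr::bind_rows(wald, tukey, fr)
}
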