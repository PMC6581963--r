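#' Fit a mixed log-linear or log-quadratic marker washout model
#'
#' Log concentrations are regressed on per-diet intercepts and per-diet
#' time slopes (plus per-diet quadratic terms for the decelerating
#' solid-phase washout) with a random intercept per animal, by REML.
#' Pre-dose rows (`time_h == 0`) are ignored; the first usable sample is
#' the 1 h one. Profiles are sorted by (cow, period, time) before fitting
#' so the result does not depend on input row order. With fewer than two
#' animals the random intercept is dropped and the model reduces to
#' ordinary least squares.
#'
#' @param profiles A profiles tibble as produced by
#'   [generate_marker_profiles()] (or read from `profiles.csv`); must
#'   contain `cow_id`, `period`, `diet`, `phase`, `time_h`, `conc`,
#'   `dose_g`.
#' @param phase `"liquid"` or `"solid"`.
#' @param model `"linear"` or `"quadratic"`; defaults to linear for the
#'   liquid phase and quadratic for the solid phase.
#' @param random_slopes If `TRUE`, adds a per-animal random time slope
#'   (off by default: with four animals the extra variance component is
#'   weakly identified).
#' @return An object of class `decay_fit` with per-diet fixed coefficients,
#'   per-animal random intercepts (BLUPs), variance components and the
#'   coefficient covariance matrix. Use [tidy()], [glance()],
#'   [fractional_kp()], [pool_volume()], [summarize_kinetics()].
#' @export
#' @examples
#' trial <- simulate_trial(trial_config(seed = 1))
#' fit <- fit_decay(trial$profiles, phase = "liquid")
#' tidy(fit)
fit_decay <- function(profiles,
                      phase = c("liquid", "solid"),
                      model = NULL,
                      random_slopes = FALSE) {
  phase <- match.arg(phase)
  if (is.null(model)) model <- if (phase == "solid") "quadratic" else "linear"
  model <- match.arg(model, c("linear", "quadratic"))

  req <- c("cow_id", "period", "diet", "phase", "time_h", "conc")
  missing_cols <- setdiff(req, names(profiles))
  if (length(missing_cols) > 0) {
    abort(sprintf("`profiles` is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (is.factor(profiles$diet)) {
    empty <- setdiff(levels(profiles$diet), unique(as.character(profiles$diet)))
    if (length(empty) > 0) {
      abort(sprintf("Diet(s) with no observations: %s (singular design).",
                    paste(empty, collapse = ", ")))
    }
    profiles$diet <- as.character(profiles$diet)
  }

  dat <- profiles |>
    dplyr::filter(.data$phase == !!phase, .data$time_h > 0) |>
    dplyr::arrange(.data$cow_id, .data$period, .data$time_h)
  if (nrow(dat) == 0) abort(sprintf("No post-dose %s-phase rows to fit.", phase))
  bad <- which(!is.finite(dat$conc) | dat$conc <= 0)
  if (length(bad) > 0) {
    abort(sprintf(
      "Non-positive marker concentration in %s phase (cow %s, period %s, t = %g h).",
      phase, dat$cow_id[bad[1]], dat$period[bad[1]], dat$time_h[bad[1]]
    ))
  }
  n_pts <- dat |> dplyr::count(.data$cow_id, .data$period, .data$diet)
  if (any(n_pts$n < 2)) {
    p1 <- n_pts[n_pts$n < 2, ][1, ]
    abort(sprintf(
      "Profile for cow %s, period %s has fewer than 2 post-dose time points.",
      p1$cow_id, p1$period
    ))
  }

  dat$log_conc <- log(dat$conc)
  dat$tsq <- dat$time_h^2
  diets <- sort(unique(dat$diet))
  n_cows <- dplyr::n_distinct(dat$cow_id)

  # with a single diet the per-diet coding degenerates to a plain curve
  single_diet <- length(diets) == 1
  fixed <- if (single_diet) {
    paste0("log_conc ~ time_h", if (model == "quadratic") " + tsq")
  } else if (model == "quadratic") {
    "log_conc ~ 0 + diet + diet:time_h + diet:tsq"
  } else {
    "log_conc ~ 0 + diet + diet:time_h"
  }

  warns <- character(0)
  if (n_cows >= 2) {
    ranform <- if (random_slopes) "(1 + time_h | cow_id)" else "(1 | cow_id)"
    fml <- as.formula(paste(fixed, "+", ranform))
    fit <- withCallingHandlers(
      lmerTest::lmer(fml, data = dat, REML = TRUE),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      },
      message = function(m) invokeRestart("muffleMessage")
    )
    vc <- as.data.frame(lme4::VarCorr(fit))
    cow_var <- vc$vcov[vc$grp == "cow_id" & vc$var1 == "(Intercept)" &
                         is.na(vc$var2)][1]
    resid_var <- sigma(fit)^2
    re <- lme4::ranef(fit)$cow_id
    ranef_tbl <- tibble(cow_id = rownames(re), a_cow = re[["(Intercept)"]])
    beta <- lme4::fixef(fit)
    vc_mat <- as.matrix(vcov(fit))
  } else {
    fit <- lm(as.formula(fixed), data = dat)
    cow_var <- 0
    resid_var <- sigma(fit)^2
    if (!is.finite(resid_var)) resid_var <- 0 # saturated noiseless fit
    ranef_tbl <- tibble(cow_id = unique(dat$cow_id), a_cow = 0)
    beta <- coef(fit)
    vc_mat <- vcov(fit)
  }

  coef_tbl <- if (single_diet) {
    tibble(
      diet = diets,
      intercept = unname(beta["(Intercept)"]),
      slope = unname(beta["time_h"]),
      quad = if (model == "quadratic") unname(beta["tsq"]) else 0
    )
  } else {
    tibble(
      diet = diets,
      intercept = unname(beta[paste0("diet", diets)]),
      slope = unname(beta[paste0("diet", diets, ":time_h")]),
      quad = if (model == "quadratic") {
        unname(beta[paste0("diet", diets, ":tsq")])
      } else {
        rep(0, length(diets))
      }
    )
  }

  doses <- if ("dose_g" %in% names(profiles)) {
    profiles |>
      dplyr::filter(.data$phase == !!phase) |>
      dplyr::distinct(.data$cow_id, .data$period, .data$diet, .data$dose_g)
  } else {
    NULL
  }

  structure(
    list(
      model = fit, phase = phase, model_type = model,
      random_slopes = random_slopes, coefficients = coef_tbl,
      ranef = ranef_tbl, cow_var = cow_var, resid_var = resid_var,
      vcov = vc_mat, n_obs = nrow(dat), data = dat, doses = doses,
      time_window = range(dat$time_h), warnings = warns
    ),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "<decay_fit> %s phase, %s model, %d obs, %d diets, %d animals\n",
    x$phase, x$model_type, x$n_obs, nrow(x$coefficients), nrow(x$ranef)
  ))
  print(x$coefficients)
  cat(sprintf("  variance components: cow %.4g, residual %.4g\n",
              x$cow_var, x$resid_var))
  invisible(x)
}

#' @rdname fit_decay
#' @param x A `decay_fit`.
#' @param ... Unused.
#' @method tidy decay_fit
#' @export
tidy.decay_fit <- function(x, ...) {
  x$coefficients |>
    tidyr::pivot_longer(c("intercept", "slope", "quad"),
                        names_to = "term", values_to = "estimate") |>
    dplyr::filter(x$model_type == "quadratic" | .data$term != "quad")
}

#' @rdname fit_decay
#' @method glance decay_fit
#' @export
glance.decay_fit <- function(x, ...) {
  tibble(
    phase = x$phase, model = x$model_type, n_obs = x$n_obs,
    n_animals = nrow(x$ranef), cow_var = x$cow_var,
    resid_var = x$resid_var,
    REMLcrit = if (inherits(x$model, "merMod")) lme4::REMLcrit(x$model) else NA_real_
  )
}

#' Fractional passage rate from a fitted washout model
#'
#' For the log-linear model the fractional outflow rate of a diet is the
#' negated time slope. For the log-quadratic model the instantaneous slope
#' `b + 2 c t` varies over time and the rate is reported as the steepest
#' descending tangent over the observed window (the maximum of
#' `-(b + 2 c t)` over `t` in the window, attained at the window end when
#' `c < 0`) -- the maximal-slope convention for passage rates. Set
#' `at = "initial"` for the tangent at the start of the window instead.
#'
#' @param fit A [fit_decay()] object.
#' @param window Evaluation window in hours; defaults to the observed
#'   sampling window.
#' @param at `"steepest"` (default) or `"initial"`.
#' @return A tibble with `diet`, `phase`, `frac_kp_per_h`.
#' @export
fractional_kp <- function(fit, window = NULL, at = c("steepest", "initial")) {
  stopifnot(inherits(fit, "decay_fit"))
  at <- match.arg(at)
  if (is.null(window)) window <- fit$time_window
  if (length(window) != 2 || window[1] >= window[2]) {
    abort("`window` must be an increasing pair of hours.")
  }

  out <- fit$coefficients |>
    dplyr::mutate(
      frac_kp_per_h = dplyr::case_when(
        fit$model_type == "linear" ~ -.data$slope,
        at == "initial" ~ -(.data$slope + 2 * .data$quad * window[1]),
        TRUE ~ pmax(
          -(.data$slope + 2 * .data$quad * window[1]),
          -(.data$slope + 2 * .data$quad * window[2])
        )
      )
    )
  non_clearing <- out$diet[out$frac_kp_per_h <= 0]
  if (length(non_clearing) > 0) {
    abort(sprintf(
      "Fitted curve is non-descending over [%g, %g] h for diet(s) %s: marker not clearing.",
      window[1], window[2], paste(non_clearing, collapse = ", ")
    ))
  }
  out |>
    dplyr::mutate(phase = fit$phase) |>
    dplyr::select("diet", "phase", "frac_kp_per_h")
}

#' Pool volume by marker dilution
#'
#' The pool volume of a cow on a diet is the marker dose divided by the
#' model's extrapolated zero-time concentration,
#' `dose / exp(a_diet + a_cow)`, where `a_cow` is the animal's random
#' intercept (BLUP). Set `include_cow_effect = FALSE` to extrapolate from
#' the diet-level intercept alone.
#'
#' @param fit A [fit_decay()] object.
#' @param doses Optional tibble `cow_id`, `diet`, `dose_g`; defaults to the
#'   doses carried by the fitted profiles.
#' @param include_cow_effect Include the animal BLUP in the extrapolated
#'   intercept (default `TRUE`).
#' @return A tibble `cow_id`, `diet`, `phase`, `volume` (litres for the
#'   liquid phase, kg DM for the solid phase).
#' @export
pool_volume <- function(fit, doses = NULL, include_cow_effect = TRUE) {
  stopifnot(inherits(fit, "decay_fit"))
  if (is.null(doses)) doses <- fit$doses
  if (is.null(doses)) {
    abort("No dose information: supply `doses` (cow_id, diet, dose_g).")
  }
  if (any(!is.finite(doses$dose_g) | doses$dose_g <= 0)) {
    abort("All doses must be positive.")
  }
  doses |>
    dplyr::distinct(.data$cow_id, .data$diet, .data$dose_g) |>
    dplyr::left_join(fit$coefficients[, c("diet", "intercept")], by = "diet") |>
    dplyr::left_join(fit$ranef, by = "cow_id") |>
    dplyr::mutate(
      a_cow = dplyr::coalesce(.data$a_cow, 0),
      log_c0 = .data$intercept + if (include_cow_effect) .data$a_cow else 0,
      volume = .data$dose_g / exp(.data$log_c0),
      phase = fit$phase
    ) |>
    dplyr::select("cow_id", "diet", "phase", "volume")
}

#' Per-cow kinetics estimates from a fitted washout model
#'
#' Combines [pool_volume()] and [fractional_kp()] into one estimate per
#' cow x diet: pool volume, fractional passage rate and their product, the
#' absolute passage rate (`abs_kp = volume * frac_kp`, an exact identity).
#' Units follow the phase: litres and l/h for the liquid phase, kg DM and
#' kg DM/h for the solid phase.
#'
#' @inheritParams pool_volume
#' @param ... Passed to [fractional_kp()].
#' @return A tibble `cow_id`, `diet`, `phase`, `volume`, `volume_units`,
#'   `frac_kp_per_h`, `abs_kp`, `abs_kp_units`.
#' @export
summarize_kinetics <- function(fit, doses = NULL, ...) {
  stopifnot(inherits(fit, "decay_fit"))
  units <- if (fit$phase == "liquid") c("l", "l_per_h") else c("kg_dm", "kg_dm_per_h")
  pool_volume(fit, doses = doses) |>
    dplyr::left_join(fractional_kp(fit, ...), by = c("diet", "phase")) |>
    dplyr::mutate(
      volume_units = units[1],
      abs_kp = .data$volume * .data$frac_kp_per_h,
      abs_kp_units = units[2]
    ) |>
    dplyr::select(
      "cow_id", "diet", "phase", "volume", "volume_units",
      "frac_kp_per_h", "abs_kp", "abs_kp_units"
    )
}

#' Fit both digesta phases and tabulate kinetics estimates
#'
#' Convenience wrapper: fits the liquid phase with the log-linear model and
#' the solid phase with the log-quadratic model, and returns the combined
#' per-cow estimates. The two `decay_fit` objects are attached as the
#' `"fits"` attribute.
#'
#' @param profiles A profiles tibble covering both phases.
#' @param ... Passed on to [fit_decay()].
#' @return A tibble of kinetics estimates for both phases.
#' @export
estimate_kinetics <- function(profiles, ...) {
  fits <- list(
    liquid = fit_decay(profiles, phase = "liquid", ...),
    solid = fit_decay(profiles, phase = "solid", ...)
  )
  est <- dplyr::bind_rows(
    summarize_kinetics(fits$liquid),
    summarize_kinetics(fits$solid)
  )
  attr(est, "fits") <- fits
  est
}
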