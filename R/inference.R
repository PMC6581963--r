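#' Crossover ANOVA with a random animal effect
#'
#' Fits the crossover model `response = mean + Diet + Period + Animal +
#' error` with Diet and Period fixed and Animal random (REML), and reports
#' Type III Wald F tests (Satterthwaite denominator df) and diet
#' least-squares means. `method = "fixed"` fits Animal as a fixed block
#' instead -- for a balanced complete crossover the Diet F statistic is
#' identical, and the fixed fit is exactly reproducible without an
#' optimiser.
#'
#' @param data A tibble with one row per cow x period.
#' @param response Bare column name of the response.
#' @param diet,period,cow Bare column names of the design factors
#'   (defaults `diet`, `period`, `cow_id`).
#' @param method `"random"` (animal as random intercept, default) or
#'   `"fixed"` (animal as fixed block).
#' @return An object of class `crossover_anova` with the F table, diet
#'   lsmeans and variance components. Use [tidy()], [glance()],
#'   [tukey_contrasts()].
#' @export
#' @examples
#' trial <- simulate_trial(trial_config(seed = 2))
#' mg <- dplyr::filter(derive_balance(trial$balance), element == "Mg")
#' fit <- crossover_anova(mg, absorption_g_d)
#' tidy(fit)
#' tukey_contrasts(fit)
crossover_anova <- function(data, response,
                            diet = diet, period = period, cow = cow_id,
                            method = c("random", "fixed")) {
  method <- match.arg(method)
  d <- dplyr::transmute(
    data,
    resp = {{ response }},
    diet = factor({{ diet }}),
    period = factor({{ period }}),
    cow = factor({{ cow }})
  )
  if (any(!is.finite(d$resp))) abort("Response contains non-finite values.")
  dup <- dplyr::count(d, .data$cow, .data$period) |> dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("Duplicated cow x period row(s): cow %s, period %s.",
                  dup$cow[1], dup$period[1]))
  }
  if (nlevels(d$diet) < 2) abort("At least two diets are required.")

  if (method == "random") {
    m <- fit_lmer_quietly(resp ~ diet + period + (1 | cow), d)
    at <- as.data.frame(anova(m, type = 3))
    aov_tbl <- tibble(
      term = rownames(at), df1 = at$NumDF, df2 = at$DenDF,
      statistic = at$`F value`, p_value = at$`Pr(>F)`
    )
    vc <- as.data.frame(lme4::VarCorr(m))
    varcomp <- c(animal = vc$vcov[vc$grp == "cow"][1], residual = sigma(m)^2)
  } else {
    m <- lm(resp ~ diet + period + cow, data = d)
    at <- stats::drop1(m, scope = ~ diet + period, test = "F")
    keep <- rownames(at) %in% c("diet", "period")
    aov_tbl <- tibble(
      term = rownames(at)[keep], df1 = at$Df[keep],
      df2 = m$df.residual, statistic = at$`F value`[keep],
      p_value = at$`Pr(>F)`[keep]
    )
    varcomp <- c(animal = NA_real_, residual = sigma(m)^2)
  }

  em <- emmeans::emmeans(m, "diet")
  ems <- as.data.frame(em)
  lsmeans <- tibble(
    diet = as.character(ems$diet), lsmean = ems$emmean, se = ems$SE,
    df = ems$df, lower = ems$lower.CL, upper = ems$upper.CL
  )

  structure(
    list(
      response = rlang::as_label(rlang::enquo(response)),
      method = method, model = m, anova = aov_tbl, lsmeans = lsmeans,
      varcomp = varcomp, emmeans = em, n_obs = nrow(d), data = d
    ),
    class = "crossover_anova"
  )
}

# lmer with convergence/singularity chatter muffled. The model frame is
# stashed in the formula environment under a fixed name so downstream
# tools (emmeans) can reconstruct the data after the calling frame is gone.
fit_lmer_quietly <- function(formula, data) {
  env <- new.env(parent = environment(formula))
  env$.rumenkinetics_data <- data
  environment(formula) <- env
  withCallingHandlers(
    eval(
      bquote(lmerTest::lmer(.(formula), data = .rumenkinetics_data,
                            REML = TRUE)),
      env
    ),
    warning = function(w) invokeRestart("muffleWarning"),
    message = function(m) invokeRestart("muffleMessage")
  )
}

#' @export
print.crossover_anova <- function(x, ...) {
  cat(sprintf("<crossover_anova> %s (%s animal effect), %d obs\n",
              x$response, x$method, x$n_obs))
  print(x$anova)
  print(x$lsmeans)
  invisible(x)
}

#' @rdname crossover_anova
#' @param x A `crossover_anova`.
#' @param ... Unused.
#' @method tidy crossover_anova
#' @export
tidy.crossover_anova <- function(x, ...) x$anova

#' @rdname crossover_anova
#' @method glance crossover_anova
#' @export
glance.crossover_anova <- function(x, ...) {
  tibble(
    response = x$response, method = x$method, n_obs = x$n_obs,
    animal_var = unname(x$varcomp["animal"]),
    resid_var = unname(x$varcomp["residual"])
  )
}

#' Tukey-Kramer pairwise diet contrasts
#'
#' All pairwise differences between diet least-squares means with
#' family-wise adjustment through the studentized-range distribution
#' (single-step Tukey-Kramer), on the residual df of the crossover model.
#' Raw (unadjusted) p-values are reported alongside. Labels follow the
#' usual convention: significant at adjusted p <= 0.05, trend at p < 0.10.
#'
#' @param x A [crossover_anova()] fit (or any object with an `emmeans`
#'   element).
#' @return A tibble: `contrast`, `estimate`, `se`, `df`, `t_ratio`,
#'   `p_value` (raw), `p_adj` (Tukey), `label`.
#' @export
tukey_contrasts <- function(x) {
  if (!inherits(x, "crossover_anova")) {
    abort("`x` must be a crossover_anova fit.")
  }
  if (nrow(x$lsmeans) < 2) abort("At least two lsmeans are required.")
  adj <- as.data.frame(emmeans::contrast(x$emmeans, "pairwise", adjust = "tukey"))
  raw <- as.data.frame(emmeans::contrast(x$emmeans, "pairwise", adjust = "none"))
  tibble(
    contrast = as.character(adj$contrast),
    estimate = adj$estimate, se = adj$SE, df = adj$df,
    t_ratio = adj$t.ratio,
    p_value = raw$p.value,
    p_adj = pmin(1, adj$p.value),
    label = dplyr::case_when(
      pmin(1, adj$p.value) <= 0.05 ~ "significant",
      pmin(1, adj$p.value) < 0.10 ~ "trend",
      TRUE ~ ""
    )
  )
}

#' Friedman rank test for a randomized complete block design
#'
#' The chi-square statistic `12 / (n k (k + 1)) * sum(R_j^2) - 3 n (k + 1)`
#' over midranks within blocks, with `df = k - 1` and an asymptotic
#' chi-square p-value. With `exact = TRUE` (feasible for `n * k <= 20`) the
#' p-value is additionally computed by full enumeration of all `(k!)^n`
#' within-block rearrangements.
#'
#' @param x Either a numeric matrix (blocks x treatments) or a data frame.
#' @param response,treatment,block For the data-frame method, bare column
#'   names; each block x treatment cell must be filled exactly once.
#' @param exact Also compute the exact permutation p-value.
#' @param ... Passed between methods.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `p_exact`,
#'   `n_blocks`, `n_treatments`.
#' @export
#' @examples
#' m <- matrix(c(1, 2, 3, 1, 2, 3, 1, 2, 3, 1, 2, 3), nrow = 4, byrow = TRUE)
#' friedman_test(m, exact = TRUE)
friedman_test <- function(x, ...) UseMethod("friedman_test")

#' @rdname friedman_test
#' @export
friedman_test.matrix <- function(x, exact = FALSE, ...) {
  if (anyNA(x)) abort("Block matrix has missing cells; Friedman requires complete blocks.")
  n <- nrow(x)
  k <- ncol(x)
  if (n < 2 || k < 2) abort("Need at least 2 blocks and 2 treatments.")

  stat_fn <- function(mat) {
    rk <- t(apply(mat, 1, rank)) # midranks for ties
    rj <- colSums(rk)
    12 / (n * k * (k + 1)) * sum(rj^2) - 3 * n * (k + 1)
  }
  stat <- stat_fn(x)
  p_asym <- pchisq(stat, df = k - 1, lower.tail = FALSE)

  p_exact <- NA_real_
  if (exact) {
    if (n * k > 20) {
      abort("Exact permutation p-value is only supported for n * k <= 20.")
    }
    p_exact <- exact_friedman_p(x, stat)
  }

  tibble(
    statistic = stat, df = k - 1, p_value = p_asym, p_exact = p_exact,
    n_blocks = n, n_treatments = k
  )
}

#' @rdname friedman_test
#' @export
friedman_test.data.frame <- function(x, response, treatment, block,
                                     exact = FALSE, ...) {
  d <- dplyr::transmute(
    x,
    resp = {{ response }},
    treatment = as.character({{ treatment }}),
    block = as.character({{ block }})
  )
  cnt <- dplyr::count(d, .data$block, .data$treatment)
  blocks <- unique(d$block)
  treatments <- unique(d$treatment)
  if (nrow(cnt) != length(blocks) * length(treatments) || any(cnt$n != 1)) {
    abort("Each block x treatment cell must be observed exactly once (complete blocks).")
  }
  wide <- tidyr::pivot_wider(d, names_from = "treatment", values_from = "resp")
  m <- as.matrix(wide[, treatments, drop = FALSE])
  rownames(m) <- wide$block
  friedman_test.matrix(m, exact = exact)
}

# all permutations of 1..k, one per row (k! rows)
permutations_of <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(v) {
    cbind(v, sub + (sub >= v))
  }))
}

# Exact permutation p-value of the Friedman statistic by full enumeration
# of all (k!)^n equally likely within-block rearrangements, computed as a
# dynamic-programming convolution over blocks of the joint distribution of
# the first k-1 treatment rank sums (the last is fixed by the block total).
exact_friedman_p <- function(x, stat_obs) {
  n <- nrow(x)
  k <- ncol(x)
  perms <- permutations_of(k)
  block_total <- n * k * (k + 1) / 2

  # distribution over states: named counts, key = rank sums of treatments 1..k-1
  dist <- stats::setNames(1, paste(rep(0, k - 1), collapse = "_"))
  for (b in seq_len(n)) {
    rk <- rank(x[b, ]) # midranks
    new <- new.env(hash = TRUE, parent = emptyenv())
    states <- do.call(rbind, strsplit(names(dist), "_", fixed = TRUE))
    states <- matrix(as.numeric(states), nrow = length(dist))
    for (p in seq_len(nrow(perms))) {
      contrib <- rk[perms[p, ]][seq_len(k - 1)]
      upd <- sweep(states, 2, contrib, "+")
      keys <- apply(upd, 1, paste, collapse = "_")
      for (i in seq_along(keys)) {
        prev <- if (is.null(new[[keys[i]]])) 0 else new[[keys[i]]]
        new[[keys[i]]] <- prev + dist[[i]]
      }
    }
    dist <- unlist(as.list(new))
  }

  states <- do.call(rbind, strsplit(names(dist), "_", fixed = TRUE))
  states <- matrix(as.numeric(states), nrow = length(dist))
  rk_sums <- cbind(states, block_total - rowSums(states))
  stats_all <- 12 / (n * k * (k + 1)) * rowSums(rk_sums^2) - 3 * n * (k + 1)
  sum(dist[stats_all >= stat_obs - 1e-10]) / sum(dist)
}

#' Pearson correlation with its t-based p-value
#'
#' Product-moment correlation with `df = n - 2` and a two-sided p-value
#' from the t transform, as a one-row tibble.
#'
#' @param data A data frame.
#' @param x,y Bare column names.
#' @return A tibble: `r`, `df`, `p_value`, `n`.
#' @export
pearson_cor <- function(data, x, y) {
  d <- dplyr::transmute(data, x = {{ x }}, y = {{ y }})
  d <- d[complete.cases(d), ]
  n <- nrow(d)
  if (n < 3) abort("Pearson correlation needs at least 3 complete pairs.")
  if (sd(d$x) == 0 || sd(d$y) == 0) {
    warn("Zero variance in x or y: correlation undefined.")
    return(tibble(r = NA_real_, df = n - 2L, p_value = NA_real_, n = n))
  }
  ct <- cor.test(d$x, d$y, method = "pearson", alternative = "two.sided")
  tibble(
    r = unname(ct$estimate), df = unname(ct$parameter),
    p_value = ct$p.value, n = n
  )
}

#' Cow-adjusted mixed regression
#'
#' Regresses `y` on `x` with a random intercept per cow (REML): the slope
#' is estimated from the pooled within- and between-cow information while
#' cow-level shifts are absorbed by the random intercept. The marginal
#' R-squared is the Nakagawa-Schielzeth ratio of fixed-effect variance to
#' total variance, `var(X beta) / (var(X beta) + var_cow + var_resid)`.
#'
#' @param data A data frame.
#' @param y,x Bare column names of response and regressor.
#' @param cow Bare column name of the animal identifier (default `cow_id`).
#' @return An object of class `cow_regression` with elements `slope`, `se`,
#'   `intercept`, `r2_marginal`, `p_value`, `n`. Use [tidy()], [glance()],
#'   [autoplot()].
#' @export
#' @examples
#' trial <- simulate_trial(trial_config(seed = 5))
#' mg <- dplyr::filter(derive_balance(trial$balance), element == "Mg")
#' fit <- cow_adjusted_regression(mg, absorption_g_d, ndf_intake_kg_d)
#' glance(fit)
cow_adjusted_regression <- function(data, y, x, cow = cow_id) {
  d <- dplyr::transmute(
    data, y = {{ y }}, x = {{ x }}, cow = factor({{ cow }})
  )
  if (any(!complete.cases(d))) d <- d[complete.cases(d), ]
  if (nlevels(droplevels(d$cow)) < 2) abort("At least two cows are required.")
  per_cow <- dplyr::count(d, .data$cow)
  if (any(per_cow$n < 2)) {
    abort(sprintf("Every cow needs >= 2 observations (cow %s has %d).",
                  per_cow$cow[per_cow$n < 2][1], min(per_cow$n)))
  }
  if (sd(d$x) == 0) abort("`x` is constant: slope is not identifiable.")

  m <- fit_lmer_quietly(y ~ x + (1 | cow), d)
  sm <- summary(m)$coefficients
  vc <- as.data.frame(lme4::VarCorr(m))
  cow_var <- vc$vcov[vc$grp == "cow"][1]
  resid_var <- sigma(m)^2
  var_fixed <- var(model.matrix(m) %*% lme4::fixef(m))[1, 1]
  denom <- var_fixed + cow_var + resid_var
  r2m <- if (denom > 0) min(1, max(0, var_fixed / denom)) else NA_real_

  structure(
    list(
      model = m,
      slope = unname(sm["x", "Estimate"]),
      se = unname(sm["x", "Std. Error"]),
      intercept = unname(sm["(Intercept)", "Estimate"]),
      p_value = unname(sm["x", "Pr(>|t|)"]),
      df = unname(sm["x", "df"]),
      r2_marginal = r2m,
      cow_var = cow_var, resid_var = resid_var, var_fixed = var_fixed,
      n = nrow(d), n_cows = nlevels(droplevels(d$cow)),
      x_name = rlang::as_label(rlang::enquo(x)),
      y_name = rlang::as_label(rlang::enquo(y)),
      data = d
    ),
    class = "cow_regression"
  )
}

#' @export
print.cow_regression <- function(x, ...) {
  cat(sprintf(
    "<cow_regression> %s ~ %s + (1 | cow): slope %.4g +/- %.4g (p = %.3g), marginal R2 %.3f\n",
    x$y_name, x$x_name, x$slope, x$se, x$p_value, x$r2_marginal
  ))
  invisible(x)
}

#' @rdname cow_adjusted_regression
#' @param x A `cow_regression`.
#' @param ... Unused.
#' @method tidy cow_regression
#' @export
tidy.cow_regression <- function(x, ...) {
  tibble(
    term = c("(Intercept)", x$x_name),
    estimate = c(x$intercept, x$slope),
    std.error = c(NA_real_, x$se),
    df = c(NA_real_, x$df),
    p.value = c(NA_real_, x$p_value)
  )
}

#' @rdname cow_adjusted_regression
#' @method glance cow_regression
#' @export
glance.cow_regression <- function(x, ...) {
  tibble(
    slope = x$slope, se = x$se, intercept = x$intercept,
    r2_marginal = x$r2_marginal, p_value = x$p_value,
    n = x$n, n_cows = x$n_cows
  )
}
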