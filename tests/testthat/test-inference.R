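# A balanced 6-cow x 3-period crossover table for inference tests
crossover_table <- function(seed = 1, diet_eff = c(A = 0, B = 0, C = 0),
                            sd = 1) {
  withr::with_seed(seed, {
    design <- generate_design(trial_config(seed = seed),
                              diets = names(diet_eff))
    design |>
      dplyr::mutate(
        y = 10 + diet_eff[diet] +
          c(0, 0.5, -0.5)[period] +
          rnorm(6, 0, 1.5)[as.integer(factor(cow_id))] +
          rnorm(dplyr::n(), 0, sd)
      )
  })
}

test_that("additive diet effects are recovered exactly as lsmean differences", {
  tbl <- crossover_table(seed = 2, diet_eff = c(A = 0, B = 2, C = 5), sd = 0.3)
  fit <- crossover_anova(tbl, y, cow = cow_id, method = "fixed")
  ls <- fit$lsmeans
  expect_equal(ls$lsmean[ls$diet == "B"] - ls$lsmean[ls$diet == "A"], 2,
               tolerance = 0.3 * 3) # noisy recovery, same contrast structure
  # with no residual noise the recovery is exact
  tbl0 <- crossover_table(seed = 3, diet_eff = c(A = 0, B = 2, C = 5), sd = 0)
  fit0 <- suppressWarnings(crossover_anova(tbl0, y, method = "fixed"))
  ls0 <- fit0$lsmeans
  d_ba <- ls0$lsmean[ls0$diet == "B"] - ls0$lsmean[ls0$diet == "A"]
  d_ca <- ls0$lsmean[ls0$diet == "C"] - ls0$lsmean[ls0$diet == "A"]
  d_cb <- ls0$lsmean[ls0$diet == "C"] - ls0$lsmean[ls0$diet == "B"]
  expect_equal(c(d_ba, d_ca, d_cb), c(2, 5, 3), tolerance = 1e-10)
})

test_that("the crossover F statistic matches a design-matrix projection oracle", {
  tbl <- crossover_table(seed = 11, sd = 1)
  fit <- crossover_anova(tbl, y, method = "fixed")

  X1 <- model.matrix(~ factor(diet) + factor(period) + factor(cow_id), tbl)
  X0 <- model.matrix(~ factor(period) + factor(cow_id), tbl)
  rss <- function(X) sum(lm.fit(X, tbl$y)$residuals^2)
  df2 <- nrow(tbl) - qr(X1)$rank
  f_oracle <- ((rss(X0) - rss(X1)) / 2) / (rss(X1) / df2)
  p_oracle <- pf(f_oracle, 2, df2, lower.tail = FALSE)

  diet_row <- dplyr::filter(fit$anova, term == "diet")
  expect_equal(diet_row$statistic, f_oracle, tolerance = 1e-8)
  expect_equal(diet_row$p_value, p_oracle, tolerance = 1e-8)
  expect_identical(diet_row$df2, df2)

  # the REML random-animal fit agrees on the balanced design
  fit_r <- crossover_anova(tbl, y, method = "random")
  expect_equal(dplyr::filter(fit_r$anova, term == "diet")$statistic,
               f_oracle, tolerance = 1e-3)
})

test_that("duplicated cow x period rows are rejected", {
  tbl <- crossover_table(seed = 5)
  expect_error(crossover_anova(dplyr::bind_rows(tbl, tbl[1, ]), y),
               "Duplicated cow x period")
})

test_that("Tukey contrasts match the studentized-range distribution", {
  tbl <- crossover_table(seed = 7, diet_eff = c(A = 0, B = 1, C = 2))
  fit <- crossover_anova(tbl, y, method = "fixed")
  tc <- tukey_contrasts(fit)
  k <- nrow(fit$lsmeans)
  p_oracle <- ptukey(abs(tc$t_ratio) * sqrt(2), k, tc$df, lower.tail = FALSE)
  expect_equal(tc$p_adj, p_oracle, tolerance = 1e-8)
  # family-wise adjustment can only increase p
  for (seed in c(1, 2, 9)) {
    tc_i <- tukey_contrasts(crossover_anova(crossover_table(seed = seed), y))
    expect_true(all(tc_i$p_adj >= tc_i$p_value - 1e-12))
  }
})

test_that("Friedman statistic has its closed forms, bounds and invariances", {
  # no discrimination: every treatment identical within each block
  flat <- matrix(rep(c(3, 3, 3), 4), nrow = 4, byrow = TRUE)
  f0 <- friedman_test(flat)
  expect_equal(f0$statistic, 0, tolerance = 1e-12)
  expect_equal(f0$p_value, 1, tolerance = 1e-12)

  # consistent ordering in all 4 blocks: the k = 3 maximum, chi2 = 2n = 8
  ord <- matrix(rep(c(1, 2, 3), 4), nrow = 4, byrow = TRUE)
  expect_equal(friedman_test(ord)$statistic, 8, tolerance = 1e-12)

  withr::with_seed(13, {
    for (i in 1:10) {
      m <- matrix(rnorm(12), 4, 3)
      f <- friedman_test(m)
      expect_true(f$statistic >= 0 && f$statistic <= 8 + 1e-12)
      # invariant under within-block monotone transforms
      expect_equal(friedman_test(exp(m))$statistic, f$statistic,
                   tolerance = 1e-12)
      # tie-free data agree exactly with the reference implementation
      ref <- stats::friedman.test(m)
      expect_equal(f$statistic, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(f$p_value, ref$p.value, tolerance = 1e-12)
    }
  })

  expect_error(friedman_test(matrix(c(1, NA, 2, 3, 4, 5), 2, 3)), "missing")
})

test_that("the exact Friedman p matches a brute-force enumeration oracle", {
  withr::with_seed(21, m <- matrix(rnorm(12), 4, 3))
  f <- friedman_test(m, exact = TRUE)

  # independent oracle: loop over all 6^4 = 1296 within-block rearrangements
  perms <- rbind(
    c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1)
  )
  stat_of <- function(mat) {
    rk <- t(apply(mat, 1, rank))
    12 / (4 * 3 * 4) * sum(colSums(rk)^2) - 3 * 4 * 4
  }
  idx <- expand.grid(1:6, 1:6, 1:6, 1:6)
  stats_all <- apply(idx, 1, function(ii) {
    stat_of(rbind(m[1, perms[ii[1], ]], m[2, perms[ii[2], ]],
                  m[3, perms[ii[3], ]], m[4, perms[ii[4], ]]))
  })
  p_oracle <- mean(stats_all >= f$statistic - 1e-10)
  expect_equal(f$p_exact, p_oracle, tolerance = 1e-12)
  # the chi-square approximation is coarse at n = 4 but consistent
  expect_lt(abs(f$p_value - f$p_exact), 0.2)
})

test_that("Pearson correlations carry df = n - 2 and the exact t-transform p", {
  d <- tibble::tibble(x = 1:12, y = 2 * (1:12) + 1)
  r1 <- pearson_cor(d, x, y)
  expect_equal(r1$r, 1, tolerance = 1e-12)
  expect_identical(r1$df, 10L)

  withr::with_seed(3, d2 <- tibble::tibble(x = rnorm(12), y = rnorm(12)))
  r2 <- pearson_cor(d2, x, y)
  tstat <- r2$r * sqrt(10) / sqrt(1 - r2$r^2)
  expect_equal(r2$p_value, 2 * pt(-abs(tstat), 10), tolerance = 1e-12)
  # affine invariance up to sign
  r3 <- pearson_cor(dplyr::mutate(d2, x = -3 * x + 2, y = 0.5 * y - 7), x, y)
  expect_equal(abs(r3$r), abs(r2$r), tolerance = 1e-12)

  expect_warning(rz <- pearson_cor(tibble::tibble(x = rep(1, 5), y = rnorm(5)),
                                   x, y), "Zero variance")
  expect_true(is.na(rz$r))
  expect_error(pearson_cor(d[1:2, ], x, y), "at least 3")
})

test_that("cow-adjusted regression collapses to OLS without between-cow variance", {
  withr::with_seed(17, {
    d <- tibble::tibble(
      cow_id = rep(paste0("cow", 1:4), each = 3),
      x = rnorm(12), e = rnorm(12, 0, 0.5)
    ) |>
      dplyr::mutate(y = 1 + 2 * x + e) # no cow-level shifts
  })
  fit <- cow_adjusted_regression(d, y, x)
  ols <- lm(y ~ x, data = d)
  expect_equal(fit$slope, unname(coef(ols)[2]), tolerance = 1e-8)
  # marginal R2 equals OLS R2 at zero random variance
  expect_equal(fit$cow_var, 0, tolerance = 1e-10)
  r2_ols <- var(fitted(ols)) / (var(fitted(ols)) + sigma(ols)^2)
  expect_equal(fit$r2_marginal, r2_ols, tolerance = 1e-6)
})

test_that("marginal R2 is the fixed share of the variance decomposition", {
  trial <- default_trial()
  mg <- derive_balance(trial$balance) |> dplyr::filter(element == "Mg")
  fit <- cow_adjusted_regression(mg, absorption_g_d, ndf_intake_kg_d)
  expect_equal(
    fit$r2_marginal,
    fit$var_fixed / (fit$var_fixed + fit$cow_var + fit$resid_var),
    tolerance = 1e-12
  )
  expect_true(fit$r2_marginal >= 0 && fit$r2_marginal <= 1)
})

test_that("degenerate regression inputs are rejected", {
  d <- tibble::tibble(cow_id = rep("cow1", 6), x = rnorm(6), y = rnorm(6))
  expect_error(cow_adjusted_regression(d, y, x), "two cows")
  d2 <- tibble::tibble(cow_id = c("a", "a", "b"), x = rnorm(3), y = rnorm(3))
  expect_error(cow_adjusted_regression(d2, y, x), ">= 2 observations")
  d3 <- tibble::tibble(cow_id = rep(c("a", "b"), each = 3), x = 1,
                       y = rnorm(6))
  expect_error(cow_adjusted_regression(d3, y, x), "constant")
})
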