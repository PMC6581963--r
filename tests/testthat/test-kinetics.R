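test_that("a noiseless single-profile fit recovers the exact log-linear curve", {
  prof <- make_profile(c0 = 0.5, k = 0.1)
  fit <- suppressWarnings(fit_decay(prof, phase = "liquid", model = "linear"))
  expect_equal(fit$coefficients$intercept, log(0.5), tolerance = 1e-10)
  expect_equal(fit$coefficients$slope, -0.1, tolerance = 1e-10)
  expect_lt(fit$resid_var, 1e-16)
})

test_that("the quadratic model collapses to the linear one when c = 0", {
  prof <- make_profile(c0 = 0.4, k = 0.08)
  lin <- suppressWarnings(fit_decay(prof, phase = "liquid", model = "linear"))
  quad <- suppressWarnings(fit_decay(prof, phase = "liquid", model = "quadratic"))
  expect_equal(quad$coefficients$quad, 0, tolerance = 1e-9)
  expect_equal(quad$coefficients$slope, lin$coefficients$slope,
               tolerance = 1e-8)
})

test_that("noiseless mixed fits match independent per-profile least squares", {
  trial <- cached("nl_cowre", {
    cfg <- noiseless_config(trial_config(seed = 4))
    cfg$cow_re_sd <- 0.1 # distinct per-animal intercepts, still noise-free
    simulate_trial(cfg, noiseless_calibration())
  })
  fit <- fit_decay(trial$profiles, phase = "liquid")
  liq <- dplyr::filter(trial$profiles, phase == "liquid", time_h > 0)
  ols <- liq |>
    dplyr::group_by(cow_id, diet) |>
    dplyr::group_modify(~ {
      m <- lm(log(conc) ~ time_h, data = .x)
      tibble::tibble(ols_int = coef(m)[1], ols_slope = coef(m)[2])
    }) |>
    dplyr::ungroup()
  fitted <- ols |>
    dplyr::left_join(fit$coefficients, by = "diet") |>
    dplyr::left_join(fit$ranef, by = "cow_id")
  expect_equal(fitted$intercept + fitted$a_cow, unname(fitted$ols_int),
               tolerance = 1e-6)
  expect_equal(fitted$slope, unname(fitted$ols_slope), tolerance = 1e-6)
})

test_that("fractional rates follow the closed forms and a dense-grid oracle", {
  lin <- fake_decay_fit(
    tibble::tibble(diet = "A", intercept = 0, slope = -0.12, quad = 0),
    model_type = "linear"
  )
  expect_equal(fractional_kp(lin)$frac_kp_per_h, 0.12, tolerance = 1e-12)

  quad <- fake_decay_fit(
    tibble::tibble(diet = "A", intercept = 0, slope = -0.02, quad = -0.001)
  )
  expect_equal(fractional_kp(quad, window = c(1, 23))$frac_kp_per_h,
               0.02 + 2 * 0.001 * 23, tolerance = 1e-12)

  # brute-force grid oracle over random descending quadratics
  set.seed(42)
  for (i in 1:20) {
    b <- -runif(1, 0.005, 0.05)
    c_ <- -runif(1, 0, 0.002)
    f <- fake_decay_fit(tibble::tibble(diet = "A", intercept = 0,
                                       slope = b, quad = c_))
    grid <- seq(1, 23, length.out = 1e4)
    oracle <- max(-(b + 2 * c_ * grid))
    expect_equal(fractional_kp(f, window = c(1, 23))$frac_kp_per_h, oracle,
                 tolerance = 1e-9)
  }

  rising <- fake_decay_fit(
    tibble::tibble(diet = "A", intercept = 0, slope = 0.01, quad = 0),
    model_type = "linear"
  )
  expect_error(fractional_kp(rising), "not clearing")
})

test_that("pool volume is the dose over the extrapolated zero-time concentration", {
  f <- fake_decay_fit(
    tibble::tibble(diet = "A", intercept = log(0.1), slope = -0.1, quad = 0),
    model_type = "linear"
  )
  doses <- tibble::tibble(cow_id = "cow1", diet = "A", dose_g = 10)
  expect_equal(pool_volume(f, doses)$volume, 100, tolerance = 1e-12)

  # extrapolated C0 numerically equal to the dose -> one unit of volume
  f2 <- fake_decay_fit(
    tibble::tibble(diet = "A", intercept = log(10), slope = -0.1, quad = 0),
    model_type = "linear"
  )
  expect_equal(pool_volume(f2, doses)$volume, 1, tolerance = 1e-12)
  expect_error(pool_volume(f, dplyr::mutate(doses, dose_g = -1)), "positive")
})

test_that("a noiseless trial is recovered to ~1e-6 relative error throughout", {
  trial <- noiseless_trial()
  est <- estimate_kinetics(trial$profiles)
  j <- dplyr::inner_join(est, trial$truth, by = c("cow_id", "diet"))
  liq <- dplyr::filter(j, phase == "liquid")
  sol <- dplyr::filter(j, phase == "solid")
  expect_lt(max(abs(liq$volume / liq$vol_liquid - 1)), 1e-6)
  expect_lt(max(abs(liq$frac_kp_per_h / liq$kp_liquid - 1)), 1e-6)
  expect_lt(max(abs(sol$volume / sol$vol_solid - 1)), 1e-6)
  expect_lt(max(abs(sol$frac_kp_per_h / sol$kp_solid - 1)), 1e-6)
})

test_that("kinetics summaries have the right cardinality, units and identities", {
  est <- cached("est_default", estimate_kinetics(default_trial()$profiles))
  expect_identical(nrow(dplyr::filter(est, phase == "liquid")), 12L)
  expect_identical(nrow(dplyr::filter(est, phase == "solid")), 12L)
  expect_equal(est$abs_kp, est$volume * est$frac_kp_per_h, tolerance = 1e-12)
  expect_setequal(unique(est$volume_units[est$phase == "liquid"]), "l")
  expect_setequal(unique(est$volume_units[est$phase == "solid"]), "kg_dm")

  # the low-fibre diet has the smallest liquid pool
  means <- est |>
    dplyr::filter(phase == "liquid") |>
    dplyr::group_by(diet) |>
    dplyr::summarise(v = mean(volume))
  expect_lt(means$v[means$diet == "Fibre-"],
            min(means$v[means$diet != "Fibre-"]))
})

test_that("malformed profiles are rejected with pointers", {
  prof <- make_profile()
  bad <- prof; bad$conc[3] <- -1
  expect_error(fit_decay(bad, "liquid"), "Non-positive marker concentration")
  short <- prof[1, ]
  expect_error(fit_decay(short, "liquid"), "fewer than 2")
  fac <- prof
  fac$diet <- factor(fac$diet, levels = c("A", "B"))
  expect_error(fit_decay(fac, "liquid"), "no observations: B")
})
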