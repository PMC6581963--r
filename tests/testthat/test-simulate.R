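test_that("noiseless liquid curves follow the closed-form dilution decay", {
  # force Vol_L = 100 l for every cow and k_L = 0.10/h
  cal <- noiseless_calibration()
  cal$vol_liquid_intercept <- 100
  cal$vol_liquid_ndfi_slope <- 0
  cal$true_frac_kp_liquid <- 0.10
  cfg <- noiseless_config(trial_config(seed = 1))
  prof <- generate_marker_profiles(generate_design(cfg), cal, cfg)

  liq5 <- dplyr::filter(prof, phase == "liquid", time_h == 5)
  expect_equal(liq5$conc, rep(0.0725 * exp(-0.5), nrow(liq5)), tolerance = 1e-12)
  # pre-dose background is zero
  expect_true(all(dplyr::filter(prof, time_h == 0)$conc == 0))
  # sampling grid is exactly the schedule
  expect_identical(
    sort(unique(prof$time_h)), c(0, 1, 2, 3, 5, 7, 10, 16, 23)
  )
})

test_that("profiles are emitted only for cannulated cows and decay monotonically", {
  trial <- noiseless_trial()
  cann <- dplyr::filter(trial$design, cannulated)$cow_id
  expect_setequal(unique(trial$profiles$cow_id), unique(cann))

  dec <- trial$profiles |>
    dplyr::filter(phase == "liquid", time_h > 0) |>
    dplyr::group_by(cow_id, period) |>
    dplyr::summarise(mono = all(diff(conc) < 0), .groups = "drop")
  expect_true(all(dec$mono))
})

test_that("log-residual noise matches the configured SD across replicate profiles", {
  # ~200 liquid profiles: 12 cannulated-cow cells x 17 seeds
  resids <- unlist(lapply(1:17, function(seed) {
    cfg <- trial_config(seed = seed)
    trial <- simulate_trial(cfg)
    liq <- dplyr::filter(trial$profiles, phase == "liquid", time_h > 0)
    j <- dplyr::inner_join(liq, trial$truth,
                           by = c("cow_id", "period", "diet"))
    log(j$conc) - (log(j$dose_g / j$vol_liquid) - j$kp_liquid * j$time_h)
  }))
  expect_gt(length(resids), 190 * 8)
  expect_lt(abs(sd(resids) - 0.15) / 0.15, 0.10)
})

test_that("balance generation is exact at zero noise and conserves mass always", {
  cal <- noiseless_calibration()
  cal$dmi_mean <- rep(20, 3)
  cfg <- noiseless_config(trial_config(seed = 2))
  bal <- generate_balance(generate_design(cfg), cal, cfg)$balance

  mg <- dplyr::filter(bal, element == "Mg")
  expect_equal(mg$intake_g_d, rep(46, nrow(mg)), tolerance = 1e-12)
  # urinary Mg = urine volume x molar concentration (2.07 mmol/l on Fibre-)
  u <- dplyr::filter(mg, diet == "Fibre-")
  expect_equal(u$urine_g_d, rep(28 * 2.07 * 24.305 / 1000, nrow(u)),
               tolerance = 1e-12)

  # conservation holds exactly for every record at default noise too
  noisy <- default_trial()$balance
  der <- derive_balance(noisy)
  expect_equal(der$intake_g_d - der$faecal_g_d, der$absorption_g_d,
               tolerance = 1e-12)
})

test_that("generated trials are deterministic and seed-sensitive", {
  a <- simulate_trial(trial_config(seed = 33))
  b <- simulate_trial(trial_config(seed = 33))
  expect_identical(a$profiles, b$profiles)
  expect_identical(a$balance, b$balance)
  expect_identical(a$rumen, b$rumen)
  c_ <- simulate_trial(trial_config(seed = 34))
  expect_false(identical(a$profiles, c_$profiles))
})

test_that("impossible excretion draws abort after bounded resampling", {
  cal <- default_calibration()
  cal$k_absorbability_pct <- rep(200, 3) # faecal K would always be negative
  cfg <- noiseless_config(trial_config(seed = 1))
  expect_error(generate_balance(generate_design(cfg), cal, cfg),
               "non-negative excretions")
})

test_that("non-positive calibration volumes are rejected", {
  cal <- default_calibration()
  cal$vol_solid_mean[1] <- -1
  cfg <- trial_config(seed = 1)
  expect_error(generate_marker_profiles(generate_design(cfg), cal, cfg),
               "strictly positive")
})
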