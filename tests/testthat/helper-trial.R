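# Shared fixtures, built in code and cached per test run.

.trial_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.trial_cache[[key]])) .trial_cache[[key]] <- force(expr)
  .trial_cache[[key]]
}

default_trial <- function(seed = 1) {
  cached(paste0("default", seed), simulate_trial(trial_config(seed = seed)))
}

noiseless_trial <- function(seed = 1) {
  cached(
    paste0("noiseless", seed),
    simulate_trial(noiseless_config(trial_config(seed = seed)),
                   noiseless_calibration())
  )
}

# hand-built single-profile tibble for exact closed-form fits
make_profile <- function(times = c(1, 2, 3, 5, 7, 10, 16, 23),
                         c0 = 0.5, k = 0.1, quad = 0,
                         cow = "cow1", diet = "A", period = 1,
                         phase = "liquid", dose = 10) {
  units <- if (phase == "liquid") "g_per_l" else "g_per_kg_dm"
  tibble::tibble(
    cow_id = cow, period = period, diet = diet, phase = phase,
    time_h = times,
    conc = c0 * exp(-k * times + quad * times^2),
    conc_units = units,
    dose_g = dose
  )
}

# minimal decay_fit stand-in for closed-form rate/volume identities
fake_decay_fit <- function(coef_tbl, model_type = "quadratic",
                           phase = "liquid", window = c(1, 23),
                           ranef = NULL) {
  structure(
    list(
      coefficients = coef_tbl, model_type = model_type, phase = phase,
      time_window = window,
      ranef = ranef %||% tibble::tibble(cow_id = "cow1", a_cow = 0)
    ),
    class = "decay_fit"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
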