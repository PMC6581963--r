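# rumenkinetics

Rumen marker-dilution kinetics and mineral balance for lactating dairy
cattle, with the statistical layer of a 3×3 crossover trial.

Low-fibre, intensively managed herbage is a risk factor for
hypomagnesaemia (grass tetany). Beyond the classical potassium
antagonism, fibre intake shrinks the rumen liquid pool, and a smaller
pool appears to limit magnesium absorption across the rumen wall. This
package implements the full quantitative chain needed to study that
mechanism — for ruminant nutritionists running (or re-analysing)
cannulated-cow trials, and for methodologists who want a testbed with
known ground truth:

* **Marker-dilution kinetics.** Pulse doses of Co-EDTA (liquid phase) and
  Yb-labelled fibre (solid phase) wash out of the rumen as
  `log C(t) = log(D/V) − k t` (liquid) and with an additional negative
  quadratic term (solid). `fit_decay()` fits these curves as mixed models
  (per-diet intercepts and slopes, random intercept per animal, REML);
  `pool_volume()` recovers the pool as dose over extrapolated zero-time
  concentration (`V = D / exp(a_diet + a_cow)`), `fractional_kp()` the
  outflow rate `k` (steepest descending tangent for the quadratic solid
  model), and `abs Kp = V · k` exactly.
* **Mineral balance.** `derive_balance()` computes apparent absorption
  (`intake − faecal`), absorbability (% of intake) and retention
  (`absorption − urine − milk`) per cow × period × element;
  `mg_per_k_absorbed()` and `mg_solubility()` (liquid share of the total
  rumen Mg pool) cover the derived Mg quantities.
* **Crossover inference.** `crossover_anova()` (`Y = μ + Diet + Period +
  Animal + ε`, Animal random, Type III Wald F), `tukey_contrasts()`
  (Tukey–Kramer lsmean contrasts), `friedman_test()` (blocked rank χ²
  with exact permutation p by full enumeration), `pearson_cor()`, and
  `cow_adjusted_regression()` (random-intercept regression with
  Nakagawa–Schielzeth marginal R²).
* **Synthetic trials.** `simulate_trial()` generates complete trials
  (design, washout curves, balance, rumen chemistry) from a calibration
  of published effect sizes — 6 cows (4 cannulated), two stacked 3×3
  Latin squares, sampling at 1–23 h post-dose — with every generating
  parameter recorded, so the whole pipeline is testable end to end.
  `run_pipeline()` chains simulate → fit-kinetics → balance → analyze →
  report into a directory of CSVs plus a Markdown report.

The methods vignette (`vignettes/marker-dilution-methods.Rmd`) documents
the models, the calibration and its assumptions in detail.

## Worked example

```r
library(rumenkinetics)
library(dplyr)

trial <- simulate_trial(trial_config(seed = 42))

# rumen liquid volumes and passage rates per diet
est <- estimate_kinetics(trial$profiles)
est |> filter(phase == "liquid") |> group_by(diet) |>
  summarise(vol_l = mean(volume), frac_kp = mean(frac_kp_per_h))
#>   diet     vol_l frac_kp
#> 1 Fibre+    149.   0.108
#> 2 Fibre+CP  151.   0.113
#> 3 Fibre-    114.   0.114
```

The low-fibre diet carries ~25% less rumen liquid at a slightly faster
fractional turnover — the published pattern the calibration encodes.

```r
mg <- derive_balance(trial$balance) |> filter(element == "Mg")
crossover_anova(mg, absorption_g_d)
#> <crossover_anova> absorption_g_d (random animal effect), 18 obs
#>   term     df1   df2 statistic  p_value
#> 1 diet       2  8.00    28.6   0.000227
#> 2 period     2  8.00     0.711 0.520
#>   diet     lsmean    se    df lower upper
#> 1 Fibre-     5.59 0.780  11.5  3.88  7.30
#> 2 Fibre+    12.0  0.780  11.5 10.3  13.7
#> 3 Fibre+CP  10.8  0.780  11.5  9.05 12.5
```

Mg absorption is depressed by roughly 6 g/day on the low-fibre diet
(absorbability near 12% against 24–26% on the high-fibre diets at
~46 g/day Mg intake), while period
effects are negligible. The chain closes with the cow-adjusted
regression of estimated liquid volume on NDF intake:

```r
vols <- pool_volume(attr(est, "fits")$liquid) |> rename(vol_l = volume)
cow_adjusted_regression(inner_join(mg, vols, by = c("cow_id", "diet")),
                        vol_l, ndf_intake_kg_d)
#> <cow_regression> vol_l ~ ndf_intake_kg_d + (1 | cow):
#>   slope 9.372 +/- 1.024 (p = 3.61e-05), marginal R2 0.498
```

i.e. in this simulated trial each kg of daily NDF intake carries about
9.4 l of rumen liquid volume (a single 12-observation trial scatters
around the generating 11.8 l/kg). `autoplot()` methods draw the fitted
washout curves and regressions; `tidy()`/`glance()` return the usual
broom-style tibbles.

## Command line

A thin wrapper over the pipeline lives at
`inst/scripts/rumen-pipeline.R`:

```sh
Rscript inst/scripts/rumen-pipeline.R run-all --out out/ --seed 7
Rscript inst/scripts/rumen-pipeline.R validate --out out/
```

Subcommands `simulate`, `fit-kinetics`, `balance`, `analyze`, `report`
run the idempotent stages individually; exit code 2 flags validation
failures, 1 runtime failures.
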