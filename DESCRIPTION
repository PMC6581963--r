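Package: rumenkinetics
Title: Rumen Marker-Dilution Kinetics and Mineral Balance in Dairy Cattle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of rumen liquid- and solid-phase pool volumes and
    passage rates from pulse-dose marker washout curves (Co-EDTA for the
    liquid phase, Yb-labelled fibre for the solid phase) using mixed
    log-linear and log-quadratic decay models, computation of apparent
    mineral absorption, absorbability and retention from total-collection
    balance records, and the statistical layer of a 3x3 crossover trial:
    Type III Wald F tests with Tukey-Kramer contrasts, blocked Friedman
    tests with exact permutation p-values, Pearson correlations, and
    cow-adjusted mixed regressions with marginal R-squared. Includes a
    seeded synthetic-trial generator calibrated to published effect sizes
    linking neutral-detergent-fibre intake, rumen liquid volume and
    magnesium absorption, so the full pipeline is testable end to end
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
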