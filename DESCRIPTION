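Package: behavnet
Title: Conditional Gaussian Bayesian Networks for Health-Behavior Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Score-based learning, bootstrap model averaging, and simulation
    of conditional linear Gaussian Bayesian networks over mixed
    binary/continuous cohort data, aimed at health-behavior epidemiology
    (sleep, physical activity, adiposity, inflammation and glucose-regulation
    biomarkers, quality of life). Provides tier-constrained hill-climbing
    structure search maximizing a rescaled BIC, arc/direction strength
    estimation over bootstrap resamples with an L1-optimal significance
    threshold, conditional-distribution fitting with standard errors,
    Markov-blanket and d-separation reasoning, BIC/Bayes-factor network
    comparison, logic-sampling (forward sampling with rejection) prediction
    of intervention effects, and a calibrated synthetic-cohort generator for
    an overweight breast-cancer-survivor population.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grid,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
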