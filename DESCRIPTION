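Package: foodscape
Title: Mobile Food Environments, Fast-Food Visit Decisions, and
    Intervention Ranking on Synthetic Cities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to study how the food environments people move through
    shape their decisions to visit fast-food outlets. Provides a synthetic
    city and activity-based mobility generator; food-environment ratio
    metrics (radius and k-nearest-food-outlet) with per-user home and
    mobile exposure profiles; extraction of pre-lunch, full-day, and
    DMV decision contexts; a sparse fixed-effects logistic visit model
    with two-way (user and day) cluster-robust errors; a changepoint plus
    structural-time-series natural-experiment analysis of habitual context
    changes; ranking and evaluation of food-environment intervention
    strategies via model marginal effects; and latent Dirichlet allocation
    profiling of the venue composition of targeted areas.
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
    jsonlite,
    Matrix,
    purrr,
    Rcpp,
    readr,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
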