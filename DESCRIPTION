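Package: vcforge
Title: Virtual Patient Cohorts from Modular Bayesian Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Generates virtual patient cohorts from longitudinal clinical
    study data using a modular discrete Bayesian network. Variable groups are
    aggregated per visit with sparse autoencoders, discretized by supervised
    trees or univariate Gaussian mixtures, and modelled jointly with explicit
    missing-not-at-random indicator nodes under structural constraints.
    Virtual patients are drawn by ancestral sampling and screened with a
    conservative class-weighted random-forest filter; counterfactual
    interventions are simulated on the mutilated network. Includes a
    similarity evaluation suite (cross-validated standardized partial AUC,
    per-variable homogeneity tests) and a seeded synthetic cohort generator
    for end-to-end validation without access-restricted data.
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
    mclust,
    purrr,
    ranger,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
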