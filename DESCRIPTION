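Package: painbayes
Title: Bayesian Decision Modelling of Pain Perception and Placebo Analgesia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Grid-based Bayesian decision model of pain perception in
    cue-conditioning experiments. Builds mixture priors learned through
    conditioning, combines them with a Gaussian nociceptor likelihood,
    applies a maximum a posteriori decision rule and predicts visual
    analog scale (VAS) rating distributions for cued, uncued and placebo
    trials. Includes the unimodal no-learning and simple Bayesian
    competitor models, per-subject fitting of the expectation weight and
    prior dispersion, Bayes-factor model comparison on held-out ratings,
    two-cluster (Hartigan-Wong) analyses with a separation index, a
    Bayesian bimodality test, one-tailed rank and correlation tests, and
    a synthetic-cohort generator emulating two conditioning/placebo
    psychophysics experiments.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
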