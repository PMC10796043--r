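Package: hforest
Title: Honest Causal and Instrumental Forests for Heterogeneous
    Treatment Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Honest causal forests and instrumental-variable forests for
    estimating individualized, subgroup, and overall treatment effects in
    randomized experiments with imperfect compliance, modelled on
    lottery-design studies such as the Oregon Health Insurance Experiment.
    Forests are grown with an expected-mean-squared-error splitting
    criterion on locally centered data, with split points and leaf effects
    estimated on disjoint subsamples. Per-person effects are aggregated
    through augmented inverse-probability-weighted (AIPW) scores into
    survey-weighted, household-cluster-robust average and subgroup
    treatment effects. Includes heterogeneity diagnostics (best-linear-
    predictor calibration test, targeting operator characteristic curves
    and rank-weighted average treatment effects), a three-stage
    insurance-uptake decomposition, hyperparameter tuning by the R-loss,
    and a synthetic data generator with known ground truth that emulates a
    household-randomized lottery design.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    foreign,
    sandwich,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
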