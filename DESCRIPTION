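Package: diabclust
Title: Clinical-Variable Subtypes of Type 2 Diabetes: Clustering,
    Cross-Cohort Validation and Progression to Insulin Requirement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sex-stratified k-means stratification of people with type 2
    diabetes on five routine clinical variables (age at first visit, BMI,
    HbA1c, C-peptide, HDL-cholesterol), with gap-statistic selection of the
    number of clusters, naming of the five subtype archetypes (SIDD, SIRD,
    MOD, MD, MDH), cross-cohort validation by cluster-centre transfer with
    sensitivity/specificity and exact binomial confidence intervals, a
    composite time-to-insulin-requirement endpoint derived from longitudinal
    prescription and HbA1c records, and one-vs-rest Cox hazard ratios pooled
    across cohorts by DerSimonian-Laird random-effects meta-analysis. A
    calibrated synthetic multi-cohort generator emulates the cross-sectional
    cluster structure and longitudinal follow-up so the full pipeline can be
    exercised and tested without access to the restricted cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    cluster,
    withr,
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
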