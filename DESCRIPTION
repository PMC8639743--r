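Package: ypllg
Title: Spatial Clusters of Life-Expectancy Inequality from Individual
    Death Records
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies local inequalities in life expectancy from
    georeferenced individual death records. Computes years of potential
    life lost or gained (YPLLG) against cohort life tables, detects local
    clusters of short- and long-lived individuals with a distance-band
    Local Moran statistic under conditional-permutation inference with
    Bonferroni control, adjusts YPLLG with a median (least absolute
    deviations) regression on individual and neighborhood covariates, and
    assesses cluster robustness across repeated random subsets. A
    synthetic-data generator with planted spatial clusters makes every
    stage testable without confidential mortality data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RANN,
    quantreg,
    sp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
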