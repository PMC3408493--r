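Package: seasonscan
Title: Temporal Scan Statistics for Seasonality of Conception in Case-Control Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects temporal clusters of case conceptions in large
    birth-cohort time series with a one-dimensional Bernoulli scan
    statistic and Monte Carlo permutation inference. Provides overlapping
    multi-year section windows with Holm-Bonferroni family-wise error
    control, a synthetic cohort generator (daily conception process with
    secular case trend, implanted seasonal clusters, covariates, sibling
    structure and geographic strata), cluster-composition and birth-outcome
    logistic regressions, a circular day-of-year assortative-conception
    sibling test, and gestational-age descriptives.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
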