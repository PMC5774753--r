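Package: pewmachron
Title: PEWMA Count Time-Series Regression Under Radiocarbon Dating Uncertainty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how calibrated radiocarbon-date uncertainty
    affects Poisson Exponentially Weighted Moving Average (PEWMA) state-space
    regression of count time-series on palaeoenvironmental covariates.
    Provides calibration-curve input and synthesis, date calibration and
    back-calibration, order-constrained Gibbs sampling of calendar ages,
    monotone age-depth models, generators for synthetic palaeoenvironmental
    series and PEWMA-driven count series, a maximum-likelihood PEWMA filter
    with corrected-AIC model comparison, and an experiment engine that
    measures hit-rate distributions over chronological bootstrap ensembles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
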