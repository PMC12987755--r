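Package: ipdtrend
Title: Trend Estimation in the 2PL Model Under Item Parameter Drift
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating ability trends across two time points from
    dichotomous item responses under the two-parameter logistic (2PL) model
    when a sparse subset of common items drifts. Implements concurrent and
    fixed calibration by marginal maximum likelihood, robust Haberman and
    Haebara linking with Lp and smooth-L0 losses, drift detection via the
    RMSD statistic (fixed and data-driven MAD cutoffs) and likelihood-ratio
    tests with one-step and iterative purification followed by
    partial-invariance re-estimation, and regularized joint estimation that
    minimizes a smooth Bayesian information criterion. A simulation engine
    generates 2PL responses with injected intercept drift and evaluates
    estimators by bias, RMSE and relative RMSE.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
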