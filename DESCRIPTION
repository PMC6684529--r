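Package: eslreg
Title: Robust Linear Regression with the Exponential Squared Loss
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Robust estimation of linear regression coefficients by maximizing
    an exponential squared loss (ESL) criterion, with a data-driven tuning
    parameter chosen by minimizing the determinant of the estimator's sandwich
    asymptotic covariance over a feasibility set built from a pseudo-outlier
    rule. Includes a high-breakdown MM initial estimator, percentile bootstrap
    confidence intervals, a Monte-Carlo harness comparing ESL against ordinary
    least squares under heavy-tailed contamination, and generators for
    simulated two-arm randomized-trial data with non-normal residuals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tibble,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS,
    yaml,
    optparse,
    withr
Config/testthat/edition: 3
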