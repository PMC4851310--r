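Package: gfwer
Title: Generalized Family-Wise Multiplicity Corrections via Order Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Family-wise error rate corrections for large-scale testing that
    remain calibrated when the null distribution of p-values departs from
    uniform. The negative-log-transformed p-values are modelled with a
    flexible parametric null (gamma, beta-on-p, or chi-squared), the
    order-statistic density of any ranked result is derived, and
    experiment-wise p-values and significance thresholds are computed as
    tail integrals of that density, generalizing the Dunn-Sidak correction.
    Includes moment and maximum-likelihood estimation of the null model with
    a parametric-bootstrap goodness-of-fit test, effective-number-of-tests
    estimation from marker correlation matrices for correlated (e.g. linkage
    disequilibrium) settings, a Monte Carlo engine for type-I-error
    calibration studies, and an end-to-end workflow for association-study
    result tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    fitdistrplus
Config/testthat/edition: 3
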