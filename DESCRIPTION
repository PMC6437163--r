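Package: mrpath
Title: Two-Sample Mendelian Randomisation with Pleiotropy Diagnostics and
    Mediation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Summary-statistic Mendelian randomisation estimators (Wald ratio,
    inverse-variance weighted, MR-Egger, weighted median, mode-based estimate,
    correlated-instrument IVW), heterogeneity and horizontal-pleiotropy
    diagnostics (Cochran's Q, I2, I2GX, per-instrument Q exclusion, a
    residual-sum-of-squares outlier test, funnel-plot data), multivariable
    Mendelian randomisation for mediation, individual-level genetic-score
    instrumental-variable analysis (two-stage logistic control-function and
    three-stage mediation estimators), and synthetic-data generators with
    known causal structure for calibration and recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
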