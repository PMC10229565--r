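Package: hrvtrans
Title: Cardiac Complexity Quantifiers and Depressive-Transition Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes complexity and variability quantifiers (mean interbeat
    interval, SDRR, Higuchi fractal dimension, multiscale sample entropy)
    from short RR-interval recordings, detects clinically defined depressive
    transitions from weekly symptom scores, tests within-subject
    pre-transition trends (Mann-Kendall) and between-group baseline
    differences (Mann-Whitney U, Cohen's d, logistic regression with
    Nagelkerke R-squared), and validates nonlinearity with IAAFT surrogate
    data. Includes a fully reproducible synthetic-cohort generator so every
    stage of the pipeline can be exercised without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
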