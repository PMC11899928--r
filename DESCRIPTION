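Package: pkdresp
Title: Individual-Patient Assessment of Tolvaptan Efficacy in ADPKD from
    Serial Kidney Volume Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the response of individual autosomal dominant
    polycystic kidney disease (ADPKD) patients to tolvaptan from serial MRI
    total kidney volume (TKV) measurements. Fits per-patient exponential TKV
    growth rates before and during treatment by log-linear least squares,
    classifies responders by exact one-dimensional k-means clustering of the
    change in growth rate, computes the Mayo Imaging Classification and
    CKD-EPI 2021 eGFR, compares eGFR decline slopes between response groups,
    runs the univariate and multivariate (logistic, VIF, stepwise AIC) group
    statistics with Benjamini-Hochberg correction, and performs the paired
    power calculation for the pre/during design. A seeded synthetic-cohort
    generator emulates the statistical structure of a tolvaptan-treated ADPKD
    cohort so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    car,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
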