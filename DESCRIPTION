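Package: cbconfound
Title: Confound Detection for Predictive Models via Counterbalancing with
    Oversampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects psychometric variables that partially explain the
    accuracy of a brain-structure based classifier of future binge
    drinking. Candidate variables are controlled by counterbalancing with
    oversampling, which resamples training subjects with replacement
    until the variable is identically distributed across outcome classes,
    severing the c -> y arm of a confounding pathway X <- c -> y. The
    change in mean balanced accuracy of a radial-kernel support vector
    machine before and after controlling each variable is screened in an
    exploration stage and validated on an independent holdout with
    permutation tests and Benjamini-Hochberg correction. Includes a
    synthetic cohort generator with known causal structure for
    calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    e1071,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
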