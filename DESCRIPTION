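Package: ttnorm
Title: Age-Related Normative Modelling of Male Total Testosterone
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds age-indexed normative reference models for serum total
    testosterone in healthy males from pooled cross-sectional data. Provides
    harmonization of multi-assay measurements to a common LC-MS/MS scale,
    rational-polynomial mean-curve fitting on the log-adjusted scale by
    Levenberg-Marquardt least squares, model-complexity selection by k-fold
    cross-validation, residual Gaussianity diagnostics, age-dependent
    standard-deviation estimation, centile tables, and z-score/centile
    scoring of individual measurements. A synthetic multi-study cohort
    generator with known ground truth makes the whole pipeline testable
    without access to source data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
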