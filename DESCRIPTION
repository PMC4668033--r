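Package: pinetaper
Title: Multilevel Mixed-Effects Stem Taper Modelling for Maritime Pine
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits the Kozak (2004) variable-exponent stem taper equation to
    hierarchical stem-analysis data (sections within trees within plots) by
    ordinary least squares, generalized least squares with a power-of-diameter
    variance function and continuous AR(1) within-tree correlation, and by
    two-level nonlinear mixed-effects estimation using first-order conditional
    expectation (FOCE) linearization under ML or REML.  Supports iterative
    EBLUP calibration of plot- and tree-level random effects from extra
    diameter measurements, subject-specific taper and volume prediction by
    numerical integration, merchantable-height inversion, model evaluation
    statistics (RMSE and percentage mean prediction error) with calibration-
    height sweeps and disaggregated error tables, random-effect sensitivity
    envelopes, and a hierarchical synthetic-data generator with a
    parameter-recovery harness.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0), nlme, minpack.lm, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
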