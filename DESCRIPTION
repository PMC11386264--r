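Package: fourierreg
Title: Fourier Series Nonparametric Regression with GCV Selection and LRT Inference
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Nonparametric regression with the Bilodeau cosine-series basis: each
    predictor contributes a constant, a linear trend and cosine harmonics up to a
    per-predictor oscillation parameter T. Provides minimum-norm least-squares
    estimation on the (intrinsically rank-deficient) stacked design, generalized
    cross-validation (GCV) search over uniform and per-predictor oscillation
    parameters, a likelihood-ratio-derived simultaneous F test and partial t tests
    for single coefficients (via Lagrange-multiplier constrained least squares),
    Glejser residual diagnostics, a seeded synthetic-data generator with known
    truth, and a command-line front end for reproducible fit/select/test runs.
License: MIT
Encoding: UTF-8
Imports: stats, utils, jsonlite, optparse
Suggests: testthat (>= 3.0.0), MASS, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
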