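Package: voidev
Title: Value of Information for the Development of Clinical Risk Prediction Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decision-theoretic assessment of uncertainty in clinical risk
    prediction models at the development stage.  Computes Bayesian
    (posterior-mean) net benefit, the expected value of perfect information
    (EVPI) and relative EVPI over a grid of risk thresholds by Monte Carlo
    sampling from the posterior distribution of "correct" risks, using the
    ordinary bootstrap, the Bayesian bootstrap (Dirichlet weights) or
    likelihood-based multivariate-normal coefficient sampling.  Harrell's
    bootstrap optimism correction for decision curves and the c-statistic is
    integrated into the same resampling loop.  Includes a synthetic
    logistic-model data generator with truncation and linear-spline covariate
    transforms, CSV/JSON input and output, and a thin command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
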