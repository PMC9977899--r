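Package: snllsem
Title: Separable Nonlinear Least Squares Estimation for Structural
    Equation Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Least squares estimation of linear structural equation
    models in RAM notation by variable projection (separable nonlinear
    least squares): only the directed parameters (loadings, regression
    paths) are optimized iteratively, while the undirected (co)variance
    parameters and mean parameters are recovered in closed form by a
    weighted linear solve.  Provides the model-implied moment machinery
    (GLS/ULS/user weight matrices, duplication matrix, half-
    vectorization), analytic gradients of the reduced objective, a
    trek-rule path-tracing engine that serves as an independent symbolic
    oracle for the implied covariance, an iteratively reweighted route
    towards maximum likelihood, a multivariate-normal data simulator,
    and a small convergence simulation study comparing the reduced and
    full least squares optimizations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
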