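Package: epodose
Title: Individualized Erythropoietin Dosing by Nonlinear Model Predictive
    Control of an Age-Structured Erythropoiesis Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates erythropoiesis in hemodialysis patients with a system
    of five coupled age-structured population equations (BFU-E, CFU-E,
    erythroblasts, marrow reticulocytes, circulating erythrocytes) driven by
    the plasma erythropoietin (EPO) concentration, and computes individualized
    EPO dosing schedules that stabilize hemoglobin inside a clinical target
    window. The hyperbolic state equations are discretized with a shifted
    Legendre spectral-Galerkin scheme and integrated by the implicit Euler
    method. Open-loop dose optimization minimizes a tracking-plus-control-cost
    functional with an exact discrete-adjoint gradient and a projected BFGS
    method with Armijo line search under box constraints; a receding-horizon
    (NMPC) loop applies the first optimized rate, advances the plant, and
    re-plans, with support for unforeseen events (bleedings, missed or
    erroneous administrations) and multi-week constant-rate periods. Includes
    a calibrated synthetic-patient generator, scenario and grid experiment
    drivers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    pracma,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
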