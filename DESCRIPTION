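Package: pwemu
Title: Emulation of 1D Pulmonary Pulse-Wave Propagation Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale toolkit for surrogate modelling of one-dimensional
    arterial pulse-wave propagation in bifurcating vascular networks. Provides
    a nonlinear hyperbolic blood-flow solver (Richtmyer two-step Lax-Wendroff)
    with Windkessel and structured-tree outflow boundary conditions, Sobol
    sequence experimental designs, principal-component reduction of pressure
    waveforms, Gaussian-process emulators (independent GPs on PCA scores, and a
    time-input GP with Kronecker-separable covariance), polynomial-chaos
    emulators fitted by ordinary least squares with variance-based Sobol
    sensitivity indices, and a pipeline comparing emulator variants on forward
    prediction and inverse parameter estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    lhs,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
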