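Package: woundfem
Title: Agent-Based and Continuum Force Models for Skin Contraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finite-element modelling of fibroblast-driven skin contraction
    with two interchangeable force descriptions: a smoothed-particle model in
    which every cell contributes the gradient of a Gaussian mollifier (a force
    dipole), and a continuum model forced by the gradient of a piecewise
    constant cell-density field. Provides P1 elements for the 1D Poisson
    problem and 2D plane-strain linear elasticity, closed-form 1D solutions
    (error-function dipole sums and a Dirichlet Green's function), upscaling
    algorithms between cell positions and cell densities, and the diagnostics
    used to establish consistency between the two models (L2/H1 norms, RMS
    nodal error, mesh-convergence rates, wound reduction ratios).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
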