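Package: porecapture
Title: Analytical Capture Rates for Particles in Nanopores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytical model of single-particle capture by a nanopore under
    the combined action of electrophoresis, electroosmosis, dielectrophoresis,
    and Brownian motion.  Solves the stationary radial advection-diffusion
    problem with a partially absorbing (Robin) pore boundary, splitting the
    mean capture time into an approach time and a barrier-controlled entrance
    time.  Includes closed-form and quadrature evaluation of the approach
    frequency, an Arrhenius/Eyring entrance model, concentration profiles, a
    Brownian-dynamics oracle for stochastic validation, blockade-trace
    statistics with a synthetic two-state trace generator, and packaged
    experiment scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
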