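Package: ctlsim
Title: Spatially Explicit Stochastic Simulation of CTL Control of Spreading Infections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Agent-based simulation of cytotoxic T lymphocytes (CTL)
    patrolling a two-dimensional toroidal tissue in which an infection
    spreads either diffusely or in virion-mediated clusters. Includes the
    deterministic mass-action comparators (a simple exponential model and an
    age-structured conjugate model with a fixed handling time), calibration
    routines for the surveillance rate and the uncontrolled growth rate,
    chemotactic persistent random walks, and estimation of the critical CTL
    density (the density driving half of stochastic infections extinct) by
    adaptive search and sigmoid fitting.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
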