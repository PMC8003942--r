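Package: rdgep
Title: Coupled Reaction-Diffusion Modelling of mRNA-siRNA Dynamics with
    Cluster-Based Expression Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates coupled two-species reaction-diffusion systems
    describing messenger RNA (mRNA) production, self-degradation, and
    siRNA-mediated coupled degradation on rectangular tissue domains
    under homogeneous Dirichlet or Neumann boundary conditions.  Ships a
    registry of fifteen parameterised kinetic models built from a library
    of constant, exponential, logarithmic, and spatial (tanh) rate
    functions, a dimension-generic finite-difference Laplacian, a
    boundary-consistency window for Gaussian-mixture initial states, and
    explicit fixed-step time integrators (forward Euler and classical
    Runge-Kutta) with CFL safeguards.  Downstream profiling discretises
    total mRNA abundance onto a four-cluster normalized 0-12 scale and
    matches observed gene cluster patterns against the model library by
    minimal L1 distance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    optparse
Config/testthat/edition: 3
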