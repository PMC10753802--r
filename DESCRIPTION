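Package: pathsampler
Title: Adaptive Path Collective Variables with Stabilized WTM-eABF Sampling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Enhanced-sampling toolkit for free-energy calculations along
    adaptive path collective variables.  Provides geometric path collective
    variables (progress and distance with analytic gradients), adaptive node
    updates with equidistant reparametrization, Langevin dynamics of a
    physical system coupled to an extended variable, metadynamics,
    well-tempered metadynamics and extended-system adaptive biasing force
    (eABF) bias engines including the hybrid WTM-eABF scheme, a stabilization
    correction for discontinuous collective variables, and free-energy
    estimators (bias inversion, mean-force integration, and MBAR reweighting
    of lambda-windowed trajectories).  Ships analytic test potentials
    (Muller-Brown and one-dimensional toys), a nudged-elastic-band reference
    optimizer, and frozen experiment presets for the Muller-Brown benchmark.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
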