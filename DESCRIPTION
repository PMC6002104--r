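Package: ringswarm
Title: Individual-Based Simulation of Collective Movement on a Periodic Ring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-time stochastic individual-based simulation of collective
    animal movement in one dimension with periodic boundary conditions.
    Individuals are self-propelled particles that switch travel direction at
    rates driven by zonal social forces (repulsion, alignment, attraction)
    weighted by truncated Gaussian interaction kernels, with five
    direction-dependent interaction rules controlling which neighbours
    contribute to each force. Includes a density-dependent movement speed
    variant, kernel density estimation of space-time aggregation patterns,
    order-parameter diagnostics (polarization, centroid drift, aggregation
    width), a catalog of named pattern-forming parameterisations, parameter
    sweep generators, and YAML configuration input/output. The inner
    simulation loop is implemented in C++ for speed; a pure-R stepper with an
    identical random-draw discipline is provided for verification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
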