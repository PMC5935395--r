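Package: flock3d
Title: Minimal Continuous Three-Dimensional Flocking with Speed Control,
    Noise and Delay
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Agent-based simulator for a minimal continuous model of
    three-dimensional collective motion: each self-propelled agent relaxes
    its speed toward a preferred value, repels neighbours with an
    inverse-square central force below a cutoff radius, and moves in a
    periodic box whose boundaries supply an effective weak attraction.
    Provides explicit midpoint and Euler integration with optional isotropic
    noise and delayed (time-lagged) forces, cell-list neighbour search,
    disordered and equilibrated-ordered initial conditions, order-parameter
    observables (polar efficiency, Binder cumulant, ensemble histograms),
    the symmetric two-agent encounter experiment with its alignment
    threshold angle, and reproducible drivers for order-transition, noise
    hysteresis and delay-sweep experiments.
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
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
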