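Package: actomyosim
Title: Agent-Based Simulation of Force Generation by Myosin Thick Filaments
    in Actin Bundles and Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Brownian-dynamics simulation of disorganized actomyosin
    structures: semiflexible bead-spring actin filaments, bipolar myosin
    thick filaments with configurable architecture (arm number, bare-zone
    length, arm spacing), and permanent cross-linkers, integrated with
    overdamped Langevin dynamics. Includes stochastic motor mechanochemistry
    (linear force-velocity walking, catch-bond unbinding), builders for
    two-filament, bundle and quasi-2D network systems, cross-section tension
    measurement with force-generation efficiency, and the contractile-unit
    overlap theory (critical overlap length, cooperative motor number Xi,
    predicted force) for interpreting bundle forces.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
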