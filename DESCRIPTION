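Package: polyfold
Title: Monte Carlo-Molecular Dynamics Simulation of Methylation-Driven
    Chromatin Folding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained simulation framework for Polycomb-mediated
    chromatin folding. Chromatin is modelled as a semi-flexible bead-spring
    polymer (FENE bonds, cosine bending, Weeks-Chandler-Andersen excluded
    volume) carrying a central H3K27-trimethylated locus with embedded
    Polycomb Response Elements (PREs). PRC1 occupancy of PREs is assigned
    probabilistically before each Langevin dynamics round; occupied PREs
    attract methylated beads through a truncated-shifted Lennard-Jones well.
    The package provides the hybrid Monte Carlo-molecular dynamics protocol,
    calibration of the attraction strength against dissociation constants
    (closed form and by many-particle binding simulation), system
    preparation and equilibration, experiment drivers (occupancy scans,
    affinity scans, post-replication dilution, PRE repositioning, controls),
    a stochastic anchored-loop model of PRE clustering, and trajectory
    observables (radius of gyration, locus volume, pairwise-distance maps,
    chain statistics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
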