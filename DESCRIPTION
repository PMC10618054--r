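Package: chromocycle
Title: Hi-C Restrained Polymer Simulation of Cell-Cycle Chromosome Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Data-driven coarse-grained modelling of chromosome structural
    dynamics across the cell cycle. Provides readers, writers and observables
    for contact-probability matrices (insulation scores and TAD boundaries,
    observed-over-expected enhanced contacts, A/B compartment eigenvectors),
    a reduced-unit Langevin bead-chain simulator with analytic forces,
    maximum-entropy calibration of pairwise biasing potentials against a
    target contact map, a landscape-switching protocol for non-equilibrium
    transitions between stage potentials, structural metrics (gyration
    geometry, asphericity, fluctuation matrices, free-energy landscapes),
    PCA-quantified transition pathways with linear-interpolation baselines,
    and a synthetic contact-map generator for desk-scale validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
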