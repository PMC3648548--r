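Package: allopath
Title: Allosteric Signaling Pathways from Perturbation-Based Markovian
    Transmission Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Residue-level analysis of allosteric signal transduction in
    multi-chain protein structures, aimed at pentameric ligand-gated ion
    channels. Builds a Markov transmission network from heavy-atom contact
    counts, propagates site-specific perturbations through the master
    equation dp/dt = p(M - I) to obtain probability-flux trajectories and
    equilibrium distributions, and extracts the k highest-probability
    signaling paths from perturbed extracellular residues to the channel
    gate with Yen's loopless k-shortest-path algorithm on the inverse-
    probability cost graph. Includes seeded generators for exactly
    C5-symmetric synthetic pentamer structures so the whole pipeline is
    testable without deposited coordinates, plus structure superposition
    (Kabsch RMSD) utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    Matrix,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    ggplot2,
    igraph,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
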