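Package: raftadhesion
Title: Lattice Monte Carlo and Mean-Field Models of Receptor-Ligand
    Binding and Lipid Raft Phase Behaviour in Cell-Substrate Adhesion
Version: 0.1.0
Authors@R:
    person("raftadhesion", "developers", email = "raftadhesion@example.org",
           role = c("aut", "cre"))
Description: Statistical-mechanical modelling of the adhesion of a
    fluctuating cell membrane, carrying lipid-raft patches and adhesion
    receptors, to a substrate presenting mobile or immobile ligands. The
    membrane is a square-lattice separation field with discretized Helfrich
    bending energy; receptors bind apposed ligands through a square-well
    potential, partition into rafts, and rafts interact through a
    nearest-neighbour contact energy. A Metropolis Monte Carlo engine with
    membrane height moves and protein/raft hopping samples the model;
    observables include the heat capacity per site (used to locate the
    homogeneous to phase-separated transition), the two-dimensional binding
    constant K = [RL]/([R][L]), and raft-partition statistics. A
    Bragg-Williams mean-field theory with a membrane-contact-probability
    binding term provides the corresponding phase-transition lines.
    Scenario generators reproduce the studied systems: mobile ligands on a
    supported bilayer and immobile ligands placed uniformly, randomly, or
    in rasterized circular clusters.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
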