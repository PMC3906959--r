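Package: ifnlattice
Title: Agent-Based Stochastic Simulation of Interferon Noise Propagation
Version: 1.0.0
Authors@R:
    person("ifnlattice", "developers", email = "ifnlattice@example.org",
           role = c("aut", "cre"))
Description: Multi-scale agent-based stochastic simulator of noise propagation
    through extracellular cytokine signaling. Virus-infected dendritic cells on
    a two-dimensional lattice stochastically assemble the IFN-beta enhanceosome
    and secrete IFN-beta; the cytokine diffuses between lattice boxes, binds
    type-I interferon receptors (IFNAR) on all cells, and drives noisy two-state
    (telegraph) induction of the interferon-stimulated gene DDX58. The package
    couples an exact per-cell Gillespie stochastic simulation algorithm to a
    lattice random-walk diffusion sweep by operator splitting, and computes the
    population observables that characterize the transient cell-to-cell
    variability: Fano-factor trajectories, expressing fractions, bound-receptor
    histograms, spatial category maps, and an autocrine/paracrine decomposition.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
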