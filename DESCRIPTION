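Package: cellmet
Title: Coevolution of Cellular Impermeability and Metabolism in Digital
    Organisms
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Agent-based digital-evolution simulator in which populations of
    organisms carrying Boolean logic-gate (NAND network) genomes coevolve
    cellular impermeability -- a membrane-like trait gating stochastic gene and
    energy exchange with a shared environment -- and metabolic proficiency at
    converting 8-bit food puzzles into processing energy.  Provides the genome
    model with insertion, deletion and pointer mutation operators, gene and
    energy transfer through environmental pools, a population engine with an
    energy economy, replication and density-dependent reward reduction,
    scenario presets for energy-rich and energy-poor environments, trace
    recording and correlation analysis, and a standalone directional-drift
    model of a trait that lowers its own mutation rate, with an exact
    Markov-chain oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
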