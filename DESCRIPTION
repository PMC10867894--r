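Package: pecsim
Title: Coarse-Grained Simulation of Polyelectrolyte Complex Coexistence and
    Solute Partitioning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A two-phase simulator for polyelectrolyte complexes (PECs) in
    equilibrium with a dilute supernatant. Implements a bead-spring model with
    a hydrophobicity-tunable Weeks-Chandler-Andersen pair potential, harmonic
    bonds and Coulomb electrostatics under Ewald summation; Langevin dynamics
    interleaved with grand-reaction Monte Carlo moves that exchange ions,
    water self-ions and weak-acid species with a virtual reservoir of
    prescribed pH and salt concentration; a pressure-composition protocol that
    locates the PEC volume fraction coexisting with the supernatant; and an
    analysis layer producing partition coefficients, titration curves,
    structure factors and demixing diagnostics.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    minpack.lm,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
SystemRequirements: C++17
RoxygenNote: 7.3.3
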