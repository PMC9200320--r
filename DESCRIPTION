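Package: flexidock
Title: Flexible Protein-Protein Docking with Temperature Replica-Exchange
    Monte Carlo
Version: 1.0.0
Authors@R: person("flexidock", "contributors", email = "flexidock@example.com",
    role = c("aut", "cre"))
Description: An induced-fit protein-protein docking engine. Couples rigid-body
    Monte Carlo moves with Backrub backbone moves over interface residues
    inside a temperature replica-exchange scheduler, scores candidates with a
    composite low-resolution energy (residue-pair-transform term, soft
    Lennard-Jones clash terms and backbone torsion statistics), refines them
    with a zero-temperature rigid-body quench, and evaluates predictions with
    CAPRI-style metrics (fnat, interface RMSD, ligand RMSD) and the
    bootstrapped expected-N5 success statistic. Ships a synthetic mini-protein
    fixture generator so the whole pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
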