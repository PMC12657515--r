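Package: qmmdock
Title: Hybrid QM/MM Rescoring of Protein-Ligand Docking Poses
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A self-contained engine for hybrid quantum-mechanics/molecular-
    mechanics (QM/MM) rescoring of protein-ligand docking poses. Implements
    primary/secondary system partitioning with hydrogen link atoms and
    charge-scaled electrostatic embedding, subtractive QM/MM energies,
    classical and hybrid MM-GBSA-style scoring with a generalized-Born/
    surface-area solvation surrogate, a Morse-like metal binding potential,
    pose clustering, selection, constrained optimization and refinement,
    symmetry-adapted RMSD redocking evaluation, and benchmark quality
    filtering. Ships pluggable QM backends (a mirror-MM oracle and a toy
    electronegativity-equalization engine) and a deterministic synthetic
    complex generator, so the whole scheme is testable at desk scale
    without external quantum chemistry or molecular mechanics programs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
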