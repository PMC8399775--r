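Package: SiteRescore
Title: Geometric Binding-Site Rescoring and Ensemble Docking Evaluation
    for GPCR Virtual Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stage-II virtual-screening rescoring toolkit built around a
    geometric binding-site fitness score: the mean, over the alpha carbons of a
    configurable binding-site residue set, of the minimum distance to any atom
    of a docked ligand pose. Provides readers for PDB/PDBQT receptor structures
    and multi-pose docking output, binding-site definitions with set algebra,
    AutoDock-style grid-box construction from contact residues, ROC/AUC
    enrichment analysis against true-positive/decoy libraries, geometric
    protein-ligand interaction analysis (hydrogen bonds, pi stacking, aromatic
    pose clusters), generic Hamiltonian Monte Carlo and Langevin samplers over
    pluggable potentials for receptor-ensemble generation at toy scale with
    RMSD/RMSF trajectory metrics, and a synthetic benchmark generator that
    builds labeled receptor/ligand libraries with known enrichment structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    igraph
Suggests:
    testthat (>= 3.0.0),
    optparse,
    bio3d,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
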