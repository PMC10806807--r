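Package: symstack
Title: Screw-Symmetry Ligand Stacking Toolkit for Fibril Docking
Version: 1.0.0
Authors@R: person("SymStack", "Developers", role = c("aut", "cre"),
    email = "symstack@example.org")
Description: Tools for docking workflows on helical (screw-symmetric) protein
    fibrils such as tau filaments. Derives the fibril's affine screw operator
    from a multi-chain structure by least-squares superposition of consecutive
    monomers, generates symmetry images of ligand poses, filters poses by a
    ligand-ligand clash rule, scores self-stacking with a united-atom 12-6
    Lennard-Jones term, extends fibrils periodically to suppress grid edge
    effects, refines stacks by rigid-body Metropolis Monte Carlo under a
    pluggable per-monomer energy backend, and computes virtual-screening
    enrichment statistics (enrichment factor, adjusted logAUC). Includes
    deterministic generators for synthetic helical fibrils, planar ligands,
    and labelled screen lists, plus readers and writers for PDB, SDF, MOL2,
    operator JSON, and xyzr pseudo-atom files, and a unified command-line
    interface.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
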