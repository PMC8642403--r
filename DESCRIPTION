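Package: ppirank
Title: Grid Featurization and 3D Convolutional Scoring of Protein-Protein
    Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Featurizes protein-protein interfaces from two-chain PDB
    structures onto multi-channel 3D grids (element densities, partial
    charges, intermolecular Coulomb and van der Waals energies, buried
    surface area, position-specific scoring matrices), stores grids and
    docking-quality target values (iRMSD, lRMSD, FNAT, DockQ, CAPRI class)
    in HDF5 datasets, trains a compact 3D convolutional network for
    classification or regression on the grids, and evaluates docking-model
    rankings with per-case hit-rate curves and cross-case success rates.
    Ships generators for synthetic toy dimers, rigid-body decoy sets and
    synthetic PSSM profiles so the full pipeline runs self-contained at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    rhdf5,
    Matrix,
    digest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
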