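# ppirank

Grid featurization and 3D convolutional scoring of protein-protein
interfaces, in R.

## What it is for

Computational docking produces thousands of candidate conformations
("decoys") of a protein-protein complex, of which only a handful are
near-native; telling those apart is the scoring problem. `ppirank`
implements the full data path for learning-based scoring at desk scale,
for structural bioinformaticians who want a self-contained, inspectable
pipeline rather than a GPU framework:

1. **Structures** — parse/write two-chain PDB files, detect interface
   residues (any atom pair across chains within 5.5 Å, configurable,
   inclusive).
2. **Features** — 36 channels per complex: element densities (C/N/O/S
   per chain), per-atom partial charges and intermolecular Coulomb and
   Lennard-Jones energies from a shipped reduced force-field table,
   per-residue buried surface area (Shrake–Rupley), and 20 shared PSSM
   log-odds channels.
3. **Grids** — each channel is spread onto an interface-centered 3D
   lattice (default 30×30×30 Å at 1 Å) with a Gaussian kernel,
   `w_k(r) = v_k exp(−‖r−r_k‖²/2σ_k²)`, σ set by the van der Waals
   radius; rotation augmentation is uniform on the rotation group.
4. **Targets** — docking quality against a reference: iRMSD, lRMSD
   (Kabsch superposition), FNAT, DockQ, CAPRI class, and the binary
   hit label iRMSD ≤ 4 Å.
5. **Storage** — one HDF5 group per model
   (`mapped_features/`, `grid_points/`, `targets/`), deterministic
   sorted-id streaming, channel subsets, target-value filters, and
   complex-level grouped k-fold splits.
6. **Learning** — a compact 3D CNN (two conv blocks 8/16, kernel 3,
   batch norm, max pool, FC 84) written in base R, with weighted
   cross-entropy or MSE, SGD/momentum and Adam presets, early stopping,
   and seeded determinism.
7. **Evaluation** — per-case hit-rate curves `HR(K) = n_hits(K)/M`,
   cross-case success rates `SR(K)`, and the HADDOCK it0/it1/itw stage
   scores for comparison.

Synthetic generators (toy dimers, rigid-body decoy ladders, synthetic
PSSMs, planted-signal grid datasets) make every stage runnable and
testable without any external data. The channel inventory summing to 36
is this package's documented reconstruction; see the methods vignette
(`vignettes/interface-scoring.Rmd`) for the layout and every numerical
convention.

## Worked example

```r
library(ppirank)

ref    <- make_toy_dimer(8, seed = 2)          # 64-atom two-chain fixture
decoys <- make_decoys(ref, n_decoys = 20, seed = 5)
compute_targets(decoys[[1]]$complex, ref)
#> $irmsd        6.256
#> $lrmsd        15.24
#> $fnat         0
#> $dockq        0.0972
#> $capri_class  "incorrect"
#> $binary_label "wrong"
#> $binary_class 0

profiles <- setNames(
  lapply(ref$chain_ids, function(ch) make_synthetic_pssm(ref, ch, 1)),
  ref$chain_ids)
grid <- featurize_complex(ref, profiles)
length(grid$channels)
#> [1] 36
```

The decoy above sits 6.3 Å (interface RMSD) from the reference — an
incorrect model with no native contacts preserved (13 of the 20 decoys
in this ladder are near-native) — and every complex featurizes to 36
grid channels of 30³ voxels each. A shell entry point wrapping the same
functions lives at `inst/cli/ppirank`
(`simulate | featurize | train | evaluate | score`).

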