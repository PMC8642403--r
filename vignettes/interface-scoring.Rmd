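---
title: "Grid featurization and convolutional scoring of protein-protein interfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid featurization and convolutional scoring of protein-protein interfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppirank)
```

## The problem

A protein-protein interface (PPI) is the contact region between two chains
of a complex. Two recurring questions in structural biology reduce to
learning from PPIs: is an observed crystallographic contact a biological
interface or a packing artifact, and, given thousands of computationally
docked candidate conformations ("decoys") of a complex, which ones are
near-native? `ppirank` implements a complete pipeline for the second kind
of question at desk scale: it converts two-chain PDB structures into
multi-channel 3D images of their interface, stores them with
docking-quality target values in HDF5, trains a small 3D convolutional
network on them, and evaluates how well the resulting score ranks decoys.

## Interface definition

A residue is an interface residue when any of its atoms lies within a
distance cutoff (default 5.5 Angstrom, inclusive) of any atom of the
other chain. The boundary is inclusive by convention, matching the
inclusive iRMSD threshold used for labels. Hydrogens participate if
present in the file (the shipped fixtures are heavy-atom only); waters
never do. Alternate locations other than blank/'A' are dropped at parse
time and insertion codes become part of a composite residue identifier,
so real PDB files parse deterministically.

## Features and their grid mapping

Each complex is summarised by 36 feature channels:

| channels | feature | level | sigma |
|---|---|---|---|
| 8 | element densities (C, N, O, S per chain) | atomic | element vdW radius |
| 2 | partial charge (per chain) | atomic | element vdW radius |
| 2 | intermolecular Coulomb energy (per chain) | atomic | element vdW radius |
| 2 | intermolecular van der Waals energy (per chain) | atomic | element vdW radius |
| 2 | per-residue buried surface area (per chain) | residue (at CA) | carbon radius |
| 20 | PSSM log-odds, one channel per residue type (both chains shared) | residue (at CA) | carbon radius |

The 36-channel layout is a documented reconstruction: the total count is
fixed, but no published inventory enumerates the channels, so the
assignment above (8 densities + 2 each of charge/Coulomb/vdW/BSA + 20
PSSM) is this package's own, stated here and stable across stored
datasets. Residue-contact-count channels (partner residues classified as
charged {D,E,K,R}, polar {C,H,N,Q,S,T,W,Y}, or apolar, per the usual
partition) are implemented but excluded from the default set, precisely
so the default totals 36.

A channel is mapped onto an interface-centered lattice (default 30 x 30
x 30 Angstrom at 1 Angstrom resolution; points per axis is
`round(size/resolution)`) by Gaussian spreading: a point with value
$v_k$ at $r_k$ contributes

$$ w_k(r) = v_k \exp\left(-\frac{\lVert r - r_k\rVert^2}{2\sigma_k^2}\right) $$

to grid position $r$. The decaying form (negative exponent) is the only
physically sensible one: a growing exponential would diverge away from
the atom. No $(2\pi\sigma^2)^{-3/2}$ normalization is applied, so peak
height, not integral, is what a channel value means. Contributions are
truncated beyond $4\sigma_k$, where the Gaussian is below $3.4\times
10^{-4}$ of its peak; this bounds mapping cost without visible effect on
the grids. The grid center is the mean position of the interface heavy
atoms. Rotation augmentation rotates the atom coordinates (uniformly on
the rotation group, via normalized quaternions) about the grid center
before mapping, rather than resampling the grid.

## Energies and the reduced force field

Per-atom intermolecular energies sum over cross-chain partners within a
hard 8.5 Angstrom cutoff at constant dielectric:
Coulomb $332.0636\, q_k q_l / r_{kl}$ kcal/mol and Lennard-Jones
$4\epsilon_{kl}[(\sigma_{kl}/r)^{12} - (\sigma_{kl}/r)^6]$ with
Lorentz-Berthelot combining. Each pair term is clamped to ±1000
kcal/mol: rigid-body decoys routinely contain steric clashes, and an
unclamped $r^{-12}$ spike in one voxel would otherwise dominate an
entire channel. The shipped parameter table is deliberately reduced —
backbone N/CA/C/O/CB charges for the 20 amino acids plus element-level
LJ parameters and vdW radii (C 1.70, N 1.55, O 1.52, S 1.80 Angstrom) —
because the featurization pipeline, not force-field fidelity, is the
point; the table file is plain text and user-replaceable. Atoms missing
from the table fall back to zero charge and element defaults, counted in
a warning, so odd real-world files degrade gracefully rather than
failing.

## Surface areas

Accessible surface areas use the Shrake-Rupley construction: each atom's
sphere is expanded by the probe radius (1.4 Angstrom, water) and sampled
with a deterministic golden-spiral point set (default 960 points); the
accessible fraction times the expanded-sphere area is the atom's ASA.
Buried surface area of the complex is
$\mathrm{BSA} = (\mathrm{ASA}_A + \mathrm{ASA}_B -
\mathrm{ASA}_{complex})/2$, and per-residue burial is the residue's ASA
in the isolated chain minus in the complex, floored at zero. Because the
sphere points have a fixed orientation, SASA is rotation-invariant only
to quadrature accuracy (well under 1% of the total at 960 points, which
is also where doubling the point count changes totals by <1%).

## Quality metrics

Against a reference structure, a model gets: FNAT (fraction of the
reference's cross-chain residue contacts at 5 Angstrom heavy-atom
distance that the model preserves), lRMSD (backbone RMSD of the smaller
"ligand" chain after superposing on the larger "receptor" chain; ties on
chain size break to the lexicographically smaller chain id), iRMSD
(backbone RMSD over reference-defined 10 Angstrom interface residues,
superposed on those same atoms), DockQ
$= (\mathrm{FNAT} + (1+(\mathrm{iRMSD}/1.5)^2)^{-1} +
(1+(\mathrm{lRMSD}/8.5)^2)^{-1})/3$, the CAPRI class from the standard
threshold table, and the binary hit label iRMSD $\le$ 4 Angstrom
(inclusive). Superposition is the Kabsch algorithm via SVD with the
determinant correction, so reflections are never returned. Backbone is
{N, CA, C, O}; atoms missing on either side are dropped from both by key
intersection, tolerating e.g. absent terminal oxygens. iRMSD superposes
on interface *backbone* atoms (the convention is ambiguous in parts of
the literature); this choice is fixed and documented here.

## Storage and splits

Each featurized model is one HDF5 group:
`/<model_id>/mapped_features/<channel>`, `/<model_id>/grid_points/{x,y,z}`,
`/<model_id>/targets/<name>`, with `case_id`, augmentation seed and a
configuration hash as group attributes. Reading streams entries in
sorted-id order — independent of write order — with optional channel
subsets and target filters (`name op value`, comparators `< <= > >= =`),
so training selections are reproducible. Cross-validation splits are
grouped at the case (complex) level: cases are shuffled by seed, cut
into k equal test blocks (leftover cases are never tested), and each
fold draws its validation cases from the non-test remainder; a case
therefore never appears in two folds' test sets and never straddles
train/test within a fold.

## The network and training

The default classifier is two convolution blocks (8 then 16 filters,
kernel 3, batch normalization, ReLU, 2x2x2 max pooling) followed by a
fully connected layer of width 84 and a 2-unit output; it accepts any
grid of at least 12 points per axis and any channel count, and a
regression variant has a single output trained with mean squared error.
The engine is a compact, self-contained implementation in base R
(im2col convolution via BLAS matrix products, with a finite-difference
gradient check in the test suite). Two optimizer presets are shipped:
an SGD setup (learning rate 5e-4, momentum 0.9, weight decay 1e-3,
batch 8) and an Adam setup (learning rate 1e-3, batch 100, automatic
class weights). Class weights follow the opposite-fraction rule — the
negative class is weighted by the fraction of positives and vice versa,
summing to one — so a 7.1%-positive dataset yields (0.071, 0.929) and
the expected penalty on both classes balances. Training is seeded and
deterministic given (seed, data, config); early stopping watches the
validation loss and restores the best epoch's weights. For
classification the two outputs are log-softmax scores and the
wrong-class score is the ranking score: lower means the model is
predicted to be better.

## Ranking evaluation

Within a case, models are ranked by ascending score with deterministic
lexicographic tie-breaks. The hit-rate curve at depth K is the number of
hits in the top K divided by the case's total hit count M; cases with
M = 0 are excluded from hit-rate statistics (the quantity is undefined)
but count as failures in the success rate, the fraction of cases with at
least one hit in the top K. Cross-case medians and quartiles are
reported only up to the smallest case size. The three HADDOCK stage
scores (it0/it1/itw) are provided for comparison as pure arithmetic on
supplied energy terms — desolvation energy is always an input, never
computed — with restraint terms omitted.

## What the synthetic fixtures do and do not show

The generators make the whole pipeline self-contained: idealized
two-chain dimers (N/CA/C/O pseudo-backbone, 3.8 Angstrom CA spacing,
seeded jitter, chains placed in contact), rigid-body decoys (seeded
ligand rotation up to 60 degrees about its centroid plus translation up
to 15 Angstrom, resampled so the chains stay in atomic contact as
docking output does, with guaranteed minimum counts of hits and
non-hits), synthetic PSSMs (integer log-odds uniform in -5..8 with the
native residue's column biased +4, information content uniform in 0..2),
and planted-signal grid datasets (the default 36-channel layout filled
with unit-variance noise; positives carry a centered Gaussian blob of
amplitude `snr` in one designated channel; defaults 30 positives + 30
negatives on 12-point grids). Every generator is a pure function of its
seed.

These fixtures exercise every code path — parsing, featurization,
metrics, storage, training, ranking — but they are not protein physics:
the dimers have no side chains or realistic packing, decoys sample rigid
perturbations rather than docking energetics, and the planted signal is
linearly separable by construction. A passing suite therefore
demonstrates that the machinery is correct, not that the default network
discriminates real near-native models; that claim would require training
on a real docking corpus, which is outside what a single desk-scale run
can support.

## Numerical choices and problem sizes

Decisions a maintainer would look for, in one place: distance boundaries
are inclusive throughout; coincident atoms raise errors rather than
producing infinities; per-pair energies clamp at ±1000 kcal/mol;
Gaussian mapping truncates at 4 sigma; grids must have at least 2 points
per axis and the default CNN at least 12; score ties break
lexicographically; k-fold leftovers are never tested. The test suite and
the reproduction script run everything at sizes chosen to keep a
single-CPU run comfortable: 5-8 residue dimers, 50-decoy ladders,
24 Angstrom / 2 Angstrom grids (12 points per axis) for end-to-end
training runs, 240-point SASA spheres inside featurization-heavy tests,
and the full 30-cube defaults wherever a single featurization is enough.
The channel-count, class-weight, fold-arithmetic and metric landmark
values these runs print are exact consequences of the definitions above,
so they are the same at any scale.

## A worked example

```{r example, eval = FALSE}
ref <- make_toy_dimer(8, seed = 2)
decoys <- make_decoys(ref, n_decoys = 20, seed = 5)
targets <- compute_targets(decoys[[1]]$complex, ref)
str(targets)

profiles <- setNames(
  lapply(ref$chain_ids, function(ch) make_synthetic_pssm(ref, ch, 1)),
  ref$chain_ids)
grid <- featurize_complex(ref, profiles)
length(grid$channels)   # 36
```

## Known limitations

Only two-chain complexes are supported (the first MODEL of multi-model
files); mmCIF is not parsed; the force field is reduced and the
desolvation term is never computed; the CNN engine is single-threaded
base R sized for desk-scale grids, not a GPU corpus; and binding
affinity targets would have to be supplied by the user (the regression
path accepts any numeric target, but no affinity calculator is
included).
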