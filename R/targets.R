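## Docking-model quality metrics against a reference structure: Kabsch
## superposition, ligand and interface RMSD, fraction of native contacts,
## DockQ, CAPRI class and the near-native binary label.

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Least-squares superposition of two matched point sets (Kabsch)
#'
#' Returns the proper rotation and translation minimizing the RMSD of the
#' transformed `P` onto `Q` (`P` and `Q` index-matched), and that minimum
#' RMSD.
#'
#' @param P,Q n x 3 coordinate matrices, n >= 3.
#' @return list with `rotation` (3 x 3, determinant +1), `translation`
#'   (length 3; the fit maps `p` to `rotation %*% p + translation`) and
#'   `rmsd` (Angstrom).
#' @export
superpose <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) < 3 || nrow(P) != nrow(Q))
    stop_ppi("ppi_geometry_error",
             "superposition needs >= 3 index-matched points")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  if (sv$d[2] < 1e-10)
    stop_ppi("ppi_geometry_error", "rank-deficient point sets")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- cq - as.vector(R %*% cp)
  fitted <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Qc)^2)))
  list(rotation = R, translation = t_vec, rmsd = rmsd)
}

## Backbone atoms of `complex` keyed by chain:residue:atom; missing atoms
## (e.g. terminal O) are tolerated by matching on the key intersection.
backbone_keyed <- function(complex, chains = NULL, uids_by_chain = NULL) {
  at <- complex$atoms
  uid <- residue_uid(complex)
  keep <- at$name %in% BACKBONE_ATOMS
  if (!is.null(chains)) keep <- keep & at$chain %in% chains
  if (!is.null(uids_by_chain)) {
    sel <- rep(FALSE, nrow(at))
    for (ch in names(uids_by_chain))
      sel <- sel | (at$chain == ch & uid %in% uids_by_chain[[ch]])
    keep <- keep & sel
  }
  rows <- which(keep)
  key <- paste(at$chain[rows], uid[rows], at$name[rows], sep = ":")
  list(rows = rows, key = key)
}

## Matched backbone coordinate pair (model, reference) for a key subset.
matched_backbone <- function(model, reference, chains = NULL,
                             uids_by_chain = NULL) {
  bm <- backbone_keyed(model, chains, uids_by_chain)
  br <- backbone_keyed(reference, chains, uids_by_chain)
  common <- intersect(bm$key, br$key)
  if (length(common) < 3)
    stop_ppi("ppi_correspondence_error",
             "fewer than 3 matched backbone atoms between model and reference")
  mi <- bm$rows[match(common, bm$key)]
  ri <- br$rows[match(common, br$key)]
  list(P = coords(model)[mi, , drop = FALSE],
       Q = coords(reference)[ri, , drop = FALSE])
}

#' Ligand RMSD
#'
#' Superposes the model onto the reference on the receptor-chain backbone
#' (receptor = chain with more residues) and reports the backbone RMSD of
#' the ligand chain under that fit, without re-fitting.
#'
#' @param model,reference [make_complex()] objects sharing chain ids and
#'   residue numbering on the backbone.
#' @return lRMSD in Angstrom.
#' @export
lrmsd <- function(model, reference) {
  rl <- receptor_ligand(reference)
  rec <- matched_backbone(model, reference, chains = rl$receptor)
  fit <- superpose(rec$P, rec$Q)
  lig <- matched_backbone(model, reference, chains = rl$ligand)
  P <- sweep(lig$P %*% t(fit$rotation), 2, fit$translation, "+")
  sqrt(mean(rowSums((P - lig$Q)^2)))
}

#' Reference-defined interface residues (10 A heavy-atom cutoff)
#' @noRd
reference_interface_uids <- function(reference, cutoff = 10) {
  heavy <- reference
  heavy$atoms <- heavy$atoms[toupper(heavy$atoms$element) != "H", , drop = FALSE]
  sel <- interface_residues(heavy, cutoff)
  if (nrow(sel$contact_atom_pairs) == 0)
    stop_ppi("ppi_metric_error",
             "reference has no interface at the %.0f A cutoff", cutoff)
  sel$residues_by_chain
}

#' Interface RMSD
#'
#' Interface residues are defined on the reference with a 10 A heavy-atom
#' contact cutoff; the model is superposed onto the reference using those
#' residues' backbone atoms, and that fit's RMSD is the iRMSD.
#'
#' @inheritParams lrmsd
#' @param interface_cutoff reference-interface cutoff in Angstrom.
#' @return iRMSD in Angstrom.
#' @export
irmsd <- function(model, reference, interface_cutoff = 10) {
  uids <- reference_interface_uids(reference, interface_cutoff)
  mb <- matched_backbone(model, reference, uids_by_chain = uids)
  superpose(mb$P, mb$Q)$rmsd
}

## Cross-chain residue contact pairs (any heavy atom <= cutoff), as keys.
residue_contact_keys <- function(complex, cutoff) {
  heavy <- complex
  heavy$atoms <- heavy$atoms[toupper(heavy$atoms$element) != "H", , drop = FALSE]
  pairs <- atomic_contact_pairs(heavy, cutoff)
  if (nrow(pairs) == 0) return(character(0))
  uid <- residue_uid(heavy)
  unique(paste(uid[pairs[, 1]], uid[pairs[, 2]], sep = "|"))
}

#' Fraction of native contacts (FNAT)
#'
#' Native contacts are the reference's cross-chain residue pairs with any
#' heavy-atom distance within 5 A; FNAT is the fraction preserved in the
#' model.
#'
#' @inheritParams lrmsd
#' @param cutoff contact cutoff in Angstrom (default 5).
#' @return fraction between 0 and 1.
#' @export
fnat <- function(model, reference, cutoff = 5) {
  native <- residue_contact_keys(reference, cutoff)
  if (length(native) == 0)
    stop_ppi("ppi_metric_error", "reference has zero native contacts")
  modeled <- residue_contact_keys(model, cutoff)
  length(intersect(native, modeled)) / length(native)
}

#' DockQ score
#'
#' `(fnat + 1/(1+(irmsd/1.5)^2) + 1/(1+(lrmsd/8.5)^2)) / 3`.
#'
#' @param fnat fraction of native contacts between 0 and 1.
#' @param lrmsd,irmsd RMSDs in Angstrom (non-negative).
#' @return score between 0 and 1.
#' @export
dockq <- function(fnat, lrmsd, irmsd) {
  if (fnat < 0 || fnat > 1 || lrmsd < 0 || irmsd < 0)
    stop_ppi("ppi_domain_error", "dockq inputs out of range")
  (fnat + 1 / (1 + (irmsd / 1.5)^2) + 1 / (1 + (lrmsd / 8.5)^2)) / 3
}

#' CAPRI quality class
#'
#' Threshold table (inclusive boundaries): high if fnat >= 0.5 and
#' (irmsd <= 1 or lrmsd <= 1); else medium if fnat >= 0.3 and (irmsd <= 2
#' or lrmsd <= 5); else acceptable if fnat >= 0.1 and (irmsd <= 4 or
#' lrmsd <= 10); else incorrect.
#'
#' @inheritParams dockq
#' @return one of `"high"`, `"medium"`, `"acceptable"`, `"incorrect"`.
#' @export
capri_class <- function(fnat, lrmsd, irmsd) {
  if (fnat >= 0.5 && (irmsd <= 1.0 || lrmsd <= 1.0)) "high"
  else if (fnat >= 0.3 && (irmsd <= 2.0 || lrmsd <= 5.0)) "medium"
  else if (fnat >= 0.1 && (irmsd <= 4.0 || lrmsd <= 10.0)) "acceptable"
  else "incorrect"
}

#' Near-native binary label
#'
#' A model is near-native (a hit) when its iRMSD is within the threshold
#' (inclusive), 4 A by default.
#'
#' @param irmsd iRMSD in Angstrom.
#' @param threshold hit threshold in Angstrom.
#' @return `"near-native"` or `"wrong"`.
#' @export
binary_label <- function(irmsd, threshold = 4.0) {
  if (irmsd < 0) stop_ppi("ppi_domain_error", "irmsd must be non-negative")
  if (irmsd <= threshold) "near-native" else "wrong"
}

#' Compute the full quality-target record of a model
#'
#' @inheritParams lrmsd
#' @param hit_threshold iRMSD threshold for the binary label (Angstrom).
#' @return list with `irmsd`, `lrmsd`, `fnat`, `dockq`, `capri_class`,
#'   `binary_label` and `binary_class` (1 = near-native, 0 = wrong).
#' @export
compute_targets <- function(model, reference, hit_threshold = 4.0) {
  ir <- irmsd(model, reference)
  lr <- lrmsd(model, reference)
  fn <- fnat(model, reference)
  lab <- binary_label(ir, hit_threshold)
  list(irmsd = ir, lrmsd = lr, fnat = fn,
       dockq = dockq(fn, lr, ir),
       capri_class = capri_class(fn, lr, ir),
       binary_label = lab,
       binary_class = as.integer(lab == "near-native"))
}
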