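## Self-contained synthetic inputs: idealized two-chain dimers, rigid-body
## decoy sets with a controllable quality spread, synthetic PSSM profiles,
## and planted-signal grid datasets for exercising the training path.
## Every generator is a pure function of its seed and parameters.

#' Generate an idealized toy dimer
#'
#' Two pseudo-backbone chains (N, CA, C, O per residue; 3.8 A alpha-carbon
#' spacing on a gently curved trace) placed so that at least one residue
#' pair lies within the default 5.5 A interface cutoff. Coordinates are
#' rounded to 3 decimals so the complex round-trips through the PDB format
#' exactly. Residue types are drawn (seeded) from the 20 standard amino
#' acids.
#'
#' @param n_res_per_chain residues per chain (>= 3).
#' @param seed integer seed; same seed, identical coordinates.
#' @param chain_gap z-offset between the chains in Angstrom.
#' @return a [make_complex()] object with chains A and B.
#' @export
make_toy_dimer <- function(n_res_per_chain = 5, seed = 1, chain_gap = 4.3) {
  if (n_res_per_chain < 3)
    stop_ppi("ppi_config_error", "need at least 3 residues per chain")
  n <- n_res_per_chain
  resnames <- with_seed(derive_seed(seed, 1),
                        sample(AA3, 2 * n, replace = TRUE))
  jit <- with_seed(derive_seed(seed, 2),
                   matrix(stats::runif(2 * n * 4 * 3, -0.05, 0.05),
                          ncol = 3))
  offsets <- list(N = c(-1.20, 0.80, 0.30), CA = c(0, 0, 0),
                  C = c(1.25, 0.75, -0.30), O = c(1.45, 1.90, -0.20))
  off <- do.call(rbind, offsets)
  build_chain <- function(chain, phase, zoff, xoff, zsign) {
    i <- rep(seq_len(n), each = 4)
    an <- rep(rownames(off), n)
    data.frame(
      name = an, element = substr(an, 1, 1), chain = chain,
      resno = i, insert = "",
      resname = resnames[i + if (chain == "A") 0 else n],
      x = 3.8 * i + xoff + off[an, 1],
      y = 0.6 * sin(0.8 * i + phase) + off[an, 2],
      z = zoff + zsign * off[an, 3],
      stringsAsFactors = FALSE)
  }
  at <- rbind(build_chain("A", 0, 0, 0, 1),
              build_chain("B", 0.5, chain_gap, 1.9, -1))
  at$x <- round(at$x + jit[, 1], 3)
  at$y <- round(at$y + jit[, 2], 3)
  at$z <- round(at$z + jit[, 3], 3)
  at$serial <- seq_len(nrow(at))
  make_complex(at, source_id = sprintf("toy_dimer_s%d", seed))
}

#' Generate rigid-body decoys of a reference complex
#'
#' Each decoy perturbs the ligand chain rigidly (seeded rotation about
#' the ligand centroid up to `max_rotation` degrees plus a translation up
#' to `max_translation` Angstrom), leaving the receptor untouched, and is
#' labelled by its iRMSD against the reference. Candidates are
#' rejection-resampled until at least `guarantee["near_native"]` hits
#' (iRMSD <= 4) and `guarantee["wrong"]` non-hits are present.
#'
#' @param reference a [make_complex()] object.
#' @param n_decoys number of decoys to produce.
#' @param max_translation maximum translation magnitude (Angstrom).
#' @param max_rotation maximum rotation angle (degrees).
#' @param guarantee named vector `c(near_native =, wrong =)` of minimum
#'   class counts.
#' @param contact_cutoff decoys must retain at least one cross-chain
#'   atomic contact within this distance (Angstrom), as rigid-body
#'   docking output does; candidates that drift apart are resampled.
#'   Set to `Inf` to disable.
#' @param seed integer seed.
#' @return list of decoys, each a list with `complex` (source_id
#'   `decoy_<i>`), `displacement` (ligand-atom RMS displacement before
#'   refitting), `irmsd`, `label`.
#' @export
make_decoys <- function(reference, n_decoys = 20, max_translation = 15,
                        max_rotation = 60,
                        guarantee = c(near_native = 3, wrong = 3),
                        contact_cutoff = 5.5, seed = 1) {
  if (sum(guarantee) > n_decoys)
    stop_ppi("ppi_config_error", "guarantee counts exceed n_decoys")
  lig <- receptor_ligand(reference)$ligand
  lig_rows <- which(reference$atoms$chain == lig)
  lig_xyz <- coords(reference)[lig_rows, , drop = FALSE]
  centroid <- colMeans(lig_xyz)
  need_nn <- guarantee[["near_native"]]
  need_w <- guarantee[["wrong"]]
  out <- list()
  attempts <- 0
  k <- 0
  while (length(out) < n_decoys) {
    attempts <- attempts + 1
    if (attempts > 100 * n_decoys)
      stop_ppi("ppi_generation_error",
               "could not satisfy decoy guarantees in %d attempts", attempts)
    k <- k + 1
    pars <- with_seed(derive_seed(seed, k), {
      u <- stats::runif(1)
      axis <- stats::rnorm(3)
      dir <- stats::rnorm(3)
      list(u = u, axis = axis / sqrt(sum(axis^2)),
           dir = dir / sqrt(sum(dir^2)), u2 = stats::runif(1))
    })
    angle <- pars$u * max_rotation * pi / 180
    K <- matrix(c(0, -pars$axis[3], pars$axis[2],
                  pars$axis[3], 0, -pars$axis[1],
                  -pars$axis[2], pars$axis[1], 0), 3, byrow = TRUE)
    R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
    shift <- pars$dir * pars$u2 * max_translation
    new_xyz <- sweep(sweep(lig_xyz, 2, centroid) %*% t(R), 2,
                     centroid + shift, "+")
    decoy <- reference
    decoy$atoms$x[lig_rows] <- new_xyz[, 1]
    decoy$atoms$y[lig_rows] <- new_xyz[, 2]
    decoy$atoms$z[lig_rows] <- new_xyz[, 3]
    if (is.finite(contact_cutoff) &&
        nrow(atomic_contact_pairs(decoy, contact_cutoff)) == 0) next
    ir <- irmsd(decoy, reference)
    lab <- binary_label(ir)
    is_nn <- lab == "near-native"
    free <- n_decoys - length(out) - max(need_nn, 0) - max(need_w, 0)
    take <- (is_nn && need_nn > 0) || (!is_nn && need_w > 0) || free > 0
    if (!take) next
    if (is_nn) need_nn <- need_nn - 1 else need_w <- need_w - 1
    i <- length(out) + 1
    decoy$source_id <- sprintf("decoy_%03d", i)
    out[[i]] <- list(
      complex = decoy,
      displacement = sqrt(mean(rowSums((new_xyz - lig_xyz)^2))),
      irmsd = ir, label = lab)
  }
  out
}

#' Generate a synthetic PSSM profile for one chain
#'
#' Per residue, 20 integer log-odds scores drawn uniformly in -5..8
#' with the residue's own column biased by +4, and information content
#' uniform in 0..2. The dialect matches [read_pssm()].
#'
#' @param complex a [make_complex()] object.
#' @param chain_id which chain to profile.
#' @param seed integer seed.
#' @return a `ppi_pssm` profile.
#' @export
make_synthetic_pssm <- function(complex, chain_id, seed = 1) {
  if (!(chain_id %in% complex$chain_ids))
    stop_ppi("ppi_structure_error", "no chain '%s' in complex", chain_id)
  rows <- complex$atoms[complex$atoms$chain == chain_id, ]
  res <- rows[!duplicated(paste0(rows$resno, rows$insert)), ]
  letters1 <- residue_letter(res$resname)
  letters1[is.na(letters1)] <- "A"
  df <- with_seed(derive_seed(seed, 3), {
    scores <- matrix(as.numeric(sample(-5:8, nrow(res) * 20,
                                       replace = TRUE)), ncol = 20)
    colnames(scores) <- PSSM_COLS
    for (i in seq_len(nrow(res)))
      scores[i, letters1[i]] <- scores[i, letters1[i]] + 4
    data.frame(resnum = res$resno, resname = letters1, scores,
               IC = round(stats::runif(nrow(res), 0, 2), 3),
               check.names = FALSE)
  })
  structure(list(chain_id = chain_id, rows = df), class = "ppi_pssm")
}

#' Canonical 36-channel layout of the default feature set
#' @return character vector of channel names in the documented order.
#' @export
default_channel_names <- function() {
  c(as.vector(t(outer(c("C", "N", "O", "S"), c("A", "B"),
                      function(e, t) sprintf("density_%s_%s", e, t)))),
    "charge_A", "charge_B", "coulomb_A", "coulomb_B", "vdw_A", "vdw_B",
    "bsa_A", "bsa_B", paste0("pssm_", PSSM_COLS))
}

#' Generate a planted-signal grid dataset
#'
#' Writes an HDF5 dataset whose entries carry the default 36-channel
#' layout filled with unit-variance Gaussian noise; positive entries
#' additionally carry a centered Gaussian blob of amplitude `snr` in one
#' designated channel. Labels (and surrogate iRMSD values consistent
#' with them) are stored as targets, so the file exercises the full
#' selection/filter/training path.
#'
#' @param path output HDF5 file.
#' @param n_pos,n_neg numbers of positive (near-native) and negative
#'   entries.
#' @param snr blob amplitude over unit-variance noise.
#' @param seed integer seed.
#' @param grid_n grid points per axis (default 12).
#' @param resolution grid spacing in Angstrom.
#' @param signal_channel channel carrying the planted blob.
#' @param n_cases number of case ids the entries cycle through.
#' @return `path`, invisibly.
#' @export
make_planted_grid_dataset <- function(path, n_pos = 30, n_neg = 30,
                                      snr = 5, seed = 1, grid_n = 12,
                                      resolution = 1.0,
                                      signal_channel = "density_C_A",
                                      n_cases = 4) {
  if (n_pos < 1 || n_neg < 1 || snr < 0)
    stop_ppi("ppi_config_error", "need n_pos, n_neg >= 1 and snr >= 0")
  channels <- default_channel_names()
  if (!(signal_channel %in% channels))
    stop_ppi("ppi_config_error", "unknown signal channel '%s'",
             signal_channel)
  spec <- make_grid(c(0, 0, 0), size = grid_n * resolution,
                    resolution = resolution)
  ax <- spec$coords[[1]]
  blob_sigma <- grid_n * resolution / 6
  d2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  blob <- exp(-d2 / (2 * blob_sigma^2))
  n <- n_pos + n_neg
  labels <- rep(c(1L, 0L), c(n_pos, n_neg))
  entries <- vector("list", n)
  for (i in seq_len(n)) {
    chans <- with_seed(derive_seed(seed, 100 + i), {
      cs <- lapply(channels, function(ch)
        array(stats::rnorm(grid_n^3), dim = spec$n))
      names(cs) <- channels
      cs
    })
    if (labels[i] == 1)
      chans[[signal_channel]] <- chans[[signal_channel]] + snr * blob
    ir <- with_seed(derive_seed(seed, 500 + i),
                    if (labels[i] == 1) stats::runif(1, 0, 4)
                    else stats::runif(1, 4.5, 15))
    grid <- structure(list(spec = spec, channels = chans,
                           provenance = list(source_id = "planted")),
                      class = "ppi_feature_grid")
    entries[[i]] <- dataset_entry(
      model_id = sprintf("planted_%03d", i),
      case_id = sprintf("case_%02d", (i - 1) %% n_cases + 1),
      grid = grid,
      targets = list(binary_class = labels[i],
                     binary_label = if (labels[i] == 1) "near-native"
                                    else "wrong",
                     irmsd = ir),
      seed = derive_seed(seed, 100 + i))
  }
  if (file.exists(path)) unlink(path)
  write_entries(path, entries)
  invisible(path)
}
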