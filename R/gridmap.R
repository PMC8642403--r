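#' Define an interface-centered 3D grid
#'
#' The lattice has `round(size/resolution)` points per axis; point `j` of
#' axis `i` sits at `center_i + (j - (n_i - 1)/2) * resolution`, so the
#' lattice is symmetric about the center.
#'
#' @param center grid center, length-3 numeric (Angstrom).
#' @param size box edge lengths, length-3 (or scalar) numeric (Angstrom);
#'   default 30 x 30 x 30.
#' @param resolution lattice spacing in Angstrom, default 1.
#' @return object of class `ppi_gridspec`: list with `center`, `size`,
#'   `resolution`, `n` (points per axis) and `coords` (list of axis
#'   coordinate vectors).
#' @export
make_grid <- function(center = c(0, 0, 0), size = c(30, 30, 30),
                      resolution = 1.0) {
  size <- rep_len(as.numeric(size), 3)
  if (any(size <= 0) || resolution <= 0)
    stop_ppi("ppi_config_error", "grid size and resolution must be positive")
  n <- round(size / resolution)
  if (any(n < 2))
    stop_ppi("ppi_config_error",
             "grid must have at least 2 points per axis (size/resolution >= 2)")
  coords <- lapply(1:3, function(i)
    center[i] + (seq_len(n[i]) - 1 - (n[i] - 1) / 2) * resolution)
  structure(list(center = as.numeric(center), size = size,
                 resolution = resolution, n = as.integer(n),
                 coords = coords),
            class = "ppi_gridspec")
}

#' Map a feature point set onto a grid by Gaussian spreading
#'
#' Grid value at position `r` is `sum_k v_k * exp(-||r - r_k||^2 /
#' (2 sigma_k^2))`; contributions are truncated (set to zero) beyond
#' `4 sigma_k` of a point, where the Gaussian has fallen below 3.4e-4 of
#' its peak. Additive over points; points outside the box still
#' contribute their tails.
#'
#' @param points a [feature_point_set()] (or its `points` data frame).
#' @param spec a [make_grid()] spec.
#' @return 3D numeric array of dimensions `spec$n`.
#' @export
map_points <- function(points, spec) {
  if (inherits(points, "ppi_feature_points")) points <- points$points
  g <- array(0, dim = spec$n)
  if (nrow(points) == 0) return(g)
  cx <- spec$coords[[1]]; cy <- spec$coords[[2]]; cz <- spec$coords[[3]]
  for (k in seq_len(nrow(points))) {
    s2 <- 2 * points$sigma[k]^2
    trunc2 <- (4 * points$sigma[k])^2
    dx2 <- (cx - points$x[k])^2
    dy2 <- (cy - points$y[k])^2
    dz2 <- (cz - points$z[k])^2
    if (min(dx2) + min(dy2) + min(dz2) > trunc2) next
    d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
    w <- points$value[k] * exp(-d2 / s2)
    w[d2 > trunc2] <- 0
    g <- g + w
  }
  g
}

#' Assemble the default 36-channel feature point sets of a complex
#'
#' Channel order is fixed and layout-stable: 8 element densities
#' (C, N, O, S by chain), per-atom charge (2), intermolecular Coulomb
#' energy (2), intermolecular van der Waals energy (2), per-residue
#' buried surface area (2), then the 20 shared PSSM channels.
#'
#' @param complex a [make_complex()] object.
#' @param selection an [interface_residues()] selection.
#' @param profiles named list of PSSM profiles per chain (NULL entries
#'   forbidden when `include` requests PSSM channels).
#' @param table a [read_forcefield()] table.
#' @param include character vector of feature families to include, any of
#'   `"density"`, `"charge"`, `"coulomb"`, `"vdw"`, `"bsa"`, `"pssm"`,
#'   `"contacts"` (contacts are off by default).
#' @param sasa_points sphere points for the BSA calculation.
#' @return named list of [feature_point_set()]s in the documented order.
#' @export
default_feature_points <- function(complex, selection, profiles = NULL,
                                   table = read_forcefield(),
                                   include = c("density", "charge",
                                               "coulomb", "vdw", "bsa",
                                               "pssm"),
                                   sasa_points = 960) {
  out <- list()
  tags <- chain_tags(complex)
  idx <- interface_atom_idx(complex, selection)
  atom_channels <- function(prefix, values) {
    res <- list()
    for (ci in 1:2) {
      rows <- idx[[ci]]
      nm <- sprintf("%s_%s", prefix, tags[ci])
      res[[nm]] <- feature_point_set(
        nm, data.frame(x = complex$atoms$x[rows], y = complex$atoms$y[rows],
                       z = complex$atoms$z[rows], value = values[rows],
                       sigma = complex$atoms$radius[rows]),
        "atomic", tags[ci])
    }
    res
  }
  needs_params <- any(c("charge", "coulomb", "vdw") %in% include)
  if (needs_params && is.null(complex$atoms$charge))
    complex <- assign_parameters(complex, table)
  if (is.null(complex$atoms$radius))
    complex$atoms$radius <- vdw_radius(complex$atoms$element, table)
  if ("density" %in% include)
    out <- c(out, atom_density_points(complex, selection, table))
  if ("charge" %in% include)
    out <- c(out, atom_channels("charge", complex$atoms$charge))
  if ("coulomb" %in% include)
    out <- c(out, atom_channels("coulomb",
                                coulomb_energy_per_atom(complex, table)))
  if ("vdw" %in% include)
    out <- c(out, atom_channels("vdw", vdw_energy_per_atom(complex, table)))
  if ("bsa" %in% include) {
    b <- bsa(complex, table, n_points = sasa_points)
    sig_c <- vdw_radius("C", table)
    for (ci in 1:2) {
      ch <- complex$chain_ids[ci]
      uids <- selection$residues_by_chain[[ch]]
      cai <- ca_index(complex, ch, uids)
      vals <- b$per_residue[paste(ch, uids, sep = ":")]
      vals[is.na(vals)] <- 0
      nm <- sprintf("bsa_%s", tags[ci])
      out[[nm]] <- feature_point_set(
        nm, data.frame(x = complex$atoms$x[cai], y = complex$atoms$y[cai],
                       z = complex$atoms$z[cai], value = unname(vals),
                       sigma = sig_c),
        "residue", tags[ci])
    }
  }
  if ("pssm" %in% include) {
    if (is.null(profiles))
      stop_ppi("ppi_alignment_error",
               "PSSM channels requested but no profiles supplied")
    out <- c(out, pssm_feature_points(complex, selection, profiles, table))
  }
  if ("contacts" %in% include)
    out <- c(out, residue_contact_counts(complex, selection, table = table))
  out
}

#' Featurize a complex onto a multi-channel 3D grid
#'
#' Detects the interface, centers a grid on the mean position of the
#' interface heavy atoms, assembles the configured feature channels and
#' maps each onto the grid by Gaussian spreading. The default
#' configuration yields 36 channels.
#'
#' @param complex a [make_complex()] object.
#' @param profiles named list of PSSM profiles per chain id.
#' @param config a [default_config()]-style list; relevant keys
#'   `grid.size`, `grid.resolution`, `grid.cutoff`,
#'   `features.include`, `features.sasa_points`.
#' @param table a [read_forcefield()] table.
#' @return object of class `ppi_feature_grid`: list with `spec`,
#'   `channels` (named list of 3D arrays, fixed order) and `provenance`.
#' @export
featurize_complex <- function(complex, profiles = NULL,
                              config = default_config(),
                              table = read_forcefield()) {
  cutoff <- config$grid.cutoff
  selection <- interface_residues(complex, cutoff)
  if (nrow(selection$contact_atom_pairs) == 0)
    stop_ppi("ppi_featurization_error",
             "complex '%s' has an empty interface at cutoff %.2f",
             complex$source_id, cutoff)
  heavy <- interface_atom_idx(complex, selection)
  rows <- unlist(heavy)
  rows <- rows[toupper(complex$atoms$element[rows]) != "H"]
  center <- colMeans(coords(complex)[rows, , drop = FALSE])
  spec <- make_grid(center, config$grid.size, config$grid.resolution)
  fps <- default_feature_points(complex, selection, profiles, table,
                                include = config$features.include,
                                sasa_points = config$features.sasa_points)
  channels <- lapply(fps, map_points, spec = spec)
  structure(list(spec = spec, channels = channels,
                 provenance = list(source_id = complex$source_id,
                                   cutoff = cutoff)),
            class = "ppi_feature_grid")
}

#' Draw a uniform random rotation matrix
#'
#' Uniform on the rotation group via a normalized quaternion of four
#' standard normals.
#'
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return 3 x 3 proper rotation matrix.
#' @export
random_rotation_matrix <- function(seed = NULL) {
  q <- if (is.null(seed)) stats::rnorm(4) else with_seed(seed, stats::rnorm(4))
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

#' Randomly rotate a complex about a center (data augmentation)
#'
#' Applies a rotation drawn uniformly on the rotation group from a seeded
#' generator; all interatomic distances are preserved.
#'
#' @param complex a [make_complex()] object.
#' @param seed integer seed making the rotation reproducible.
#' @param center rotation center (Angstrom); default the centroid of all
#'   atoms.
#' @return the rotated complex.
#' @export
random_rotation <- function(complex, seed, center = NULL) {
  if (is.null(center)) center <- colMeans(coords(complex))
  R <- random_rotation_matrix(seed)
  transform_complex(complex, rotation = R, center = center)
}
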