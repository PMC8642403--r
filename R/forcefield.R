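## Reduced force field: per-(residue, atom) partial charges plus
## element-level Lennard-Jones parameters and van der Waals radii, read
## from a plain-text table. Intermolecular Coulomb and van der Waals
## energies are summed per atom over cross-chain partners within a hard
## cutoff, with per-pair clamping so steric clashes cannot produce
## unbounded grid values.

COULOMB_CONSTANT <- 332.0636   # kcal*A/(mol*e^2)

#' Read a force-field parameter table
#'
#' Plain-text, whitespace-delimited, `#` comments; sections `[charges]`
#' (`residue atom charge`), `[lj]` (`element epsilon sigma`) and `[radii]`
#' (`element radius`).
#'
#' @param path table file; default is the table shipped with the package.
#' @param pair_cutoff hard distance cutoff for energy pair sums (Angstrom).
#' @param energy_clamp per-pair energy clamp (kcal/mol).
#' @return An object of class `ppi_forcefield`: lists `charge_map`
#'   (named by `"RES|ATOM"`), `lj_map` (element -> c(epsilon, sigma)),
#'   `radius_map` (element -> radius), plus `coulomb_constant`,
#'   `pair_cutoff`, `energy_clamp`, `default_element` and
#'   `default_radius`.
#' @export
read_forcefield <- function(path = system.file("extdata",
                                               "forcefield_params.txt",
                                               package = "ppirank"),
                            pair_cutoff = 8.5, energy_clamp = 1000) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  section <- NA_character_
  charge_map <- c()
  lj_eps <- c(); lj_sig <- c(); radius_map <- c()
  for (ln in lines) {
    if (grepl("^\\[", ln)) {
      section <- gsub("\\[|\\]", "", ln)
      next
    }
    f <- strsplit(ln, "\\s+")[[1]]
    if (identical(section, "charges")) {
      charge_map[paste(toupper(f[1]), toupper(f[2]), sep = "|")] <-
        as.numeric(f[3])
    } else if (identical(section, "lj")) {
      lj_eps[toupper(f[1])] <- as.numeric(f[2])
      lj_sig[toupper(f[1])] <- as.numeric(f[3])
    } else if (identical(section, "radii")) {
      radius_map[toupper(f[1])] <- as.numeric(f[2])
    }
  }
  if (any(lj_eps < 0) || any(lj_sig <= 0) || any(radius_map <= 0))
    stop_ppi("ppi_parameter_error",
             "invalid force-field table: require epsilon >= 0, sigma > 0, radii > 0")
  if (!("C" %in% names(lj_eps)))
    stop_ppi("ppi_parameter_error",
             "force-field table must define the default element C in [lj]")
  structure(list(charge_map = charge_map,
                 lj_map = list(epsilon = lj_eps, sigma = lj_sig),
                 radius_map = radius_map,
                 coulomb_constant = COULOMB_CONSTANT,
                 pair_cutoff = pair_cutoff,
                 energy_clamp = energy_clamp,
                 default_element = "C",
                 default_radius = 1.70),
            class = "ppi_forcefield")
}

#' Van der Waals radius per element under a force-field table
#' @param element character vector of element symbols.
#' @param table a [read_forcefield()] table.
#' @return numeric vector of radii (Angstrom); unknown elements get the
#'   table's default radius.
#' @export
vdw_radius <- function(element, table) {
  r <- table$radius_map[toupper(element)]
  r[is.na(r)] <- table$default_radius
  unname(r)
}

#' Assign force-field parameters to every atom of a complex
#'
#' Adds `charge`, `epsilon`, `sigma` and `radius` columns to the atom
#' table. Unknown (residue, atom) keys receive charge 0 and unknown
#' elements receive the default element's Lennard-Jones parameters and the
#' default radius; both cases are tallied in the `n_unparameterized`
#' attribute and reported once via [warning()] when any occur.
#'
#' @param complex a [make_complex()] object.
#' @param table a [read_forcefield()] table.
#' @return the complex with parameter columns added and attribute
#'   `n_unparameterized` on the result.
#' @export
assign_parameters <- function(complex, table = read_forcefield()) {
  at <- complex$atoms
  key <- paste(toupper(at$resname), toupper(at$name), sep = "|")
  q <- table$charge_map[key]
  n_missing_q <- sum(is.na(q))
  q[is.na(q)] <- 0
  el <- toupper(at$element)
  eps <- table$lj_map$epsilon[el]
  sig <- table$lj_map$sigma[el]
  n_missing_el <- sum(is.na(eps))
  if (is.na(table$lj_map$epsilon[table$default_element]))
    stop_ppi("ppi_parameter_error", "default element '%s' missing from [lj]",
             table$default_element)
  eps[is.na(eps)] <- table$lj_map$epsilon[table$default_element]
  sig[is.na(sig)] <- table$lj_map$sigma[table$default_element]
  complex$atoms$charge <- unname(q)
  complex$atoms$epsilon <- unname(eps)
  complex$atoms$sigma <- unname(sig)
  complex$atoms$radius <- vdw_radius(el, table)
  n_unparam <- n_missing_q + n_missing_el
  if (n_unparam > 0)
    warning(sprintf("%d atom parameter lookups fell back to defaults (%d charges, %d elements)",
                    n_unparam, n_missing_q, n_missing_el), call. = FALSE)
  attr(complex, "n_unparameterized") <- n_unparam
  complex
}

## Shared pair scan: cross-chain pairs within cutoff with distances.
energy_pairs <- function(complex, cutoff) {
  pairs <- atomic_contact_pairs(complex, cutoff)
  if (nrow(pairs) == 0)
    return(list(pairs = pairs, r = numeric(0)))
  xyz <- coords(complex)
  d <- sqrt(rowSums((xyz[pairs[, 1], , drop = FALSE] -
                     xyz[pairs[, 2], , drop = FALSE])^2))
  if (any(d == 0)) {
    k <- which(d == 0)[1]
    stop_ppi("ppi_geometry_error",
             "coincident atoms: serials %d and %d at zero distance",
             complex$atoms$serial[pairs[k, 1]],
             complex$atoms$serial[pairs[k, 2]])
  }
  list(pairs = pairs, r = d)
}

## Accumulate clamped per-pair energies onto both endpoint atoms.
accumulate_pair_energy <- function(complex, pairs, e_pair, clamp) {
  e_pair <- pmin(pmax(e_pair, -clamp), clamp)
  v <- numeric(nrow(complex$atoms))
  if (length(e_pair) > 0) {
    v1 <- tapply(e_pair, pairs[, 1], sum)
    v2 <- tapply(e_pair, pairs[, 2], sum)
    v[as.integer(names(v1))] <- v[as.integer(names(v1))] + v1
    v[as.integer(names(v2))] <- v[as.integer(names(v2))] + v2
  }
  v
}

#' Per-atom intermolecular Coulomb energy
#'
#' For each atom the sum over cross-chain partners within the cutoff of
#' `C * q_k * q_l / r_kl` (constant dielectric), each pair term clamped to
#' the table's energy clamp. Intra-chain pairs contribute nothing.
#'
#' @param complex a parameterized complex from [assign_parameters()].
#' @param table the force-field table (supplies constant, clamp and the
#'   default cutoff).
#' @param cutoff pair cutoff in Angstrom; default from the table (8.5).
#' @return numeric vector, one summed energy (kcal/mol) per atom.
#' @export
coulomb_energy_per_atom <- function(complex, table = read_forcefield(),
                                    cutoff = table$pair_cutoff) {
  if (is.null(complex$atoms$charge))
    stop_ppi("ppi_parameter_error", "complex lacks parameters; call assign_parameters()")
  ep <- energy_pairs(complex, cutoff)
  q <- complex$atoms$charge
  e_pair <- table$coulomb_constant * q[ep$pairs[, 1]] * q[ep$pairs[, 2]] / ep$r
  accumulate_pair_energy(complex, ep$pairs, e_pair, table$energy_clamp)
}

#' Per-atom intermolecular van der Waals (Lennard-Jones) energy
#'
#' For each atom the sum over cross-chain partners within the cutoff of
#' `4*eps_kl*((sig_kl/r)^12 - (sig_kl/r)^6)` with Lorentz-Berthelot
#' combining (arithmetic-mean sigma, geometric-mean epsilon); each pair
#' term clamped to the table's energy clamp.
#'
#' @inheritParams coulomb_energy_per_atom
#' @return numeric vector, one summed energy (kcal/mol) per atom.
#' @export
vdw_energy_per_atom <- function(complex, table = read_forcefield(),
                                cutoff = table$pair_cutoff) {
  if (is.null(complex$atoms$epsilon))
    stop_ppi("ppi_parameter_error", "complex lacks parameters; call assign_parameters()")
  ep <- energy_pairs(complex, cutoff)
  eps <- sqrt(complex$atoms$epsilon[ep$pairs[, 1]] *
              complex$atoms$epsilon[ep$pairs[, 2]])
  sig <- (complex$atoms$sigma[ep$pairs[, 1]] +
          complex$atoms$sigma[ep$pairs[, 2]]) / 2
  sr6 <- (sig / ep$r)^6
  e_pair <- 4 * eps * (sr6^2 - sr6)
  accumulate_pair_energy(complex, ep$pairs, e_pair, table$energy_clamp)
}
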