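#' Two-chain protein complex container
#'
#' A `ppi_complex` holds the atoms of a two-chain protein-protein complex as
#' a data frame plus bookkeeping attributes. It is the common currency of the
#' featurization and quality-metric functions.
#'
#' @param atoms data frame with columns `serial` (integer), `name` (atom
#'   name), `element` (element symbol), `chain` (single character),
#'   `resno` (integer residue number), `insert` (insertion code, `""` if
#'   none), `resname` (3-letter residue code) and `x`, `y`, `z`
#'   (coordinates in Angstrom).
#' @param source_id string label identifying the model.
#' @return An object of class `ppi_complex`.
#' @export
make_complex <- function(atoms, source_id = "complex") {
  req <- c("serial", "name", "element", "chain", "resno", "insert",
           "resname", "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss) > 0)
    stop_ppi("ppi_structure_error", "atoms table lacks columns: %s",
             paste(miss, collapse = ", "))
  atoms <- as.data.frame(atoms)[req]
  chains <- unique(atoms$chain)
  if (length(chains) != 2)
    stop_ppi("ppi_structure_error",
             "a complex must have exactly two chains, found %d (%s)",
             length(chains), paste(chains, collapse = ", "))
  if (anyDuplicated(atoms$serial))
    stop_ppi("ppi_structure_error", "atom serial numbers must be unique")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop_ppi("ppi_structure_error", "non-finite atom coordinates")
  structure(list(atoms = atoms, chain_ids = chains, source_id = source_id),
            class = "ppi_complex")
}

#' @export
print.ppi_complex <- function(x, ...) {
  cat(sprintf("<ppi_complex '%s': %d atoms, chains %s/%s, %d+%d residues>\n",
              x$source_id, nrow(x$atoms), x$chain_ids[1], x$chain_ids[2],
              length(unique(residue_uid(x)[x$atoms$chain == x$chain_ids[1]])),
              length(unique(residue_uid(x)[x$atoms$chain == x$chain_ids[2]]))))
  invisible(x)
}

#' Composite residue identifier (residue number + insertion code)
#' @noRd
residue_uid <- function(complex) {
  paste0(complex$atoms$resno, complex$atoms$insert)
}

#' Atom coordinates as an n x 3 matrix
#' @param complex a [make_complex()] object.
#' @return numeric matrix with columns x, y, z (Angstrom).
#' @export
coords <- function(complex) {
  as.matrix(complex$atoms[, c("x", "y", "z")])
}

## Infer an element symbol from a PDB atom name (fallback when the element
## column is blank). Digits and primes are stripped; leading H of names such
## as "1HB" wins; otherwise the first letter is taken.
infer_element <- function(name) {
  vapply(name, function(nm) {
    s <- gsub("[^A-Za-z]", "", nm)
    if (nchar(s) == 0) return("X")
    toupper(substr(s, 1, 1))
  }, character(1), USE.NAMES = FALSE)
}

#' Parse a PDB-format string into a two-chain complex
#'
#' Reads ATOM records (HETATM and waters are ignored), keeping only blank or
#' 'A' alternate locations and the first MODEL of multi-model files.
#' Insertion codes are kept as part of the composite residue identifier.
#' Parsing is delegated to [bio3d::read.pdb()] after a validation pass that
#' reports malformed ATOM lines by line number.
#'
#' @param text PDB file contents as a single string or character vector of
#'   lines.
#' @param source_id label stored on the returned complex.
#' @return A [make_complex()] object with atoms in file order.
#' @export
parse_pdb <- function(text, source_id = "complex") {
  lines <- if (length(text) == 1) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  is_atom <- startsWith(lines, "ATOM")
  if (!any(is_atom))
    stop_ppi("ppi_parse_error", "no ATOM records found")
  for (i in which(is_atom)) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop_ppi("ppi_parse_error", "ATOM line %d too short (%d chars)", i, nchar(ln))
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (any(is.na(xyz)))
      stop_ppi("ppi_parse_error", "unparseable coordinates on ATOM line %d", i)
  }
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  pdb <- bio3d::read.pdb(tf, multi = FALSE, rm.alt = TRUE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & !(at$resid %in% WATER_RESNAMES), , drop = FALSE]
  if (nrow(at) == 0)
    stop_ppi("ppi_parse_error", "no usable ATOM records after filtering")
  elem <- at$elesy
  blank <- is.na(elem) | trimws(elem) == ""
  elem[blank] <- infer_element(at$elety[blank])
  atoms <- data.frame(
    serial = at$eleno, name = trimws(at$elety), element = trimws(elem),
    chain = at$chain, resno = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    resname = trimws(at$resid),
    x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE)
  make_complex(atoms, source_id = source_id)
}

#' Read a PDB file into a two-chain complex
#' @param path file path.
#' @inheritParams parse_pdb
#' @return A [make_complex()] object.
#' @export
read_pdb_file <- function(path, source_id = sub("\\.pdb$", "", basename(path))) {
  parse_pdb(readLines(path, warn = FALSE), source_id = source_id)
}

#' Write a complex as a PDB-format string
#'
#' Emits fixed-column ATOM records (coordinates at 3 decimals) followed by
#' END, via [bio3d::write.pdb()]. `parse_pdb(write_pdb(c))` reproduces `c`
#' at the 3-decimal coordinate precision of the format.
#'
#' @param complex a [make_complex()] object.
#' @param path optional output file; when given the string is also written
#'   there.
#' @return PDB text as a single string (invisibly when `path` is given).
#' @export
write_pdb <- function(complex, path = NULL) {
  at <- complex$atoms
  if (any(nchar(at$name) > 4))
    stop_ppi("ppi_format_error", "atom names exceeding 4 characters: %s",
             paste(unique(at$name[nchar(at$name) > 4]), collapse = ", "))
  if (any(nchar(at$resname) > 3))
    stop_ppi("ppi_format_error", "residue names exceeding 3 characters: %s",
             paste(unique(at$resname[nchar(at$resname) > 3]), collapse = ", "))
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  ins <- at$insert
  ins[ins == ""] <- ""
  bio3d::write.pdb(file = tf,
                   type = rep("ATOM", nrow(at)),
                   xyz = as.vector(t(as.matrix(at[, c("x", "y", "z")]))),
                   resno = at$resno, resid = at$resname, eleno = at$serial,
                   elety = at$name, chain = at$chain, insert = ins,
                   o = rep(1, nrow(at)), b = rep(0, nrow(at)),
                   elesy = at$element, end = TRUE, chainter = FALSE,
                   verbose = FALSE)
  out <- paste(readLines(tf, warn = FALSE), collapse = "\n")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Detect interface residues between the two chains
#'
#' A residue of one chain is an interface residue when at least one of its
#' atoms lies within `cutoff` (inclusive) of any atom of the other chain.
#' Hydrogens participate if present; water residues never do.
#'
#' @param complex a [make_complex()] object.
#' @param cutoff distance cutoff in Angstrom (default 5.5).
#' @return An object of class `ppi_interface`: list with `cutoff`,
#'   `residues_by_chain` (per-chain character vectors of composite residue
#'   identifiers) and `contact_atom_pairs` (2-column matrix of atom row
#'   indices into `complex$atoms`, first column on chain 1).
#' @export
interface_residues <- function(complex, cutoff = 5.5) {
  if (!is.numeric(cutoff) || cutoff <= 0)
    stop_ppi("ppi_config_error", "cutoff must be positive")
  pairs <- atomic_contact_pairs(complex, cutoff)
  uid <- residue_uid(complex)
  ch <- complex$atoms$chain
  res_by_chain <- list(
    unique(uid[pairs[, 1]]),
    unique(uid[pairs[, 2]]))
  names(res_by_chain) <- complex$chain_ids
  structure(list(cutoff = cutoff, residues_by_chain = res_by_chain,
                 contact_atom_pairs = pairs),
            class = "ppi_interface")
}

#' Cross-chain atom pairs within a distance cutoff
#'
#' @inheritParams interface_residues
#' @param cutoff distance cutoff in Angstrom (inclusive).
#' @return 2-column integer matrix of atom row indices (column 1 on the
#'   first chain, column 2 on the second); zero rows when no contacts.
#' @export
atomic_contact_pairs <- function(complex, cutoff) {
  if (!is.numeric(cutoff) || cutoff < 0)
    stop_ppi("ppi_config_error", "cutoff must be non-negative")
  keep <- !(complex$atoms$resname %in% WATER_RESNAMES)
  ia <- which(keep & complex$atoms$chain == complex$chain_ids[1])
  ib <- which(keep & complex$atoms$chain == complex$chain_ids[2])
  if (length(ia) == 0 || length(ib) == 0)
    stop_ppi("ppi_structure_error", "empty chain in complex '%s'",
             complex$source_id)
  xyz <- coords(complex)
  d <- cross_dist(xyz[ia, , drop = FALSE], xyz[ib, , drop = FALSE])
  hit <- which(d <= cutoff, arr.ind = TRUE)
  cbind(ia[hit[, 1]], ib[hit[, 2]], deparse.level = 0)
}

#' Receptor and ligand chain identifiers
#'
#' The chain with more residues is the receptor; ties break to the
#' lexicographically smaller chain identifier.
#'
#' @param complex a [make_complex()] object.
#' @return list with elements `receptor` and `ligand` (chain ids).
#' @export
receptor_ligand <- function(complex) {
  uid <- residue_uid(complex)
  n1 <- length(unique(uid[complex$atoms$chain == complex$chain_ids[1]]))
  n2 <- length(unique(uid[complex$atoms$chain == complex$chain_ids[2]]))
  ids <- complex$chain_ids
  if (n1 > n2) r <- ids[1]
  else if (n2 > n1) r <- ids[2]
  else r <- min(ids)
  list(receptor = r, ligand = setdiff(ids, r))
}

#' Apply a rigid transform (rotation then translation) to a complex
#' @param complex a [make_complex()] object.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 numeric vector (Angstrom).
#' @param center point about which the rotation is applied.
#' @return transformed complex.
#' @export
transform_complex <- function(complex, rotation = diag(3),
                              translation = c(0, 0, 0),
                              center = c(0, 0, 0)) {
  xyz <- coords(complex)
  xyz <- sweep(xyz, 2, center)
  xyz <- xyz %*% t(rotation)
  xyz <- sweep(xyz, 2, center + translation, "+")
  complex$atoms$x <- xyz[, 1]
  complex$atoms$y <- xyz[, 2]
  complex$atoms$z <- xyz[, 3]
  complex
}
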