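#' Named feature point set awaiting grid mapping
#'
#' A feature channel before mapping: a set of points, each carrying a
#' position, a value and a Gaussian width sigma (the van der Waals radius
#' of the underlying atom for atomic features, the carbon radius for
#' residue features anchored at the alpha-carbon).
#'
#' @param name channel name, unique within one complex's feature set.
#' @param points data frame with columns `x`, `y`, `z`, `value`, `sigma`.
#' @param level `"atomic"` or `"residue"`.
#' @param chain_tag `"A"`, `"B"` or `"shared"`.
#' @return object of class `ppi_feature_points`.
#' @export
feature_point_set <- function(name, points, level = "atomic",
                              chain_tag = "shared") {
  points <- as.data.frame(points)
  if (nrow(points) > 0 && any(points$sigma <= 0))
    stop_ppi("ppi_feature_error", "feature '%s': all sigmas must be positive", name)
  structure(list(name = name, points = points, level = level,
                 chain_tag = chain_tag),
            class = "ppi_feature_points")
}

## Positional chain tag: first chain id -> "A", second -> "B".
chain_tags <- function(complex) {
  stats::setNames(c("A", "B"), complex$chain_ids)
}

## Atoms belonging to interface residues, as row indices per chain.
interface_atom_idx <- function(complex, selection) {
  uid <- residue_uid(complex)
  lapply(complex$chain_ids, function(ch) {
    which(complex$atoms$chain == ch &
          uid %in% selection$residues_by_chain[[ch]])
  })
}

#' Element-density feature points
#'
#' One channel per element in {C, N, O, S} per chain (8 channels). Each
#' atom of an interface residue contributes one point of value 1 with
#' sigma equal to its element's van der Waals radius. Atoms of other
#' elements are skipped with a warning.
#'
#' @param complex a [make_complex()] object.
#' @param selection an [interface_residues()] selection.
#' @param table a [read_forcefield()] table (radii source).
#' @return named list of [feature_point_set()]s, channels
#'   `density_<element>_<A|B>`.
#' @export
atom_density_points <- function(complex, selection, table = read_forcefield()) {
  idx <- interface_atom_idx(complex, selection)
  tags <- chain_tags(complex)
  elements <- c("C", "N", "O", "S")
  out <- list()
  skipped <- 0
  for (el in elements) {
    for (ci in 1:2) {
      rows <- idx[[ci]][toupper(complex$atoms$element[idx[[ci]]]) == el]
      pts <- data.frame(x = complex$atoms$x[rows], y = complex$atoms$y[rows],
                        z = complex$atoms$z[rows],
                        value = rep(1, length(rows)),
                        sigma = vdw_radius(rep(el, length(rows)), table))
      nm <- sprintf("density_%s_%s", el, tags[ci])
      out[[nm]] <- feature_point_set(nm, pts, "atomic", tags[ci])
    }
  }
  other <- sum(!(toupper(complex$atoms$element[unlist(idx)]) %in% elements))
  if (other > 0)
    warning(sprintf("%d interface atoms of elements outside {C,N,O,S} skipped from density channels",
                    other), call. = FALSE)
  out
}

## Deterministic quasi-uniform points on the unit sphere (golden spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Per atom, the fraction of quasi-uniform test points on the expanded
#' sphere of radius `r_atom + probe` not buried inside any neighbour's
#' expanded sphere, times the expanded-sphere area.
#'
#' @param xyz n x 3 coordinate matrix (Angstrom).
#' @param radii per-atom van der Waals radii (Angstrom).
#' @param probe probe radius, default 1.4 (water).
#' @param n_points sphere test points per atom, default 960 (min 92).
#' @return object of class `ppi_sasa`: list with `per_atom_area` (A^2),
#'   `total`, `probe_radius`, `n_sphere_points`.
#' @export
sasa <- function(xyz, radii, probe = 1.4, n_points = 960) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  if (length(radii) != n || any(radii <= 0))
    stop_ppi("ppi_config_error", "need one positive radius per atom")
  if (n_points < 92)
    stop_ppi("ppi_config_error", "n_points must be >= 92")
  expanded <- radii + probe
  sp <- sphere_points(n_points)
  area <- numeric(n)
  if (n > 1) {
    d <- cross_dist(xyz, xyz)
    if (any(d[upper.tri(d)] == 0))
      stop_ppi("ppi_geometry_error", "coincident atom centers in SASA input")
  }
  for (i in seq_len(n)) {
    pts <- sweep(sp * expanded[i], 2, xyz[i, ], "+")
    if (n > 1) {
      nb <- which(d[i, ] < expanded[i] + expanded & seq_len(n) != i)
    } else nb <- integer(0)
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
             (pts[, 3] - xyz[j, 3])^2
      acc <- acc & (dj2 >= expanded[j]^2)
      if (!any(acc)) break
    }
    area[i] <- sum(acc) / n_points * 4 * pi * expanded[i]^2
  }
  structure(list(per_atom_area = area, total = sum(area),
                 probe_radius = probe, n_sphere_points = n_points),
            class = "ppi_sasa")
}

#' Buried surface area of a two-chain complex
#'
#' Total BSA is `(ASA_chainA + ASA_chainB - ASA_complex) / 2`, each term a
#' Shrake-Rupley accessible surface area of the isolated chain or the full
#' complex. Per-residue burial is the residue's area in the isolated chain
#' minus its area in the complex, floored at zero.
#'
#' @param complex a [make_complex()] object.
#' @param table a [read_forcefield()] table (radii source).
#' @param probe,n_points forwarded to [sasa()].
#' @return list with `total` (A^2) and `per_residue` (named vector, names
#'   `"<chain>:<residue uid>"`).
#' @export
bsa <- function(complex, table = read_forcefield(), probe = 1.4,
                n_points = 960) {
  at <- complex$atoms
  radii <- vdw_radius(at$element, table)
  xyz <- coords(complex)
  s_all <- sasa(xyz, radii, probe, n_points)
  uid <- residue_uid(complex)
  key <- paste(at$chain, uid, sep = ":")
  per_res <- numeric(0)
  asa_chain <- numeric(2)
  for (ci in 1:2) {
    rows <- which(at$chain == complex$chain_ids[ci])
    s_alone <- sasa(xyz[rows, , drop = FALSE], radii[rows], probe, n_points)
    asa_chain[ci] <- s_alone$total
    buried <- tapply(s_alone$per_atom_area - s_all$per_atom_area[rows],
                     key[rows], sum)
    buried[buried < 0] <- 0
    per_res <- c(per_res, buried)
  }
  list(total = (asa_chain[1] + asa_chain[2] - s_all$total) / 2,
       per_residue = per_res,
       asa_chain = stats::setNames(asa_chain, complex$chain_ids),
       asa_complex = s_all$total)
}

#' Read a PSSM profile
#'
#' Tab-separated dialect with header
#' `resnum resname A R N D C Q E G H I L K M F P S T W Y V IC`:
#' one row per residue carrying 20 log-odds scores plus information
#' content.
#'
#' @param text profile contents (single string or lines), or use `path`.
#' @param path file to read instead of `text`.
#' @param chain_id optional chain this profile describes.
#' @return object of class `ppi_pssm`: list with `chain_id` and `rows`
#'   (data frame: `resnum`, `resname`, the 20 score columns, `IC`).
#' @export
read_pssm <- function(text = NULL, path = NULL, chain_id = NA_character_) {
  if (is.null(text)) text <- readLines(path, warn = FALSE)
  lines <- if (length(text) == 1) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- lines[nzchar(trimws(lines))]
  expected <- c("resnum", "resname", PSSM_COLS, "IC")
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!identical(trimws(hdr), expected))
    stop_ppi("ppi_format_error", "PSSM header must be: %s",
             paste(expected, collapse = " "))
  rows <- lapply(seq_along(lines[-1]), function(i) {
    f <- strsplit(lines[i + 1], "\t", fixed = TRUE)[[1]]
    if (length(f) != 23)
      stop_ppi("ppi_format_error",
               "PSSM row %d has %d fields, expected 23", i, length(f))
    f
  })
  m <- do.call(rbind, rows)
  df <- data.frame(resnum = as.integer(m[, 1]), resname = m[, 2],
                   stringsAsFactors = FALSE)
  scores <- apply(m[, 3:22, drop = FALSE], 2, as.numeric)
  if (length(rows) == 1) scores <- matrix(scores, nrow = 1)
  colnames(scores) <- PSSM_COLS
  df <- cbind(df, scores)
  df$IC <- as.numeric(m[, 23])
  if (any(is.na(as.matrix(df[, c(PSSM_COLS, "IC")]))))
    stop_ppi("ppi_format_error", "non-numeric PSSM scores")
  structure(list(chain_id = chain_id, rows = df), class = "ppi_pssm")
}

#' Write a PSSM profile in the package dialect
#' @param profile a [read_pssm()] object.
#' @param path optional output file.
#' @return the profile text (invisibly when `path` is given).
#' @export
write_pssm <- function(profile, path = NULL) {
  df <- profile$rows
  hdr <- paste(c("resnum", "resname", PSSM_COLS, "IC"), collapse = "\t")
  body <- apply(df, 1, function(r) paste(trimws(r), collapse = "\t"))
  out <- paste(c(hdr, body), collapse = "\n")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

## One-letter code for a 3- or 1-letter residue name (NA if unknown).
residue_letter <- function(resname) {
  resname <- toupper(resname)
  out <- ifelse(nchar(resname) == 1, resname, unname(AA1[resname]))
  out
}

## Alpha-carbon row index for each requested residue uid on a chain.
ca_index <- function(complex, chain, uids) {
  uid <- residue_uid(complex)
  vapply(uids, function(u) {
    i <- which(complex$atoms$chain == chain & uid == u &
               complex$atoms$name == "CA")
    if (length(i) == 0)
      stop_ppi("ppi_structure_error",
               "residue %s:%s has no alpha carbon", chain, u)
    i[1]
  }, integer(1))
}

#' PSSM feature points (20 shared channels)
#'
#' For every interface residue of either chain and each of the 20
#' residue-type columns, one point at the residue's alpha carbon whose
#' value is that column's log-odds score; sigma is the carbon van der
#' Waals radius. Both chains map into the same 20 channels.
#'
#' @param complex a [make_complex()] object.
#' @param selection an [interface_residues()] selection.
#' @param profiles named list of [read_pssm()] profiles, one per chain id.
#' @param table a [read_forcefield()] table (carbon radius source).
#' @return named list of 20 [feature_point_set()]s, `pssm_A` .. `pssm_V`.
#' @export
pssm_feature_points <- function(complex, selection, profiles,
                                table = read_forcefield()) {
  missing_chain <- setdiff(complex$chain_ids, names(profiles))
  if (length(missing_chain) > 0)
    stop_ppi("ppi_alignment_error", "no PSSM profile for chain %s",
             paste(missing_chain, collapse = ", "))
  sig_c <- vdw_radius("C", table)
  pts <- list()
  for (ch in complex$chain_ids) {
    uids <- selection$residues_by_chain[[ch]]
    if (length(uids) == 0) next
    prof <- profiles[[ch]]$rows
    rowi <- match(uids, as.character(prof$resnum))
    if (anyNA(rowi))
      stop_ppi("ppi_alignment_error",
               "chain %s interface residue(s) %s missing from PSSM profile",
               ch, paste(uids[is.na(rowi)], collapse = ", "))
    cai <- ca_index(complex, ch, uids)
    want <- residue_letter(complex$atoms$resname[cai])
    got <- residue_letter(prof$resname[rowi])
    bad <- which(!is.na(want) & want != got)
    if (length(bad) > 0)
      stop_ppi("ppi_alignment_error",
               "chain %s residue %s: PSSM says %s, structure says %s",
               ch, uids[bad[1]], got[bad[1]], want[bad[1]])
    pts[[ch]] <- list(cai = cai, scores = as.matrix(prof[rowi, PSSM_COLS]))
  }
  out <- list()
  for (col in PSSM_COLS) {
    df <- do.call(rbind, lapply(complex$chain_ids, function(ch) {
      p <- pts[[ch]]
      if (is.null(p)) return(NULL)
      data.frame(x = complex$atoms$x[p$cai], y = complex$atoms$y[p$cai],
                 z = complex$atoms$z[p$cai], value = p$scores[, col],
                 sigma = sig_c)
    }))
    if (is.null(df))
      df <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                       value = numeric(0), sigma = numeric(0))
    nm <- paste0("pssm_", col)
    out[[nm]] <- feature_point_set(nm, df, "residue", "shared")
  }
  out
}

#' Residue-contact-count feature points (optional, off by default)
#'
#' For each interface residue, counts of its cross-chain residue contacts
#' partitioned by partner class (charged / polar / apolar), anchored at
#' the alpha carbon. Six channels: three classes per chain.
#'
#' @param complex a [make_complex()] object.
#' @param selection an [interface_residues()] selection.
#' @param classes list partitioning the 20 one-letter residue types into
#'   `charged`, `polar`, `apolar` (default the built-in charged/polar/apolar partition).
#' @param table a [read_forcefield()] table.
#' @return named list of 6 [feature_point_set()]s,
#'   `contacts_<class>_<A|B>`.
#' @export
residue_contact_counts <- function(complex, selection,
                                   classes = RESIDUE_CLASSES,
                                   table = read_forcefield()) {
  uid <- residue_uid(complex)
  pr <- unique(data.frame(
    u1 = uid[selection$contact_atom_pairs[, 1]],
    u2 = uid[selection$contact_atom_pairs[, 2]],
    r1 = complex$atoms$resname[selection$contact_atom_pairs[, 1]],
    r2 = complex$atoms$resname[selection$contact_atom_pairs[, 2]],
    stringsAsFactors = FALSE))
  class_of <- function(resname) {
    l <- residue_letter(resname)
    cl <- rep(NA_character_, length(l))
    for (k in names(classes)) cl[l %in% classes[[k]]] <- k
    unk <- is.na(cl)
    if (any(unk)) {
      warning(sprintf("%d residue types outside the class table treated as apolar",
                      sum(unk)), call. = FALSE)
      cl[unk] <- "apolar"
    }
    cl
  }
  tags <- chain_tags(complex)
  sig_c <- vdw_radius("C", table)
  out <- list()
  for (ci in 1:2) {
    ch <- complex$chain_ids[ci]
    uids <- selection$residues_by_chain[[ch]]
    own <- if (ci == 1) pr$u1 else pr$u2
    partner_class <- class_of(if (ci == 1) pr$r2 else pr$r1)
    cai <- ca_index(complex, ch, uids)
    for (k in names(classes)) {
      counts <- vapply(uids, function(u) sum(own == u & partner_class == k),
                       numeric(1))
      nm <- sprintf("contacts_%s_%s", k, tags[ci])
      out[[nm]] <- feature_point_set(
        nm, data.frame(x = complex$atoms$x[cai], y = complex$atoms$y[cai],
                       z = complex$atoms$z[cai], value = unname(counts),
                       sigma = sig_c),
        "residue", tags[ci])
    }
  }
  out
}
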