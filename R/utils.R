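#' @keywords internal
"_PACKAGE"

## Amino-acid code tables used across modules.
AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
         "F", "P", "S", "T", "W", "Y", "V")
names(AA1) <- AA3

## Column order of the 20 residue-type scores in PSSM profiles.
PSSM_COLS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
               "M", "F", "P", "S", "T", "W", "Y", "V")

## Residue classes used by the optional residue-contact-count feature.
## Configurable via the `classes` argument of residue_contact_counts().
RESIDUE_CLASSES <- list(
  charged = c("D", "E", "K", "R"),
  polar   = c("C", "H", "N", "Q", "S", "T", "W", "Y"),
  apolar  = c("A", "F", "G", "I", "L", "M", "P", "V")
)

## Water residue names excluded from interface detection.
WATER_RESNAMES <- c("HOH", "WAT", "H2O", "DOD", "TIP")

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded generators do not disturb
#' the caller's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a bounded child seed from a parent seed
#'
#' Keeps derived seeds within 32-bit integer range.
#' @noRd
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483647)
}

#' Euclidean distance matrix between two coordinate sets
#'
#' @param a,b numeric matrices, n x 3 and m x 3.
#' @return n x m matrix of pairwise distances in the units of the input.
#' @noRd
cross_dist <- function(a, b) {
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

stop_ppi <- function(class, msg, ...) {
  stop(structure(class = c(class, "ppirank_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}
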