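#' Default run configuration
#'
#' Flat key-value configuration covering the whole pipeline. Keys are
#' `section.key` strings; [read_run_config()] parses INI-style files into
#' this structure and rejects unknown keys.
#'
#' @return named list of defaults:
#' \describe{
#'   \item{grid.size}{grid edge length, Angstrom (30)}
#'   \item{grid.resolution}{lattice spacing, Angstrom (1)}
#'   \item{grid.cutoff}{interface cutoff, Angstrom (5.5)}
#'   \item{augment.rotations}{entries per model incl. the unrotated one (1)}
#'   \item{augment.seed}{augmentation RNG seed (1)}
#'   \item{features.include}{feature families (density, charge, coulomb,
#'     vdw, bsa, pssm)}
#'   \item{features.sasa_points}{sphere points for BSA (960)}
#'   \item{targets.hit_threshold}{near-native iRMSD threshold, Angstrom (4)}
#'   \item{model.task}{classification or regression}
#'   \item{model.preset}{adam or sgd preset}
#'   \item{training.batch_size,training.max_epochs,training.patience,
#'     training.seed}{training loop controls}
#' }
#' @export
default_config <- function() {
  list(
    grid.size = 30, grid.resolution = 1.0, grid.cutoff = 5.5,
    augment.rotations = 1L, augment.seed = 1L,
    features.include = c("density", "charge", "coulomb", "vdw", "bsa",
                         "pssm"),
    features.sasa_points = 960L,
    targets.hit_threshold = 4.0,
    model.task = "classification", model.preset = "adam",
    training.batch_size = NA_integer_, training.max_epochs = 30L,
    training.patience = 10L, training.seed = 1L)
}

#' Read an INI-style run configuration
#'
#' Sections `[grid]`, `[augment]`, `[features]`, `[targets]`, `[model]`,
#' `[training]` with `key = value` lines; `#` comments. Values are
#' coerced to the type of the corresponding default; comma-separated
#' lists become character vectors. Unknown keys are rejected.
#'
#' @param path configuration file.
#' @param defaults base configuration to override.
#' @return the merged configuration list, with attribute `hash` (also
#'   available via [config_hash()]).
#' @export
read_run_config <- function(path, defaults = default_config()) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  cfg <- defaults
  section <- ""
  for (ln in lines) {
    if (grepl("^\\[", ln)) {
      section <- gsub("\\[|\\]", "", ln)
      next
    }
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2)
      stop_ppi("ppi_config_error", "malformed config line: '%s'", ln)
    key <- paste0(section, ".", trimws(kv[1]))
    if (!(key %in% names(defaults)))
      stop_ppi("ppi_config_error", "unknown config key '%s'", key)
    val <- trimws(kv[2])
    ref <- defaults[[key]]
    cfg[[key]] <- if (identical(val, "NA")) ref[NA_integer_]
                  else if (is.numeric(ref)) as.numeric(val)
                  else if (length(ref) > 1 || grepl(",", val))
                    trimws(strsplit(val, ",")[[1]])
                  else val
  }
  attr(cfg, "hash") <- config_hash(cfg)
  cfg
}

#' Hash of a configuration (recorded into outputs for provenance)
#' @param config a configuration list.
#' @return short character hash.
#' @export
config_hash <- function(config) {
  attr(config, "hash") <- NULL
  substr(digest::digest(config), 1, 12)
}

#' Serialize the effective configuration next to outputs
#' @param config configuration list.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  keys <- names(config)
  secs <- sub("\\..*$", "", keys)
  out <- c()
  for (s in unique(secs)) {
    out <- c(out, sprintf("[%s]", s))
    for (k in keys[secs == s]) {
      v <- config[[k]]
      out <- c(out, sprintf("%s = %s", sub("^[^.]*\\.", "", k),
                            paste(v, collapse = ",")))
    }
    out <- c(out, "")
  }
  out <- c(out, sprintf("# config hash: %s", config_hash(config)))
  writeLines(out, path)
  invisible(path)
}
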