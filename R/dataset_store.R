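## HDF5 persistence of featurized complexes: one group per model holding
## the mapped feature channels, the grid axis coordinates, the target
## values and provenance attributes. Reading streams deterministic
## (sorted-id) selections with optional channel subsetting and
## target-value filters.

#' Construct a dataset entry
#'
#' @param model_id unique model identifier within a file.
#' @param case_id the complex/case this model belongs to.
#' @param grid a [featurize_complex()] feature grid.
#' @param targets named list of target values (numeric or character),
#'   e.g. from [compute_targets()]; may be `NULL`.
#' @param seed augmentation seed recorded as metadata.
#' @param config_hash configuration hash recorded as metadata.
#' @return object of class `ppi_dataset_entry`.
#' @export
dataset_entry <- function(model_id, case_id, grid, targets = NULL,
                          seed = NA_integer_, config_hash = "") {
  if (!nzchar(case_id)) stop_ppi("ppi_store_error", "case_id must be non-empty")
  structure(list(model_id = model_id, case_id = case_id, grid = grid,
                 targets = targets, seed = seed, config_hash = config_hash),
            class = "ppi_dataset_entry")
}

h5_model_ids <- function(path) {
  ls <- rhdf5::h5ls(path, recursive = FALSE)
  if (nrow(ls) == 0) character(0) else ls$name
}

#' Write dataset entries to an HDF5 file
#'
#' Layout: `/<model_id>/mapped_features/<channel>` (3D arrays),
#' `/<model_id>/grid_points/{x,y,z}`, `/<model_id>/targets/<name>`, and
#' group attributes `case_id`, `seed`, `config_hash`. Appendable: an
#' existing file gains new groups; duplicate model ids are rejected
#' before anything is written.
#'
#' @param path HDF5 file path (created if absent).
#' @param entries list of [dataset_entry()] objects.
#' @return `path`, invisibly.
#' @export
write_entries <- function(path, entries) {
  if (inherits(entries, "ppi_dataset_entry")) entries <- list(entries)
  ids <- vapply(entries, function(e) e$model_id, character(1))
  if (anyDuplicated(ids))
    stop_ppi("ppi_store_error", "duplicate model_id among entries: %s",
             ids[duplicated(ids)][1])
  dims <- vapply(entries, function(e) paste(e$grid$spec$n, collapse = "x"),
                 character(1))
  if (length(unique(dims)) > 1)
    stop_ppi("ppi_store_error", "inconsistent grid dimensions across entries")
  if (!file.exists(path)) rhdf5::h5createFile(path)
  existing <- h5_model_ids(path)
  clash <- intersect(ids, existing)
  if (length(clash) > 0)
    stop_ppi("ppi_store_error", "model_id already present in %s: %s",
             path, clash[1])
  on.exit(rhdf5::h5closeAll())
  for (e in entries) {
    g <- e$model_id
    rhdf5::h5createGroup(path, g)
    rhdf5::h5createGroup(path, paste0(g, "/mapped_features"))
    for (ch in names(e$grid$channels))
      rhdf5::h5write(e$grid$channels[[ch]], path,
                     paste0(g, "/mapped_features/", ch))
    rhdf5::h5createGroup(path, paste0(g, "/grid_points"))
    ax <- c("x", "y", "z")
    for (i in 1:3)
      rhdf5::h5write(e$grid$spec$coords[[i]], path,
                     paste0(g, "/grid_points/", ax[i]))
    rhdf5::h5write(names(e$grid$channels), path,
                   paste0(g, "/channel_order"))
    if (!is.null(e$targets) && length(e$targets) > 0) {
      rhdf5::h5createGroup(path, paste0(g, "/targets"))
      for (tn in names(e$targets))
        rhdf5::h5write(e$targets[[tn]], path, paste0(g, "/targets/", tn))
    }
    fid <- rhdf5::H5Fopen(path)
    gid <- rhdf5::H5Gopen(fid, g)
    rhdf5::h5writeAttribute(e$case_id, gid, "case_id")
    rhdf5::h5writeAttribute(as.integer(e$seed), gid, "seed")
    rhdf5::h5writeAttribute(e$config_hash, gid, "config_hash")
    rhdf5::H5Gclose(gid)
    rhdf5::H5Fclose(fid)
  }
  invisible(path)
}

read_entry_targets <- function(path, id) {
  ls <- rhdf5::h5ls(path, recursive = TRUE)
  tg <- ls[ls$group == paste0("/", id, "/targets"), "name"]
  out <- list()
  for (tn in tg)
    out[[tn]] <- as.vector(rhdf5::h5read(path, paste0(id, "/targets/", tn)))
  out
}

apply_filter <- function(value, op, bound) {
  switch(op,
         "<"  = value < bound,
         "<=" = value <= bound,
         ">"  = value > bound,
         ">=" = value >= bound,
         "="  = value == bound,
         "==" = value == bound,
         stop_ppi("ppi_selection_error", "unknown comparator '%s'", op))
}

#' Read a selection of entries from an HDF5 dataset
#'
#' Entries are iterated in sorted model-id order (independent of write
#' order). Channels are stacked in the requested order into a 4D tensor
#' `(nx, ny, nz, channel)`. Entries failing the target filter are
#' skipped; an impossible filter yields an empty list, not an error.
#'
#' @param path HDF5 file path.
#' @param channels channel names to load, in order; `NULL` loads the
#'   stored channel order.
#' @param target name of the target to return as `y` (optional).
#' @param filter optional list `list(name=, op=, value=)` with comparator
#'   one of `<, <=, >, >=, =`.
#' @return list of entries, each a list with `model_id`, `case_id`, `x`
#'   (4D array with channel dimnames), and `y` (target value or `NULL`),
#'   plus `targets` (all stored targets).
#' @export
read_selection <- function(path, channels = NULL, target = NULL,
                           filter = NULL) {
  on.exit(rhdf5::h5closeAll())
  ids <- sort(h5_model_ids(path))
  out <- list()
  for (id in ids) {
    stored <- as.vector(rhdf5::h5read(path, paste0(id, "/channel_order")))
    want <- if (is.null(channels)) stored else channels
    missing_ch <- setdiff(want, stored)
    if (length(missing_ch) > 0)
      stop_ppi("ppi_selection_error", "unknown channel '%s' in %s",
               missing_ch[1], id)
    targets <- read_entry_targets(path, id)
    if (!is.null(filter)) {
      if (!(filter$name %in% names(targets)))
        stop_ppi("ppi_selection_error", "unknown target '%s' in %s",
                 filter$name, id)
      if (!apply_filter(targets[[filter$name]], filter$op, filter$value))
        next
    }
    y <- NULL
    if (!is.null(target)) {
      if (!(target %in% names(targets)))
        stop_ppi("ppi_selection_error", "unknown target '%s' in %s",
                 target, id)
      y <- targets[[target]]
    }
    arrs <- lapply(want, function(ch)
      rhdf5::h5read(path, paste0(id, "/mapped_features/", ch)))
    x <- array(unlist(arrs, use.names = FALSE),
               dim = c(dim(arrs[[1]]), length(want)))
    dimnames(x) <- c(rep(list(NULL), 3), list(want))
    case_id <- as.vector(rhdf5::h5readAttributes(path, id)$case_id)
    out[[length(out) + 1]] <- list(model_id = id, case_id = case_id,
                                   x = x, y = y, targets = targets)
  }
  out
}

#' Complex-level grouped k-fold assignment
#'
#' Cases are shuffled by seed and cut into `k` disjoint test blocks of
#' size `floor(n/k)`; leftover cases are never tested. Within each fold,
#' `n_val_cases` validation cases are drawn from the non-test cases and
#' the remainder trains. Train, validation and test sets are pairwise
#' disjoint at the case level, and no case appears in two folds' test
#' blocks.
#'
#' @param case_ids character vector of case identifiers.
#' @param k number of folds (>= 2).
#' @param n_val_cases validation cases per fold; default the test block
#'   size.
#' @param seed integer shuffle seed.
#' @return object of class `ppi_folds`: list with `k` and `folds`, each
#'   fold a list of `train`, `val`, `test` case-id vectors.
#' @export
grouped_kfold <- function(case_ids, k, n_val_cases = NULL, seed = 1) {
  case_ids <- unique(as.character(case_ids))
  n <- length(case_ids)
  if (k < 2 || k > n)
    stop_ppi("ppi_config_error", "need 2 <= k <= number of cases")
  b <- floor(n / k)
  if (is.null(n_val_cases)) n_val_cases <- b
  if (n_val_cases + b >= n)
    stop_ppi("ppi_config_error", "not enough cases for validation + test blocks")
  shuffled <- with_seed(seed, sample(case_ids))
  folds <- lapply(seq_len(k), function(i) {
    test <- shuffled[((i - 1) * b + 1):(i * b)]
    rest <- setdiff(shuffled, test)
    val <- with_seed(derive_seed(seed, i), sample(rest, n_val_cases))
    list(train = setdiff(rest, val), val = val, test = test)
  })
  structure(list(k = k, folds = folds), class = "ppi_folds")
}
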