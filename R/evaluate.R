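#' Rank docking models by score
#'
#' Ascending score (best first); ties break by lexicographic model id so
#' the ordering is deterministic and independent of input order.
#'
#' @param scores named numeric vector (names = model ids).
#' @return character vector of model ids, best first.
#' @export
rank_models <- function(scores) {
  if (any(!is.finite(scores)))
    stop_ppi("ppi_evaluation_error", "non-finite scores")
  names(scores)[order(scores, names(scores), method = "radix")]
}

#' Per-case hit-rate curve
#'
#' For each depth K, the number of near-native models among the top K of
#' the ordering, divided by M (the case's total number of near-native
#' models).
#'
#' @param ordering model ids, best first (see [rank_models()]).
#' @param labels named binary labels (1/"near-native" = hit) covering
#'   every id in `ordering`.
#' @param case_id case identifier carried on the result.
#' @return object of class `ppi_ranking`: list with `case_id`,
#'   `ordering`, `labels` (0/1 in rank order), `M` and `hit_rate`
#'   (numeric vector over K = 1..total).
#' @export
hit_rate_curve <- function(ordering, labels, case_id = "case") {
  if (!is.null(names(labels))) labels <- labels[ordering]
  y <- as_binary_labels(labels)
  if (anyNA(y) || length(y) != length(ordering))
    stop_ppi("ppi_evaluation_error", "labels must cover the full ordering")
  M <- sum(y)
  if (M == 0)
    stop_ppi("ppi_evaluation_error",
             "case '%s' has no near-native models; hit rate undefined",
             case_id)
  structure(list(case_id = case_id, ordering = ordering, labels = y,
                 M = M, hit_rate = cumsum(y) / M),
            class = "ppi_ranking")
}

#' Cross-case hit-rate statistics
#'
#' Median and 25/75% quantiles (linear interpolation) of the per-case
#' hit-rate curves, evaluated only up to `N_min`, the smallest number of
#' models any case has.
#'
#' @param cases list of [hit_rate_curve()] results.
#' @return data frame with columns `K`, `median`, `q25`, `q75`.
#' @export
hit_rate_statistics <- function(cases) {
  if (length(cases) == 0)
    stop_ppi("ppi_evaluation_error", "no cases")
  n_min <- min(vapply(cases, function(c) length(c$hit_rate), integer(1)))
  m <- vapply(cases, function(c) c$hit_rate[seq_len(n_min)],
              numeric(n_min))
  m <- matrix(m, nrow = n_min)
  data.frame(K = seq_len(n_min),
             median = apply(m, 1, stats::median),
             q25 = apply(m, 1, stats::quantile, probs = 0.25),
             q75 = apply(m, 1, stats::quantile, probs = 0.75))
}

#' Success rate across cases
#'
#' The fraction of cases with at least one near-native model among their
#' top K. Cases without any near-native model count as failures at every
#' K.
#'
#' @param cases list of [hit_rate_curve()] results; entries may also be
#'   plain 0/1 label vectors in rank order (for cases with zero hits).
#' @param K depths at which to evaluate; default 1 up to the largest
#'   case size.
#' @return data frame with columns `K` and `success_rate`, plus
#'   attribute `n_cases`.
#' @export
success_rate <- function(cases, K = NULL) {
  if (length(cases) == 0)
    stop_ppi("ppi_evaluation_error", "no cases")
  label_vec <- lapply(cases, function(c)
    if (inherits(c, "ppi_ranking")) c$labels else as_binary_labels(c))
  sizes <- vapply(label_vec, length, integer(1))
  if (is.null(K)) K <- seq_len(max(sizes))
  first_hit <- vapply(label_vec, function(y) {
    w <- which(y == 1)
    if (length(w) == 0) Inf else w[1]
  }, numeric(1))
  sr <- vapply(K, function(k) mean(first_hit <= k), numeric(1))
  out <- data.frame(K = K, success_rate = sr)
  attr(out, "n_cases") <- length(cases)
  out
}

#' HADDOCK stage scoring functions
#'
#' `it0` (rigid body): `0.01 E_vdw + 1.0 E_elec + 1.0 E_desol - 0.01 BSA`;
#' `it1` (semi-flexible): `1.0 E_vdw + 1.0 E_elec + 1.0 E_desol -
#' 0.01 BSA`; `itw` (water refined): `1.0 E_vdw + 0.2 E_elec +
#' 1.0 E_desol` (BSA ignored). Restraint energy terms are not included.
#' The desolvation energy is an input, never computed here.
#'
#' @param stage one of `"it0"`, `"it1"`, `"itw"`.
#' @param e_vdw,e_elec,e_desol energy terms in kcal/mol.
#' @param bsa buried surface area in A^2.
#' @return the stage score.
#' @export
haddock_score <- function(stage, e_vdw, e_elec, e_desol, bsa = 0) {
  if (any(!is.finite(c(e_vdw, e_elec, e_desol, bsa))))
    stop_ppi("ppi_evaluation_error", "non-finite energy terms")
  switch(stage,
         it0 = 0.01 * e_vdw + 1.0 * e_elec + 1.0 * e_desol - 0.01 * bsa,
         it1 = 1.0 * e_vdw + 1.0 * e_elec + 1.0 * e_desol - 0.01 * bsa,
         itw = 1.0 * e_vdw + 0.2 * e_elec + 1.0 * e_desol,
         stop_ppi("ppi_config_error", "unknown stage '%s'", stage))
}

#' Write per-case and summary evaluation reports
#'
#' @param cases list of [hit_rate_curve()] results.
#' @param scores named list (by case id) of the named score vectors used
#'   to build the orderings.
#' @param out_dir directory for `case_<id>.csv` files (rank, model_id,
#'   score, label) and `summary.csv` (K, median/q25/q75 hit rate,
#'   success rate).
#' @return `out_dir`, invisibly.
#' @export
write_evaluation_report <- function(cases, scores, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (c in cases) {
    df <- data.frame(rank = seq_along(c$ordering), model_id = c$ordering,
                     score = unname(scores[[c$case_id]][c$ordering]),
                     label = c$labels)
    utils::write.csv(df, file.path(out_dir,
                                   paste0("case_", c$case_id, ".csv")),
                     row.names = FALSE)
  }
  hr <- hit_rate_statistics(cases)
  sr <- success_rate(cases, K = hr$K)
  summary <- cbind(hr, success_rate = sr$success_rate)
  utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}
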