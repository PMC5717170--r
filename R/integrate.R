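#' Classify the outcome relation of a score
#'
#' Negative scores mark adverse genes (high expression, poor prognosis),
#' positive scores favorable genes; an exact zero is related to neither.
#'
#' @param score Numeric vector of finite scores.
#' @return Character vector over `"adverse"`, `"favorable"`, `"none"`.
#' @export
classify_outcome_relation <- function(score) {
  if (any(!is.finite(score))) {
    ipp_stop("outcome relation undefined for non-finite scores", "non_finite_score")
  }
  ifelse(score < 0, "adverse", ifelse(score > 0, "favorable", "none"))
}

#' Combine per-dataset scores with Liptak's weighted method
#'
#' Weighted Stouffer--Liptak combination of per-dataset IPP scores into one
#' representative score per gene, weighting each dataset by the square root
#' of its patient count: with w_d = sqrt(n_d),
#' \deqn{S = \sum_d w_d S_d / \sqrt{\sum_d w_d^2}.}
#' Only genes present in every supplied dataset are combined; genes missing
#' from any dataset are dropped with a warning.
#'
#' @param scores Named list (one element per dataset) of named numeric score
#'   vectors, or of `"ipp"` fits.
#' @param sizes Numeric vector of per-dataset patient counts, parallel to
#'   `scores`. Defaults to the fits' own `n_patients` when `scores` holds
#'   `"ipp"` objects.
#' @param null_sd Optional numeric vector of per-dataset null score standard
#'   deviations (e.g. the `sd` column of [null_ipp_distribution()] at each
#'   dataset's size). When supplied, each dataset's scores are divided by
#'   its null SD before combination, putting datasets of different sizes on
#'   a common z-like scale. Default `NULL`: scores are combined raw.
#' @return data.frame of class `"ipp_integrated"` with columns `gene_id`,
#'   `combined_score`, `n_datasets`, `outcome_relation`, plus a
#'   `"per_dataset"` attribute (dataset label, score, n_patients, weight per
#'   gene-dataset pair in matrix form).
#' @examples
#' liptak_combine(list(a = c(g1 = 1.0), b = c(g1 = -0.5)), sizes = c(100, 25))
#' @export
liptak_combine <- function(scores, sizes = NULL, null_sd = NULL) {
  if (length(scores) == 0L) ipp_stop("no datasets supplied", "no_datasets")
  is_fit <- vapply(scores, inherits, logical(1L), what = "ipp")
  if (is.null(sizes)) {
    if (!all(is_fit)) {
      ipp_stop("sizes must be given unless all score sets are 'ipp' fits",
               "missing_sizes")
    }
    sizes <- vapply(scores, function(f) f$n_patients, numeric(1L))
  }
  stopifnot(length(sizes) == length(scores), all(sizes >= 1))
  vecs <- lapply(scores, function(s) if (inherits(s, "ipp")) s$scores else s)
  if (!is.null(null_sd)) {
    stopifnot(length(null_sd) == length(vecs), all(null_sd > 0))
    vecs <- Map(function(v, s) v / s, vecs, null_sd)
  }
  if (is.null(names(vecs)) || any(!nzchar(names(vecs)))) {
    names(vecs) <- paste0("dataset", seq_along(vecs))
  }
  universe <- unique(unlist(lapply(vecs, names)))
  shared <- Reduce(intersect, lapply(vecs, names))
  dropped <- setdiff(universe, shared)
  if (length(dropped)) {
    ipp_warn(sprintf("%d gene(s) absent from >=1 dataset dropped from integration",
                     length(dropped)), "partial_gene_universe")
  }
  if (length(shared) == 0L) ipp_stop("no gene present in every dataset", "no_shared_genes")
  shared <- sort(shared)
  w <- sqrt(sizes)
  mat <- vapply(vecs, function(v) v[shared], numeric(length(shared)))
  mat <- matrix(mat, nrow = length(shared),
                dimnames = list(shared, names(vecs)))
  combined <- as.vector(mat %*% w) / sqrt(sum(w^2))
  out <- data.frame(gene_id = shared,
                    combined_score = combined,
                    n_datasets = length(vecs),
                    outcome_relation = classify_outcome_relation(combined),
                    row.names = NULL)
  attr(out, "per_dataset") <- list(labels = names(vecs), scores = mat,
                                   n_patients = sizes, weights = w)
  class(out) <- c("ipp_integrated", "data.frame")
  out
}

#' Select the top fraction of genes by absolute score
#'
#' Ranks genes by decreasing |score| and keeps the top `ceiling(fraction *
#' G)`; boundary ties are broken by gene id (ascending) so the selection is
#' deterministic and invariant to input row order.
#'
#' @param table A data.frame with a gene id column and a score column — an
#'   `"ipp"` fit's `table` (`ipp_score`), an `"ipp_integrated"` table
#'   (`combined_score`), or any data.frame whose first column is the gene id
#'   and which has exactly one of those score columns — or a named numeric
#'   vector of scores.
#' @param fraction Fraction of genes to keep, in (0, 1] (default 0.05).
#' @return Character vector of selected gene ids.
#' @examples
#' select_top_fraction(c(a = 0.1, b = -2, c = 1), fraction = 0.34) # "b"
#' @export
select_top_fraction <- function(table, fraction = 0.05) {
  stopifnot(fraction > 0, fraction <= 1)
  if (inherits(table, "ipp")) table <- table$table
  if (is.numeric(table) && !is.null(names(table))) {
    table <- data.frame(gene_id = names(table), score = unname(table))
  }
  score_col <- intersect(c("ipp_score", "combined_score", "score"), colnames(table))
  if (length(score_col) != 1L) {
    ipp_stop("cannot identify a unique score column", "ambiguous_score_column")
  }
  gene_id <- as.character(table[[1L]])
  score <- table[[score_col]]
  k <- as.integer(ceiling(fraction * length(gene_id)))
  ord <- order(-abs(score), gene_id)
  gene_id[ord][seq_len(k)]
}
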