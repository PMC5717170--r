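# Comparison machinery: conventional-threshold log-rank baselines,
# cross-dataset sharing/consistency counts, resampling robustness and the
# null score distribution.

#' Conventional single-threshold log-rank score
#'
#' The baseline IPP is compared against: one log-rank test per gene, with
#' patients split at the gene's mean or median expression. The high group is
#' `expression > threshold`, the low group `expression <= threshold`; the
#' signed z uses the same convention as IPP (negative = high expression at
#' higher risk). A split that leaves one group empty is degenerate and
#' returns 0 with a warning.
#'
#' @param cohort An `"ipp_cohort"`.
#' @param gene Gene identifier.
#' @param rule `"average"` or `"median"`.
#' @return Signed numeric z.
#' @export
threshold_logrank_score <- function(cohort, gene, rule = c("average", "median")) {
  rule <- match.arg(rule)
  if (!gene %in% rownames(cohort$expr)) {
    ipp_stop(sprintf("unknown gene: %s", gene), "unknown_gene")
  }
  x <- cohort$expr[gene, ]
  thr <- if (rule == "average") mean(x) else median(x)
  hi <- x > thr
  if (!any(hi) || all(hi)) {
    ipp_warn(sprintf("degenerate %s-threshold split for %s: one group empty",
                     rule, gene), "degenerate_split")
    return(0)
  }
  logrank_z(data.frame(time = cohort$time[hi], event = cohort$event[hi]),
            data.frame(time = cohort$time[!hi], event = cohort$event[!hi]))$z
}

#' Threshold log-rank scores for every gene in a cohort
#'
#' @inheritParams threshold_logrank_score
#' @return Named numeric vector of signed z-scores.
#' @export
threshold_scores <- function(cohort, rule = c("average", "median")) {
  rule <- match.arg(rule)
  genes <- rownames(cohort$expr)
  vapply(genes, function(g)
    suppressWarnings(threshold_logrank_score(cohort, g, rule)), numeric(1L))
}

#' Genes shared across per-dataset top selections
#'
#' @param top_sets List of character vectors (per-dataset selected genes).
#' @param min_datasets A gene must occur in at least this many sets to count
#'   as shared (default 5).
#' @return List with `genes` (sorted character vector) and `count`.
#' @export
count_shared_genes <- function(top_sets, min_datasets = 5L) {
  stopifnot(length(top_sets) >= min_datasets, min_datasets >= 1L)
  tallies <- table(unlist(lapply(top_sets, unique)))
  genes <- sort(names(tallies)[tallies >= min_datasets])
  list(genes = genes, count = length(genes))
}

# Internal: extract a named score vector from an 'ipp' fit, an integrated
# table, a score data.frame or a named numeric vector.
score_vector <- function(x) {
  if (inherits(x, "ipp")) return(x$scores)
  if (is.numeric(x) && !is.null(names(x))) return(x)
  if (is.data.frame(x)) {
    sc <- intersect(c("ipp_score", "combined_score", "score"), colnames(x))
    if (length(sc) == 1L) return(setNames(x[[sc]], as.character(x[[1L]])))
  }
  ipp_stop("cannot interpret score set", "ambiguous_score_column")
}

#' Outcome-relation consistency across datasets
#'
#' For every gene, counts in how many datasets its score is negative
#' (adverse) and in how many positive (favorable), then tallies the genes
#' whose relation is consistent in at least `min_datasets` of the D
#' datasets. Exact-zero scores are counted on neither side (and logged),
#' so for such genes the two counts sum to less than D.
#'
#' @param score_tables List of per-dataset score sets (`"ipp"` fits, score
#'   data.frames or named vectors) over the same gene universe.
#' @param min_datasets Consistency threshold m (default 17).
#' @return Object of class `"ipp_consistency"`: list with `per_gene`
#'   (data.frame `gene_id`, `n_adverse`, `n_favorable`), `n_adverse_consistent`,
#'   `n_favorable_consistent`, `n_datasets`, `min_datasets`.
#' @export
outcome_consistency <- function(score_tables, min_datasets = 17L) {
  vecs <- lapply(score_tables, score_vector)
  universe <- sort(names(vecs[[1L]]))
  same <- vapply(vecs, function(v) identical(sort(names(v)), universe), logical(1L))
  if (!all(same)) {
    ipp_stop("score tables do not share one gene universe", "gene_universe_mismatch")
  }
  mat <- vapply(vecs, function(v) v[universe], numeric(length(universe)))
  mat <- matrix(mat, nrow = length(universe))
  n_adverse <- rowSums(mat < 0)
  n_favorable <- rowSums(mat > 0)
  n_zero <- rowSums(mat == 0)
  if (any(n_zero > 0)) {
    ipp_warn(sprintf("%d gene-dataset score(s) are exactly zero; counted as neither relation",
                     sum(n_zero)), "zero_scores_in_consistency")
  }
  structure(
    list(per_gene = data.frame(gene_id = universe, n_adverse = n_adverse,
                               n_favorable = n_favorable, row.names = NULL),
         n_adverse_consistent = sum(n_adverse >= min_datasets),
         n_favorable_consistent = sum(n_favorable >= min_datasets),
         n_datasets = length(vecs),
         min_datasets = as.integer(min_datasets)),
    class = "ipp_consistency"
  )
}

#' @export
print.ipp_consistency <- function(x, ...) {
  cat(sprintf("outcome-relation consistency over %d datasets (threshold >= %d):\n",
              x$n_datasets, x$min_datasets))
  cat(sprintf("  consistently adverse: %d genes; consistently favorable: %d genes\n",
              x$n_adverse_consistent, x$n_favorable_consistent))
  invisible(x)
}

#' One-tailed binomial z-test for shared-gene counts
#'
#' Compares two shared-gene counts k_a and k_b out of the same total gene
#' number with a pooled two-proportion z-test:
#' z = (k_a/total - k_b/total) / sqrt(2 p(1-p)/total) with
#' p = (k_a + k_b)/(2 total); the one-tailed p-value tests the alternative
#' k_a > k_b.
#'
#' @param k_a,k_b Shared-gene counts for the two methods.
#' @param total Total number of genes.
#' @return List with `z` and one-tailed `p`.
#' @examples
#' binomial_shared_test(178, 125, 11123)
#' @export
binomial_shared_test <- function(k_a, k_b, total) {
  stopifnot(total > 0, k_a >= 0, k_b >= 0, k_a <= total, k_b <= total)
  p_hat <- (k_a + k_b) / (2 * total)
  if (p_hat <= 0 || p_hat >= 1) {
    return(list(z = 0, p = if (k_a == k_b) 1 else 0))
  }
  z <- (k_a / total - k_b / total) / sqrt(2 * p_hat * (1 - p_hat) / total)
  list(z = z, p = pnorm(z, lower.tail = FALSE))
}

# Internal: index-subset a cohort (duplicates allowed, for bootstrap draws).
resample_cohort <- function(cohort, idx) {
  structure(
    list(expr = cohort$expr[, idx, drop = FALSE],
         time = cohort$time[idx],
         event = cohort$event[idx],
         endpoint = cohort$endpoint,
         name = cohort$name,
         clinical = cohort$clinical[idx, , drop = FALSE]),
    class = "ipp_cohort"
  )
}

# Internal: scoring function by name.
get_scorer <- function(scorer) {
  switch(scorer,
         ipp = function(co) ipp(co)$scores,
         average = function(co) threshold_scores(co, "average"),
         median = function(co) threshold_scores(co, "median"),
         ipp_stop(sprintf("unknown scorer: %s", scorer), "unknown_scorer"))
}

#' Resampling robustness of gene scores
#'
#' Scores every gene on repeated bootstrap or subsample draws of the cohort
#' and compares the mean resampled score to the full-cohort score: per gene
#' a normalized mean (mean resampled / full score, with near-zero full
#' scores excluded from the aggregate) and, over all genes, the Pearson
#' correlation between full and mean-resampled score vectors.
#'
#' @param cohort An `"ipp_cohort"`.
#' @param scheme `"bootstrap"` (draw `size` with replacement) or
#'   `"subsample"` (draw `size` of the N patients without replacement).
#' @param size Draw size: 2..N for subsampling, >= 2 for bootstrapping.
#' @param n_draws Number of repeated draws (default 1000).
#' @param scorer `"ipp"`, `"average"` or `"median"`.
#' @param seed Integer seed; the summary is fully reproducible given it.
#' @param min_abs_full Genes with |full score| below this are excluded from
#'   the normalized-mean aggregate (ratio instability; default 0.05).
#' @return Object of class `"ipp_resample"`: list with `per_gene`
#'   (data.frame `gene_id`, `full_score`, `mean_resampled_score`,
#'   `normalized_mean`), `pearson_r`, `aggregate_normalized_mean`, `scheme`,
#'   `n_draws`, `subsample_size`, `scorer`.
#' @export
resample_scores <- function(cohort, scheme = c("bootstrap", "subsample"), size,
                            n_draws = 1000L, scorer = c("ipp", "average", "median"),
                            seed = 1L, min_abs_full = 0.05) {
  scheme <- match.arg(scheme)
  scorer <- match.arg(scorer)
  n <- cohort_size(cohort)
  size <- as.integer(size)
  if (size < 2L || (scheme == "subsample" && size > n)) {
    ipp_stop(sprintf("draw size %d out of range for %s over %d patients",
                     size, scheme, n), "size_out_of_range")
  }
  stopifnot(n_draws >= 1L)
  fun <- get_scorer(scorer)
  full <- fun(cohort)
  set.seed(as.integer(seed))
  acc <- numeric(length(full))
  for (d in seq_len(n_draws)) {
    idx <- sample.int(n, size, replace = scheme == "bootstrap")
    acc <- acc + fun(resample_cohort(cohort, idx))
  }
  mean_scores <- acc / n_draws
  keep <- abs(full) >= min_abs_full
  normalized <- ifelse(keep, mean_scores / full, NA_real_)
  structure(
    list(per_gene = data.frame(gene_id = names(full),
                               full_score = unname(full),
                               mean_resampled_score = unname(mean_scores),
                               normalized_mean = unname(normalized),
                               row.names = NULL),
         pearson_r = if (length(full) >= 2L && sd(full) > 0 && sd(mean_scores) > 0)
           cor(full, mean_scores) else NA_real_,
         aggregate_normalized_mean = if (any(keep)) mean(normalized[keep]) else NA_real_,
         scheme = scheme, n_draws = as.integer(n_draws),
         subsample_size = size, scorer = scorer),
    class = "ipp_resample"
  )
}

#' @export
print.ipp_resample <- function(x, ...) {
  cat(sprintf("%s resampling (%s scorer): %d draws of size %d\n",
              x$scheme, x$scorer, x$n_draws, x$subsample_size))
  cat(sprintf("  Pearson r(full, mean resampled) = %.4f; aggregate normalized mean = %.4f\n",
              x$pearson_r, x$aggregate_normalized_mean))
  invisible(x)
}

#' Null IPP score distribution from virtual patient sampling
#'
#' Estimates the distribution of the IPP score under no association: for
#' each requested cohort size, repeatedly generates virtual patients with
#' random survival (see [generate_null_cohort()]) and a random expression
#' ordering, scores the single synthetic gene, and summarizes the scores.
#'
#' @param sample_sizes Integer vector of cohort sizes (>= 2 each).
#' @param n_reps Replicates per size (default 10000).
#' @param seed Integer seed.
#' @return data.frame, one row per size: `n`, `mean`, `sd`, and quantiles
#'   `q01`, `q05`, `q25`, `q50`, `q75`, `q95`, `q99`.
#' @export
null_ipp_distribution <- function(sample_sizes, n_reps = 10000L, seed = 1L) {
  stopifnot(all(sample_sizes >= 2L), n_reps >= 1L)
  set.seed(as.integer(seed))
  rows <- lapply(sample_sizes, function(n) {
    scores <- vapply(seq_len(n_reps), function(r) {
      co <- generate_null_cohort(n, seed = NULL)
      ipp_score(co, rownames(co$expr)[1L])
    }, numeric(1L))
    q <- quantile(scores, c(0.01, 0.05, 0.25, 0.5, 0.75, 0.95, 0.99), names = FALSE)
    data.frame(n = n, mean = mean(scores), sd = sd(scores),
               q01 = q[1], q05 = q[2], q25 = q[3], q50 = q[4],
               q75 = q[5], q95 = q[6], q99 = q[7])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
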