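# Central estimator: iterative patient partitioning.
#
# For one gene, patients are sorted ascending by expression (ties broken by
# sample id, stable). For every pair (i, j) with i >= 1, j >= 1, i + j <= N
# the top-i patients form the high group and the bottom-j the low group; the
# N - i - j middle patients are excluded from that comparison. Each pair
# yields a signed log-rank z (negative = high group at higher risk); there
# are exactly N(N-1)/2 such pairs and their average is the IPP score.

# 0-based expression ranks with stable sample-id tie-break.
expression_ranks <- function(x, sample_ids) {
  ord <- order(x, sample_ids)
  r <- integer(length(x))
  r[ord] <- seq_along(x) - 1L
  r
}

time_order0 <- function(time) order(time) - 1L

#' IPP matrix of one gene
#'
#' Computes the full triangular collection of signed log-rank z-scores Z_ij
#' over every non-overlapping high/low bipartition of the cohort ordered by
#' the gene's expression: i indexes the high-group size, j the low-group
#' size, i + j <= N. Partitions whose log-rank variance is zero contribute
#' Z_ij = 0.
#'
#' @param cohort An `"ipp_cohort"` with at least 2 patients.
#' @param gene Gene identifier (must be a row of the cohort's expression).
#' @return Object of class `"ipp_matrix"`: list with `entries` (data.frame
#'   `i`, `j`, `z` of length N(N-1)/2), `n_patients`, `gene_id`.
#' @examples
#' co <- generate_null_cohort(8, seed = 1)
#' m <- ipp_matrix(co, rownames(co$expr)[1])
#' nrow(m$entries) # 8*7/2 = 28
#' @export
ipp_matrix <- function(cohort, gene) {
  n <- cohort_size(cohort)
  if (n < 2L) ipp_stop("IPP needs at least 2 patients", "too_few_patients")
  if (!gene %in% rownames(cohort$expr)) {
    ipp_stop(sprintf("unknown gene: %s", gene), "unknown_gene")
  }
  rank0 <- expression_ranks(cohort$expr[gene, ], colnames(cohort$expr))
  ent <- .ipp_matrix_cpp(cohort$time, as.integer(cohort$event),
                         time_order0(cohort$time), rank0)
  structure(
    list(entries = data.frame(i = ent$i, j = ent$j, z = ent$z),
         n_patients = n, gene_id = gene),
    class = "ipp_matrix"
  )
}

#' IPP score: average of all partition z-scores
#'
#' The score of gene k is
#' \deqn{S_k = \frac{1}{N(N-1)/2} \sum_{i=1}^{N-1} \sum_{j=1}^{N-i} Z_{ij},}
#' the arithmetic mean of the IPP matrix. The denominator is fixed at
#' N(N-1)/2 even when degenerate partitions were zeroed. A negative score
#' marks an adverse gene (high expression, poor prognosis), a positive score
#' a favorable one.
#'
#' @param x An `"ipp_matrix"`, or an `"ipp_cohort"` (in which case `gene`
#'   selects the gene and the matrix is built internally).
#' @param gene Gene identifier when `x` is a cohort.
#' @return Numeric IPP score.
#' @export
ipp_score <- function(x, gene = NULL) {
  if (inherits(x, "ipp_matrix")) {
    # Sum over canonical (a,b)/(b,a) pairs, matching the compiled scorer's
    # accumulation order, so matrix- and cohort-based scores agree bitwise
    # and expression negation negates the score exactly.
    n <- x$n_patients
    zm <- matrix(0, n - 1L, n - 1L)
    zm[cbind(x$entries$i, x$entries$j)] <- x$entries$z
    total <- 0
    for (a in seq_len(n %/% 2L)) {
      for (b in a:(n - a)) {
        pt <- zm[a, b]
        if (b != a) pt <- pt + zm[b, a]
        total <- total + pt
      }
    }
    return(total / (n * (n - 1) / 2))
  }
  stopifnot(inherits(x, "ipp_cohort"), !is.null(gene))
  n <- cohort_size(x)
  if (n < 2L) ipp_stop("IPP needs at least 2 patients", "too_few_patients")
  if (!gene %in% rownames(x$expr)) {
    ipp_stop(sprintf("unknown gene: %s", gene), "unknown_gene")
  }
  rank0 <- expression_ranks(x$expr[gene, ], colnames(x$expr))
  .ipp_score_cpp(x$time, as.integer(x$event), time_order0(x$time), rank0)
}

#' @export
print.ipp_matrix <- function(x, ...) {
  cat(sprintf("IPP matrix for %s: N = %d patients, %d partitions, score = %.5f\n",
              x$gene_id, x$n_patients, nrow(x$entries), ipp_score(x)))
  invisible(x)
}

#' Plot an IPP matrix
#'
#' Renders the triangular z-score matrix as an image: x = low-group size j,
#' y = high-group size i, blue for favorable (z > 0), red for adverse
#' (z < 0).
#'
#' @param x An `"ipp_matrix"`.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, the z matrix drawn.
#' @export
plot.ipp_matrix <- function(x, ...) {
  n <- x$n_patients
  m <- matrix(NA_real_, n - 1L, n - 1L)
  m[cbind(x$entries$j, x$entries$i)] <- x$entries$z
  lim <- max(abs(x$entries$z), .Machine$double.eps)
  pal <- grDevices::colorRampPalette(c("#b2182b", "white", "#2166ac"))(101L)
  graphics::image(x = seq_len(n - 1L), y = seq_len(n - 1L), z = m,
                  zlim = c(-lim, lim), col = pal,
                  xlab = "low-group size j", ylab = "high-group size i",
                  main = sprintf("%s (IPP score %.4f)", x$gene_id, ipp_score(x)),
                  ...)
  invisible(m)
}

#' Fit IPP scores for a cohort
#'
#' The main entry point: computes the IPP score of every (retained) gene in
#' a cohort and classifies each gene's outcome relation from the score's
#' sign. Apply [filter_invariant_genes()] first to drop near-constant genes;
#' `ipp()` scores whatever genes the cohort carries.
#'
#' @param cohort An `"ipp_cohort"`.
#' @param genes Optional character vector restricting scoring to these genes
#'   (default: all genes in the cohort).
#' @return Object of class `"ipp"`: list with `scores` (named numeric),
#'   `table` (data.frame `gene_id`, `ipp_score`, `n_patients`,
#'   `outcome_relation`), `n_patients`, `endpoint`, `name`, `call`.
#'   `coef()` extracts the score vector.
#' @examples
#' co <- generate_planted_cohort(simulation_config(
#'   n_patients = 40, n_genes = 10, planted = list(g3 = 2), seed = 7))
#' fit <- ipp(co)
#' coef(fit)["g3"] # adverse: strongly negative
#' @export
ipp <- function(cohort, genes = NULL) {
  stopifnot(inherits(cohort, "ipp_cohort"))
  n <- cohort_size(cohort)
  if (n < 2L) ipp_stop("IPP needs at least 2 patients", "too_few_patients")
  if (is.null(genes)) genes <- rownames(cohort$expr)
  missing_genes <- setdiff(genes, rownames(cohort$expr))
  if (length(missing_genes)) {
    ipp_stop(sprintf("unknown gene(s): %s", paste(head(missing_genes, 5L), collapse = ", ")),
             "unknown_gene")
  }
  ids <- colnames(cohort$expr)
  ranks <- vapply(genes, function(g) expression_ranks(cohort$expr[g, ], ids),
                  integer(n))
  ranks <- matrix(as.integer(ranks), nrow = n, ncol = length(genes))
  scores <- .ipp_score_genes_cpp(cohort$time, as.integer(cohort$event),
                                 time_order0(cohort$time), ranks)
  names(scores) <- genes
  structure(
    list(scores = scores,
         table = data.frame(gene_id = genes,
                            ipp_score = unname(scores),
                            n_patients = n,
                            outcome_relation = classify_outcome_relation(scores),
                            row.names = NULL),
         n_patients = n,
         endpoint = cohort$endpoint,
         name = cohort$name,
         call = match.call()),
    class = "ipp"
  )
}

#' @export
print.ipp <- function(x, digits = 5L, ...) {
  cat(sprintf("IPP fit: %d genes, %d patients ('%s', endpoint %s)\n",
              length(x$scores), x$n_patients, x$name, x$endpoint))
  rel <- table(factor(x$table$outcome_relation,
                      levels = c("adverse", "favorable", "none")))
  cat(sprintf("  adverse %d | favorable %d | none %d\n",
              rel[["adverse"]], rel[["favorable"]], rel[["none"]]))
  top <- x$table[order(-abs(x$table$ipp_score)), ]
  cat("  strongest scores:\n")
  print(head(top, 5L), digits = digits, row.names = FALSE)
  invisible(x)
}

#' @export
summary.ipp <- function(object, ...) {
  s <- object$scores
  structure(
    list(n_genes = length(s), n_patients = object$n_patients,
         name = object$name, endpoint = object$endpoint,
         score_summary = summary(s),
         n_adverse = sum(s < 0), n_favorable = sum(s > 0), n_none = sum(s == 0),
         table = object$table),
    class = "summary.ipp"
  )
}

#' @export
print.summary.ipp <- function(x, ...) {
  cat(sprintf("IPP fit on '%s' (%s): %d genes, %d patients\n",
              x$name, x$endpoint, x$n_genes, x$n_patients))
  cat(sprintf("  outcome relation: %d adverse, %d favorable, %d none\n",
              x$n_adverse, x$n_favorable, x$n_none))
  cat("  score distribution:\n")
  print(x$score_summary)
  invisible(x)
}

#' @export
coef.ipp <- function(object, ...) object$scores

#' Plot an IPP fit
#'
#' Histogram of per-gene IPP scores; adverse genes fall left of zero,
#' favorable genes right.
#'
#' @param x An `"ipp"` fit.
#' @param breaks Passed to [graphics::hist()].
#' @param ... Further arguments to [graphics::hist()].
#' @export
plot.ipp <- function(x, breaks = "FD", ...) {
  graphics::hist(x$scores, breaks = breaks,
                 xlab = "IPP score", main = sprintf("IPP scores ('%s')", x$name),
                 col = "grey80", border = "grey40", ...)
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}

#' Write an IPP score table to TSV
#'
#' @param fit An `"ipp"` fit (or its `table`).
#' @param path Output path.
#' @export
write_score_table <- function(fit, path) {
  tab <- if (inherits(fit, "ipp")) fit$table else fit
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
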