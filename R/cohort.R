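#' Read a genes x samples expression matrix from TSV
#'
#' Expects a tab-separated file whose first column holds gene identifiers and
#' whose header row holds sample identifiers; the body must be entirely
#' numeric (normalized expression). Gzip-compressed files are read
#' transparently.
#'
#' @param path Path to the TSV (optionally `.gz`).
#' @return A numeric matrix with gene identifiers as rownames and sample
#'   identifiers as colnames.
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\ts1\ts2", "g1\t0.5\t1.2", "g2\t-1\t0"), tsv)
#' read_expression(tsv)
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) {
    ipp_stop(sprintf("expression file not found: %s", path), "missing_file")
  }
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", quote = "")
  if (ncol(raw) < 2L) {
    ipp_stop("expression table needs a gene id column plus >= 1 sample column",
             "malformed_table")
  }
  gene_ids <- raw[[1L]]
  sample_ids <- colnames(raw)[-1L]
  if (anyDuplicated(gene_ids)) {
    dup <- unique(gene_ids[duplicated(gene_ids)])
    ipp_stop(sprintf("duplicate gene identifiers: %s",
                     paste(head(dup, 5L), collapse = ", ")), "duplicate_identifier")
  }
  if (anyDuplicated(sample_ids)) {
    ipp_stop("duplicate sample identifiers in header", "duplicate_identifier")
  }
  body <- as.matrix(raw[, -1L, drop = FALSE])
  values <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- !is.finite(values)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    ipp_stop(sprintf("non-numeric or non-finite expression value '%s' (gene %s, sample %s)",
                     body[idx[1L], idx[2L]], gene_ids[idx[1L]], sample_ids[idx[2L]]),
             "non_numeric")
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  values
}

#' Read a per-sample clinical table from TSV
#'
#' Requires columns `sample_id`, `time` and `event`; recognises optional
#' receptor-status columns `er`, `pr`, `her2` (values `pos`, `neg` or `NA`)
#' and passes any further columns (e.g. `cna_state`, `mutated`) through
#' untouched. Gzip-compressed files are read transparently.
#'
#' @param path Path to the TSV (optionally `.gz`).
#' @return A data.frame, one row per sample.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) {
    ipp_stop(sprintf("clinical file not found: %s", path), "missing_file")
  }
  clin <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                     stringsAsFactors = FALSE, quote = "")
  required <- c("sample_id", "time", "event")
  missing_cols <- setdiff(required, colnames(clin))
  if (length(missing_cols)) {
    ipp_stop(sprintf("clinical table lacks required column(s): %s",
                     paste(missing_cols, collapse = ", ")), "malformed_table")
  }
  if (anyDuplicated(clin$sample_id)) {
    ipp_stop("duplicate sample_id in clinical table", "duplicate_identifier")
  }
  clin$time <- suppressWarnings(as.numeric(clin$time))
  clin$event <- suppressWarnings(as.numeric(clin$event))
  for (col in intersect(c("er", "pr", "her2"), colnames(clin))) {
    v <- as.character(clin[[col]])
    v[!v %in% c("pos", "neg")] <- NA_character_
    clin[[col]] <- v
  }
  clin
}

#' Assemble an analysis-ready cohort
#'
#' Inner-joins an expression matrix with a clinical table on sample id and
#' drops samples without a usable survival record for the endpoint: `time`
#' must be a positive finite number and `event` must be 0 or 1. Records with
#' `time == 0` are dropped with a warning. The resulting sample order is
#' sorted by sample id, so cohorts are reproducible regardless of input
#' order.
#'
#' @param expr Numeric genes x samples matrix (see [read_expression()]).
#' @param clin Clinical data.frame (see [read_clinical()]).
#' @param endpoint Endpoint label carried on the cohort (e.g. `"DMFS"`,
#'   `"OS"`); purely descriptive.
#' @param name Cohort/dataset label.
#' @return An object of class `"ipp_cohort"`: a list with elements `expr`
#'   (genes x samples matrix), `time`, `event` (aligned to `colnames(expr)`),
#'   `endpoint`, `name`, and `clinical` (the retained clinical rows).
#' @examples
#' expr <- matrix(rnorm(6), 2, 3, dimnames = list(c("g1", "g2"), c("A", "B", "C")))
#' clin <- data.frame(sample_id = c("A", "C"), time = c(5, 2), event = c(1, 0))
#' build_cohort(expr, clin, endpoint = "DMFS")
#' @export
build_cohort <- function(expr, clin, endpoint = "DMFS", name = "cohort") {
  stopifnot(is.matrix(expr), is.numeric(expr))
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    ipp_stop("expression matrix must carry gene rownames and sample colnames",
             "malformed_table")
  }
  zero_time <- !is.na(clin$time) & clin$time == 0
  if (any(zero_time)) {
    ipp_warn(sprintf("dropping %d sample(s) with follow-up time 0", sum(zero_time)),
             "zero_time")
    clin <- clin[!zero_time, , drop = FALSE]
  }
  valid <- is.finite(clin$time) & clin$time > 0 &
    !is.na(clin$event) & clin$event %in% c(0, 1)
  clin <- clin[valid, , drop = FALSE]
  shared <- sort(intersect(colnames(expr), clin$sample_id))
  if (length(shared) == 0L) {
    ipp_stop("no samples shared between expression and usable clinical records",
             "empty_cohort")
  }
  clin <- clin[match(shared, clin$sample_id), , drop = FALSE]
  rownames(clin) <- NULL
  structure(
    list(expr = expr[, shared, drop = FALSE],
         time = as.numeric(clin$time),
         event = as.integer(clin$event),
         endpoint = endpoint,
         name = name,
         clinical = clin),
    class = "ipp_cohort"
  )
}

#' @export
print.ipp_cohort <- function(x, ...) {
  cat(sprintf("IPP cohort '%s' (%s): %d genes x %d patients, %d events\n",
              x$name, x$endpoint, nrow(x$expr), ncol(x$expr), sum(x$event)))
  invisible(x)
}

#' Number of patients in a cohort
#' @param cohort An `"ipp_cohort"`.
#' @return Integer patient count.
#' @export
cohort_size <- function(cohort) ncol(cohort$expr)

# Internal: subset a cohort to a set of sample ids (order preserved as given).
subset_cohort <- function(cohort, samples, name = cohort$name) {
  idx <- match(samples, colnames(cohort$expr))
  stopifnot(!anyNA(idx))
  clin <- cohort$clinical[idx, , drop = FALSE]
  rownames(clin) <- NULL
  structure(
    list(expr = cohort$expr[, idx, drop = FALSE],
         time = cohort$time[idx],
         event = cohort$event[idx],
         endpoint = cohort$endpoint,
         name = name,
         clinical = clin),
    class = "ipp_cohort"
  )
}

#' Stratify a cohort into breast cancer receptor subtypes
#'
#' Splits a cohort into luminal (ER+ and PR+), HER2-enriched (ER-, PR-,
#' HER2+) and triple-negative (ER-, PR-, HER2-) sub-cohorts from
#' immunohistochemistry receptor status. HER2 status is not consulted for the
#' luminal class. A sample whose required statuses include an unknown is
#' assigned to no subtype, so the three outputs are pairwise disjoint.
#'
#' @param cohort An `"ipp_cohort"`.
#' @param statuses Optional data.frame with columns `er`, `pr`, `her2`
#'   (values `"pos"`, `"neg"` or `NA`), one row per cohort sample in cohort
#'   order. Defaults to the receptor columns of the cohort's clinical table.
#' @return Named list of `"ipp_cohort"` objects: `luminal`, `her2`, `tnbc`
#'   (possibly of size zero samples are simply absent genes-wise; empty
#'   subtypes are returned with zero patients).
#' @export
stratify_by_subtype <- function(cohort, statuses = NULL) {
  if (is.null(statuses)) {
    cols <- intersect(c("er", "pr", "her2"), colnames(cohort$clinical))
    if (length(cols) < 3L) {
      ipp_stop("cohort clinical table lacks er/pr/her2 receptor status columns",
               "missing_receptor_status")
    }
    statuses <- cohort$clinical[, c("er", "pr", "her2")]
  }
  stopifnot(nrow(statuses) == cohort_size(cohort))
  er <- as.character(statuses$er); pr <- as.character(statuses$pr)
  her2 <- as.character(statuses$her2)
  known <- function(x, v) !is.na(x) & x == v
  luminal <- known(er, "pos") & known(pr, "pos")
  her2e <- known(er, "neg") & known(pr, "neg") & known(her2, "pos")
  tnbc <- known(er, "neg") & known(pr, "neg") & known(her2, "neg")
  ids <- colnames(cohort$expr)
  list(
    luminal = subset_cohort(cohort, ids[luminal], paste0(cohort$name, ":luminal")),
    her2 = subset_cohort(cohort, ids[her2e], paste0(cohort$name, ":her2")),
    tnbc = subset_cohort(cohort, ids[tnbc], paste0(cohort$name, ":tnbc"))
  )
}

#' Drop cohorts below a minimum patient count
#'
#' Small subtype cohorts carry too little survival information for stable
#' partition scores; the default floor of 20 patients mirrors common
#' practice for subtype analyses.
#'
#' @param cohorts Named list of `"ipp_cohort"` objects.
#' @param min_n Minimum patient count to retain (default 20).
#' @return The retained sublist.
#' @export
filter_min_cohort_size <- function(cohorts, min_n = 20L) {
  stopifnot(min_n >= 1L)
  keep <- vapply(cohorts, cohort_size, integer(1L)) >= min_n
  cohorts[keep]
}

#' Remove genes with near-constant expression
#'
#' A gene whose most frequent expression value (values compared after
#' rounding to 6 significant digits) covers strictly more than
#' `modal_fraction` of the patients carries almost no ordering information
#' and would generate massively tied partitions; such genes are removed
#' before scoring.
#'
#' @param cohort An `"ipp_cohort"`.
#' @param modal_fraction Maximum tolerated modal-value fraction (default
#'   0.5). Genes are dropped when the modal share strictly exceeds it.
#' @return The cohort restricted to retained genes (gene order preserved).
#' @export
filter_invariant_genes <- function(cohort, modal_fraction = 0.5) {
  stopifnot(modal_fraction > 0, modal_fraction <= 1)
  n <- cohort_size(cohort)
  modal_count <- apply(cohort$expr, 1L, function(x) max(table(signif(x, 6L))))
  keep <- modal_count <= modal_fraction * n
  if (!any(keep)) {
    ipp_stop("all genes removed by the invariant-expression filter", "empty_gene_set")
  }
  cohort$expr <- cohort$expr[keep, , drop = FALSE]
  cohort
}

#' Collapse five-level CNA calls to three groups
#'
#' Maps copy-number calls onto three groups so each group keeps a workable
#' patient count: homozygous and hemizygous deletion become `deletion`,
#' neutral/no change becomes `normal`, and gain and high-level amplification
#' become `amplification`.
#'
#' @param calls Character vector of calls drawn from `"homozygous deletion"`,
#'   `"hemizygous deletion"`, `"neutral"` (or `"neutral/no change"`),
#'   `"gain"`, `"high-level amplification"`. `NA` propagates.
#' @return Character vector over `deletion`, `normal`, `amplification`.
#' @export
collapse_cna_states <- function(calls) {
  map <- c("homozygous deletion" = "deletion",
           "hemizygous deletion" = "deletion",
           "neutral" = "normal",
           "neutral/no change" = "normal",
           "gain" = "amplification",
           "high-level amplification" = "amplification")
  calls <- as.character(calls)
  known <- is.na(calls) | calls %in% names(map)
  if (!all(known)) {
    ipp_stop(sprintf("unknown CNA call(s): %s",
                     paste(unique(calls[!known]), collapse = ", ")), "invalid_call")
  }
  out <- unname(map[calls])
  out[is.na(calls)] <- NA_character_
  out
}

#' Partition cohort samples into mutation and non-mutation groups
#'
#' A sample carrying any consequence-type mutation record for the gene goes
#' to the `mutation` group; every other cohort sample goes to `none`. The
#' two groups always partition the cohort.
#'
#' @param mutations data.frame of mutation records with columns `sample_id`
#'   and `gene` (additional columns such as consequence type are ignored —
#'   any record counts).
#' @param gene Gene identifier to query.
#' @param samples Character vector of cohort sample ids.
#' @return List with character vectors `mutation` and `none`.
#' @export
split_by_mutation <- function(mutations, gene, samples) {
  hit <- unique(mutations$sample_id[mutations$gene == gene])
  mutated <- samples[samples %in% hit]
  list(mutation = mutated, none = setdiff(samples, mutated))
}
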