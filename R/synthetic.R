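# Synthetic cohorts: exchangeable null cohorts for the random IPP score
# distribution, and proportional-hazards cohorts with planted effects for
# power/recovery studies.

#' Simulation configuration for planted-effect cohorts
#'
#' @param n_patients Number of patients (>= 2).
#' @param n_genes Number of genes.
#' @param event_rate Target event fraction in (0, 1]: when `censor_horizon`
#'   is not given it is solved (for beta = 0) so that the expected observed
#'   event fraction matches this rate.
#' @param baseline_scale Mean of the exponential event-time distribution for
#'   a patient with zero planted-gene expression (default 5, study units).
#' @param censor_horizon Upper bound of the uniform censoring-time
#'   distribution; default derived from `event_rate`.
#' @param planted Named list or vector mapping gene ids (or a numeric index)
#'   to log-hazard-ratios beta: positive beta means high expression shortens
#'   survival (adverse gene, negative IPP score).
#' @param seed Integer seed; cohorts are fully determined by the config.
#' @return List of class `"ipp_sim_config"`.
#' @export
simulation_config <- function(n_patients = 100L, n_genes = 50L,
                              event_rate = 0.5, baseline_scale = 5,
                              censor_horizon = NULL, planted = list(),
                              seed = 1L) {
  stopifnot(n_patients >= 2L, n_genes >= 1L,
            event_rate > 0, event_rate <= 1)
  if (is.null(censor_horizon)) {
    # P(event observed | beta = 0) for Exp(mean b) vs Uniform(0, h) censoring
    # is 1 - (b/h)(1 - exp(-h/b)), monotone in h; invert for the target rate.
    b <- baseline_scale
    target <- min(event_rate, 0.99)
    censor_horizon <- stats::uniroot(
      function(h) 1 - (b / h) * (1 - exp(-h / b)) - target,
      lower = 1e-6, upper = 1e6, tol = 1e-9)$root
  }
  stopifnot(baseline_scale > 0, censor_horizon > 0)
  planted <- unlist(planted)
  beta <- numeric(n_genes)
  gene_ids <- sprintf("g%d", seq_len(n_genes))
  if (length(planted)) {
    if (!is.null(names(planted)) && all(nzchar(names(planted)))) {
      idx <- match(names(planted), gene_ids)
    } else {
      idx <- as.integer(names(planted))
      if (anyNA(idx)) idx <- seq_along(planted)
    }
    if (anyNA(idx) || any(idx < 1L) || any(idx > n_genes)) {
      ipp_stop("planted gene indices/ids outside 1..n_genes", "invalid_config")
    }
    beta[idx] <- as.numeric(planted)
  }
  structure(
    list(n_patients = as.integer(n_patients), n_genes = as.integer(n_genes),
         event_rate = event_rate, baseline_scale = baseline_scale,
         censor_horizon = censor_horizon, gene_ids = gene_ids, beta = beta,
         seed = as.integer(seed)),
    class = "ipp_sim_config"
  )
}

# Internal: wrap simulated pieces as an ipp_cohort.
make_sim_cohort <- function(expr, time, event, name, endpoint = "sim") {
  ids <- colnames(expr)
  structure(
    list(expr = expr, time = time, event = as.integer(event),
         endpoint = endpoint, name = name,
         clinical = data.frame(sample_id = ids, time = time,
                               event = as.integer(event), row.names = NULL)),
    class = "ipp_cohort"
  )
}

#' Generate a null (no-association) virtual cohort
#'
#' Virtual patients with random survival and one synthetic gene whose
#' expression carries no prognostic information: each patient's event
#' indicator is Bernoulli(0.5), the observed time is Uniform(0, 10), and the
#' gene's expression is an independent random permutation of ranks. Because
#' the IPP score depends on expression only through patient order, any
#' exchangeable choice of survival law gives the same null; this one is the
#' package's fixed convention.
#'
#' @param n Number of patients (>= 2).
#' @param seed Integer seed, or `NULL` to draw from the current RNG state
#'   (for callers managing their own stream).
#' @return An `"ipp_cohort"` with one gene `"null_gene"`.
#' @export
generate_null_cohort <- function(n, seed = 1L) {
  stopifnot(n >= 2L)
  if (!is.null(seed)) set.seed(as.integer(seed))
  time <- runif(n, 0, 10)
  event <- rbinom(n, 1L, 0.5)
  expr <- matrix(as.numeric(sample.int(n)), nrow = 1L,
                 dimnames = list("null_gene", sprintf("p%03d", seq_len(n))))
  make_sim_cohort(expr, time, event, name = "null", endpoint = "sim")
}

#' Generate a proportional-hazards cohort with planted prognostic genes
#'
#' Expression is i.i.d. standard normal per gene and patient. Event times
#' are exponential with patient-specific mean
#' `baseline_scale * exp(-sum(beta_g * x_gi))` over the planted genes, so a
#' positive beta makes high expression hazardous (adverse; negative IPP
#' score) and a negative beta protective (favorable). Censoring times are
#' Uniform(0, censor_horizon); the observed time is the minimum and the
#' event indicator marks whether the event came first. The cohort is fully
#' determined by the config's seed.
#'
#' @param config An [simulation_config()] object.
#' @return An `"ipp_cohort"` with genes `g1..gK`.
#' @examples
#' co <- generate_planted_cohort(simulation_config(
#'   n_patients = 60, n_genes = 20, planted = list(g5 = 2, g7 = -1.5), seed = 42))
#' @export
generate_planted_cohort <- function(config) {
  stopifnot(inherits(config, "ipp_sim_config"))
  set.seed(config$seed)
  n <- config$n_patients
  k <- config$n_genes
  expr <- matrix(rnorm(k * n), nrow = k,
                 dimnames = list(config$gene_ids, sprintf("p%03d", seq_len(n))))
  lp <- as.vector(crossprod(expr, config$beta)) # sum_g beta_g x_gi per patient
  event_time <- rexp(n, rate = 1) * config$baseline_scale * exp(-lp)
  censor_time <- runif(n, 0, config$censor_horizon)
  time <- pmin(event_time, censor_time)
  event <- as.integer(event_time <= censor_time)
  # guard against degenerate zero times from underflow
  time[time <= 0] <- .Machine$double.eps
  make_sim_cohort(expr, time, event, name = "planted", endpoint = "sim")
}

#' Write a simulated cohort to the package's TSV dialects
#'
#' Emits the expression table (`gene_id` + one column per sample) and the
#' clinical table (`sample_id`, `time`, `event`) accepted by
#' [read_expression()] and [read_clinical()].
#'
#' @param cohort An `"ipp_cohort"`.
#' @param expr_path,clinical_path Output paths.
#' @export
write_cohort_tsv <- function(cohort, expr_path, clinical_path) {
  expr_df <- data.frame(gene_id = rownames(cohort$expr), cohort$expr,
                        check.names = FALSE, row.names = NULL)
  write.table(expr_df, expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cohort$clinical[, c("sample_id", "time", "event")], clinical_path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(expr_path, clinical_path))
}
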