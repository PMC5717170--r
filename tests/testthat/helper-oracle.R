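# Independent oracles and fixture builders, deliberately written as plain
# element-wise loops so they share no code path with the package.

# Brute-force risk-table log-rank: walk the pooled distinct event times,
# recount every risk set from scratch, accumulate O, E, V by the textbook
# formulas. Returns the signed z (negative = high group at higher risk).
oracle_logrank_z <- function(high, low) {
  time <- c(high$time, low$time)
  event <- c(high$event, low$event)
  grp <- c(rep("H", nrow(high)), rep("L", nrow(low)))
  O <- 0; E <- 0; V <- 0
  for (t in sort(unique(time[event == 1]))) {
    n_t <- 0; n_H <- 0; d_t <- 0; d_H <- 0
    for (k in seq_along(time)) {
      if (time[k] >= t) {
        n_t <- n_t + 1
        if (grp[k] == "H") n_H <- n_H + 1
      }
      if (time[k] == t && event[k] == 1) {
        d_t <- d_t + 1
        if (grp[k] == "H") d_H <- d_H + 1
      }
    }
    O <- O + d_H
    E <- E + d_t * n_H / n_t
    if (n_t > 1) {
      p <- n_H / n_t
      V <- V + d_t * p * (1 - p) * (n_t - d_t) / (n_t - 1)
    }
  }
  if (V <= 0) return(0)
  -(O - E) / sqrt(V)
}

# Naive IPP: sort patients by (expression, sample id), enumerate every
# (i, j) partition with an explicit double loop and call the brute-force
# log-rank on each.
oracle_ipp_entries <- function(cohort, gene) {
  n <- ncol(cohort$expr)
  ord <- order(cohort$expr[gene, ], colnames(cohort$expr))
  time <- cohort$time[ord]
  event <- cohort$event[ord]
  out <- NULL
  for (i in 1:(n - 1)) {
    for (j in 1:(n - i)) {
      hi <- (n - i + 1):n
      lo <- 1:j
      z <- oracle_logrank_z(data.frame(time = time[hi], event = event[hi]),
                            data.frame(time = time[lo], event = event[lo]))
      out <- rbind(out, data.frame(i = i, j = j, z = z))
    }
  }
  out
}

oracle_ipp_score <- function(cohort, gene) {
  ent <- oracle_ipp_entries(cohort, gene)
  n <- ncol(cohort$expr)
  sum(ent$z) / (n * (n - 1) / 2)
}

# Random survival group with tied times (rounded) to exercise tie handling.
random_group <- function(n, p_event = 0.6) {
  data.frame(time = round(runif(n, 0.5, 10), 1), event = rbinom(n, 1, p_event))
}

# Random small cohort; times rounded to one decimal so ties occur, and a
# fraction of expression values rounded to integers so expression ties
# occur too.
random_cohort <- function(n, n_genes = 1, tie_expr = 0.3, name = "rand") {
  time <- round(runif(n, 0.5, 10), 1)
  event <- rbinom(n, 1, 0.6)
  expr <- matrix(rnorm(n_genes * n), n_genes, n)
  if (tie_expr > 0) {
    tie <- runif(length(expr)) < tie_expr
    expr[tie] <- round(expr[tie])
  }
  dimnames(expr) <- list(sprintf("g%d", seq_len(n_genes)),
                         sprintf("s%03d", seq_len(n)))
  make_cohort(expr, time, event, name)
}

# Assemble an ipp_cohort directly from its pieces (test-side constructor).
make_cohort <- function(expr, time, event, name = "test", endpoint = "sim") {
  build_cohort(expr,
               data.frame(sample_id = colnames(expr), time = time, event = event),
               endpoint = endpoint, name = name)
}
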