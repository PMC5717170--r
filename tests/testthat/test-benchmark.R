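test_that("median-threshold split halves an even cohort with distinct values", {
  set.seed(21)
  n <- 10
  x <- rnorm(n)
  expr <- matrix(x, 1, n, dimnames = list("g1", sprintf("s%02d", 1:n)))
  co <- make_cohort(expr, time = round(runif(n, 1, 9), 1), event = rbinom(n, 1, 0.7))
  thr <- median(co$expr["g1", ])
  expect_equal(sum(co$expr["g1", ] > thr), n / 2)
  z <- threshold_logrank_score(co, "g1", "median")
  hi <- co$expr["g1", ] > thr
  direct <- oracle_logrank_z(
    data.frame(time = co$time[hi], event = co$event[hi]),
    data.frame(time = co$time[!hi], event = co$event[!hi]))
  expect_equal(z, direct, tolerance = 1e-12)
})

test_that("mean-threshold split matches the risk-table oracle and shifts with outliers", {
  set.seed(31)
  n <- 6
  x <- c(-0.2, -0.1, 0.0, 0.1, 0.2, 8) # one extreme outlier
  expr <- matrix(x, 1, n, dimnames = list("g1", sprintf("s%02d", 1:n)))
  co <- make_cohort(expr, time = c(2, 5, 3.5, 7, 1.5, 9),
                    event = c(1, 1, 0, 1, 1, 0))
  hi_avg <- co$expr["g1", ] > mean(co$expr["g1", ])
  hi_med <- co$expr["g1", ] > median(co$expr["g1", ])
  # the outlier drags the mean above all regular values but leaves the median split balanced
  expect_equal(sum(hi_avg), 1)
  expect_equal(sum(hi_med), 3)
  z <- threshold_logrank_score(co, "g1", "average")
  direct <- oracle_logrank_z(
    data.frame(time = co$time[hi_avg], event = co$event[hi_avg]),
    data.frame(time = co$time[!hi_avg], event = co$event[!hi_avg]))
  expect_equal(z, direct, tolerance = 1e-12)
})

test_that("a constant gene makes the threshold split degenerate", {
  n <- 6
  expr <- matrix(1, 1, n, dimnames = list("g1", sprintf("s%02d", 1:n)))
  co <- make_cohort(expr, time = 1:6, event = rep(1, 6))
  expect_warning(z <- threshold_logrank_score(co, "g1", "median"),
                 class = "ippscore_degenerate_split")
  expect_identical(z, 0)
})

test_that("shared-gene counting applies the at-least-m rule and is monotone", {
  sets <- list(c("a", "b"), c("a", "c"), c("a", "b"), c("a", "d"), c("a", "b"))
  # a in 5/5, b in 3/5
  expect_identical(count_shared_genes(sets, 5)$genes, "a")
  expect_identical(count_shared_genes(sets, 3)$genes, c("a", "b"))
  expect_setequal(count_shared_genes(sets, 1)$genes, c("a", "b", "c", "d"))
  counts <- vapply(1:5, function(m) count_shared_genes(sets, m)$count, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("outcome consistency tallies signs per gene across datasets", {
  d <- 21
  set.seed(8)
  # g1 adverse in 18 datasets, g2 split 11/10, g3 always favorable
  tabs <- lapply(1:d, function(k) {
    c(g1 = if (k <= 18) -1 else 1,
      g2 = if (k <= 11) -0.5 else 0.5,
      g3 = abs(rnorm(1)))
  })
  cons <- outcome_consistency(tabs, min_datasets = 17)
  pg <- cons$per_gene
  expect_equal(pg$n_adverse[pg$gene_id == "g1"], 18)
  expect_equal(pg$n_favorable[pg$gene_id == "g1"], 3)
  expect_equal(cons$n_adverse_consistent, 1) # only g1
  expect_equal(cons$n_favorable_consistent, 1) # only g3
  # per-gene tallies sum to D (no zero scores here)
  expect_true(all(pg$n_adverse + pg$n_favorable == d))
  # aggregate counts monotone non-increasing in the threshold
  totals <- vapply(15:21, function(m) {
    x <- outcome_consistency(tabs, m)
    x$n_adverse_consistent + x$n_favorable_consistent
  }, numeric(1))
  expect_true(all(diff(totals) <= 0))
  # D = threshold: only unanimous genes counted
  unan <- outcome_consistency(tabs, min_datasets = d)
  expect_equal(unan$n_adverse_consistent, 0)
  expect_equal(unan$n_favorable_consistent, 1)
})

test_that("exact-zero scores count as neither relation", {
  tabs <- list(c(g1 = 0, g2 = 1), c(g1 = -1, g2 = 1))
  expect_warning(cons <- outcome_consistency(tabs, min_datasets = 2),
                 class = "ippscore_zero_scores_in_consistency")
  pg <- cons$per_gene
  expect_equal(pg$n_adverse[pg$gene_id == "g1"] + pg$n_favorable[pg$gene_id == "g1"], 1)
  expect_error(outcome_consistency(list(c(g1 = 1), c(g2 = 1))),
               class = "ippscore_gene_universe_mismatch")
})

test_that("binomial z-test compares shared-gene proportions one-tailed", {
  eq <- binomial_shared_test(50, 50, 1000)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 0.5)
  # the headline comparison scale: 178 vs 125 shared among 11,123 genes
  cmp <- binomial_shared_test(178, 125, 11123)
  p_hat <- (178 + 125) / (2 * 11123)
  expect_equal(cmp$z, (178 / 11123 - 125 / 11123) /
                 sqrt(2 * p_hat * (1 - p_hat) / 11123), tolerance = 1e-12)
  expect_gt(cmp$z, 0)
  expect_lt(cmp$p, 0.05)
  deg <- binomial_shared_test(0, 0, 100)
  expect_equal(deg$p, 1)
})

test_that("subsampling at full size reproduces the full-cohort scores", {
  set.seed(14)
  co <- random_cohort(12, n_genes = 4, tie_expr = 0)
  rs <- resample_scores(co, "subsample", size = 12, n_draws = 3,
                        scorer = "ipp", seed = 5)
  expect_equal(rs$per_gene$mean_resampled_score, rs$per_gene$full_score,
               tolerance = 1e-12)
  kept <- !is.na(rs$per_gene$normalized_mean)
  expect_equal(rs$per_gene$normalized_mean[kept], rep(1, sum(kept)),
               tolerance = 1e-12)
  expect_equal(rs$pearson_r, 1, tolerance = 1e-12)
})

test_that("resampling summaries are reproducible given the seed", {
  set.seed(15)
  co <- random_cohort(15, n_genes = 3)
  a <- resample_scores(co, "bootstrap", size = 10, n_draws = 2, scorer = "median", seed = 99)
  b <- resample_scores(co, "bootstrap", size = 10, n_draws = 2, scorer = "median", seed = 99)
  expect_identical(a$per_gene, b$per_gene)
  expect_error(resample_scores(co, "subsample", size = 16, n_draws = 1, seed = 1),
               class = "ippscore_size_out_of_range")
  expect_error(resample_scores(co, "bootstrap", size = 1, n_draws = 1, seed = 1),
               class = "ippscore_size_out_of_range")
})

test_that("half-cohort subsampling shrinks planted scores toward zero but preserves ranking", {
  co <- generate_planted_cohort(simulation_config(
    n_patients = 40, n_genes = 8, planted = list(g2 = 2, g6 = -2), seed = 23))
  rs <- resample_scores(co, "subsample", size = 20, n_draws = 200,
                        scorer = "ipp", seed = 31)
  expect_gt(rs$pearson_r, 0)
  strong <- abs(rs$per_gene$full_score) > 1
  expect_true(any(strong))
  expect_true(all(abs(rs$per_gene$mean_resampled_score[strong]) <
                    abs(rs$per_gene$full_score[strong])))
})

test_that("null score distribution is centred and tightens with cohort size", {
  nd <- null_ipp_distribution(c(20, 60, 120), n_reps = 500, seed = 17)
  expect_equal(nd$n, c(20, 60, 120))
  for (k in 1:3) {
    expect_lt(abs(nd$mean[k]), 3 * nd$sd[k] / sqrt(500))
  }
  expect_true(all(diff(nd$sd) < 0))
  # fixed seed -> identical summaries
  expect_identical(nd, null_ipp_distribution(c(20, 60, 120), n_reps = 500, seed = 17))
})

test_that("IPP ranks an asymmetric-split prognostic gene at least as well as the median baseline", {
  # planted gene separates roughly the top 20% of expressers; the median
  # split dilutes that contrast, the partition average does not
  set.seed(41)
  wins <- 0L
  n_sims <- 40L
  for (s in seq_len(n_sims)) {
    n <- 50
    expr <- matrix(rnorm(8 * n), 8, n,
                   dimnames = list(sprintf("g%d", 1:8), sprintf("p%03d", 1:n)))
    top <- expr["g4", ] >= quantile(expr["g4", ], 0.8)
    event_time <- rexp(n, rate = ifelse(top, 1, 0.15))
    censor <- runif(n, 0, 12)
    co <- make_cohort(expr, pmax(pmin(event_time, censor), 1e-9),
                      as.integer(event_time <= censor))
    ipp_rank <- rank(-abs(coef(ipp(co))))[["g4"]]
    med_rank <- rank(-abs(threshold_scores(co, "median")))[["g4"]]
    if (ipp_rank <= med_rank) wins <- wins + 1L
  }
  expect_gte(wins / n_sims, 0.8)
})
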