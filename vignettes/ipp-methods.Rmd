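---
title: "Iterative patient partitioning: model, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Iterative patient partitioning: model, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ippscore)
```

## The estimator

IPP quantifies the association between one gene's expression and survival
without committing to an expression cutpoint. Patients are sorted by the
gene's expression; for every high-group size $i$ and low-group size $j$
with $i + j \le N$ the top-$i$ and bottom-$j$ patients are compared by the
standard (unweighted) log-rank test, the $N - i - j$ middle patients being
excluded from that comparison. Each comparison is recorded as a signed
z-score $Z_{ij}$, negative when the high-expression group is at higher
risk, and the gene's score is the plain average over all $N(N-1)/2$
partitions:

$$S_k = \frac{1}{N(N-1)/2} \sum_{i=1}^{N-1}\sum_{j=1}^{N-i} Z_{ij}.$$

The sign carries the biology: $S_k < 0$ marks an adverse gene (high
expression, poor prognosis), $S_k > 0$ a favorable one. Averaging over all
partitions is what buys sensitivity to asymmetric effects — a gene whose
risk contrast separates, say, the top fifth of expressers contributes large
$|Z_{ij}|$ at small $i$, which a median split dilutes and the average does
not.

Assumptions are those of the log-rank test, applied per partition:
non-informative censoring and, for power, a hazard contrast that is
reasonably stable over follow-up. $S_k$ is *not* a calibrated effect size —
its scale grows with the cohort's information content — so scores are
comparable within a cohort and across cohorts only after the null scale is
taken into account (see the null distribution below).

## The log-rank element

Each element uses the textbook risk-table accounting over pooled distinct
event times $t$: $d_t$ events among $n_t$ at risk, $n_{Ht}$ of them in the
high group, giving $O_H$, $E_H = \sum_t d_t n_{Ht}/n_t$ and the
hypergeometric variance with tie correction $(n_t - d_t)/(n_t - 1)$
(dropped when $n_t = 1$). Patients censored at an event time remain in that
time's risk set. Degenerate elements — no events, or risk sets that never
mix the groups, so $V = 0$ — are defined as $Z_{ij} = 0$ rather than
dropped, and the denominator of $S_k$ stays at $N(N-1)/2$ regardless, so
the score is always well defined.

Two numerical choices make the package's symmetry guarantees exact rather
than approximate. The numerator $O_H - E_H$ is accumulated as
$\sum_t (d_{Ht} n_{Lt} - d_{Lt} n_{Ht})/n_t$ and the variance through the
commutative product $n_{Ht} n_{Lt}$, so swapping the two group labels
negates $z$ to the last bit. And the score sums its $N(N-1)/2$ elements
over canonical $\{(i,j),(j,i)\}$ pairs, so negating a gene's expression
(with all-distinct values, which reverses the patient order) negates $S_k$
bitwise. With tied expression values the order is completed stably by
sample id; partitions that split a tied block are still evaluated, keeping
the count at $N(N-1)/2$, and negation antisymmetry then holds only up to
the tie-block orientation.

Enumeration is compiled: one time-ordered pass per element over
precomputed orderings, $O(N)$ per element and $O(N^3)$ per gene with a
small constant (about 10 ms per gene at $N = 250$, well under a second for
a 200-gene cohort at $N = 120$). The test suite verifies the compiled path
against a naive pure-R per-partition enumeration to $10^{-12}$ and the
element against `survival::survdiff` to $10^{-8}$ on random tied
instances.

## Pre-filters and cohort handling

*Invariant genes.* A gene whose most frequent value covers more than half
the cohort yields mostly-tied partitions dominated by sort-order
convention. `filter_invariant_genes()` removes genes whose modal
expression value — compared after rounding to 6 significant digits, so the
criterion is scale-robust — occurs in strictly more than `modal_fraction`
(default 0.5) of samples. The filter is idempotent.

*Cohort assembly.* Expression and clinical tables are inner-joined on
sample id; samples without a positive finite time and 0/1 event are
dropped, zero follow-up times with an explicit warning. Outputs are sorted
by sample id so runs are bit-reproducible regardless of input row order.

*Subtypes.* Receptor stratification uses luminal = ER+/PR+ (HER2 not
consulted), HER2-enriched = ER−/PR−/HER2+, triple-negative = ER−/PR−/HER2−.
A sample with an unknown required status joins no subtype: the cost of
discarding a few samples is preferred to contaminating subtype-specific
scores. Subtype cohorts below 20 patients are dropped by
`filter_min_cohort_size()` — below that, partition z-scores are too
unstable to rank genes.

*CNA and mutations.* Five-level copy-number calls collapse to
deletion/normal/amplification to keep group sizes workable; any
consequence-type mutation record places a patient in the mutation group.
For three-group CNA survival contrasts the package exposes pairwise
one-sided log-rank tests with a caller-chosen direction rather than
guessing a canonical pairing.

## Cross-dataset integration and comparisons

Per-dataset scores are merged by Liptak's weighted (Stouffer-type)
combination $\sum_d w_d S_d / \sqrt{\sum_d w_d^2}$ with $w_d = \sqrt{n_d}$,
the standard sample-size weighting; scores enter raw, without
re-standardization to a unit null variance, since no variance model is
imposed — callers wanting calibrated inputs can divide by the null SD at
each dataset's $N$ first (from `null_ipp_distribution()`). Top-fraction
selection keeps $\lceil f G \rceil$ genes by $|S|$ (so 5% of 11,123 genes
is 557), with boundary ties broken by gene id for determinism.

The baseline comparisons mirror the conventional practice IPP is measured
against: per-gene log-rank z at the mean or median threshold (high group
strictly above the threshold), shared-gene counts across datasets (a gene
counts as shared when it reaches the top fraction in at least 5 datasets),
outcome-relation consistency (per-gene tallies of adverse/favorable signs
across datasets; exact zeros — measure-zero with real data but possible —
count on neither side, with a warning), and a pooled two-proportion
one-tailed z-test for comparing two shared-gene counts over the same gene
total. The pooled-variance variant was chosen as the default two-proportion
form; the unpooled alternative differs negligibly at these counts.

Robustness is summarised by `resample_scores()`: bootstrap or subsample
draws, each rescored in full, reporting per-gene mean resampled scores, the
mean/full ratio, and the Pearson correlation between full and
mean-resampled score vectors. Ratios are aggregated only over genes with
$|S| \ge 0.05$; near-zero denominators make the per-gene ratio
uninformative, and the threshold is a configurable argument.

## The synthetic cohorts

`generate_null_cohort()` draws virtual patients with event
$\sim$ Bernoulli(0.5), time $\sim$ Uniform(0, 10) and an independent random
expression ordering. Because IPP is rank-based, *any* exchangeable survival
law gives the same null score distribution; the uniform/Bernoulli choice is
a fixed convention, not an inference. Note the same is not automatically
true of the mean-threshold baseline, whose split depends on expression
values, not just ranks. `null_ipp_distribution()` summarises the null score
over cohort sizes; its SD decreases with $N$, and its quantiles give the
empirical reference against which an observed score's magnitude can be
judged.

`generate_planted_cohort()` plants effects under proportional hazards:
expression i.i.d. N(0, 1), event time exponential with mean
$b\,e^{-\sum_g \beta_g x_{gi}}$ (so $\beta > 0$ shortens survival for high
expressers — an adverse gene), censoring Uniform(0, $h$). Defaults:
baseline scale $b = 5$ study units and $h$ solved so that the expected
event fraction at $\beta = 0$ equals `event_rate` (default 0.5, a typical
mid-study event fraction for cohorts of 20–300 patients). Determinism
comes from one `set.seed()` per generator call with a fixed generation
order (the whole expression matrix is drawn in a single call), which makes
a cohort a pure function of its config.

What the generator does *not* emulate: microarray noise structure, batch
effects, correlated co-expression modules, subtype mixture, or informative
censoring. Passing recovery tests therefore demonstrates that the
estimator ranks genuinely prognostic genes under clean proportional
hazards — not that it is immune to the artefacts of real expression data.

## Problem sizes and test design

The suite exercises: oracle equivalence on 200 random cohorts at
$N \le 30$; `survdiff` agreement on 100 random tied instances; exact
antisymmetry plus the $N(N-1)/2$ entry count for all $N$ in 2..60; null
calibration at $N \in \{20, 100, 250\}$ with 500 replicates per size
(mean within $\pm 3\,\mathrm{sd}/\sqrt{500}$, SD monotone decreasing);
null normality of the log-rank z at 5,000 simulated pairs of $n = 50$
groups; sign recovery of $|\beta| = 2$ planted genes at $n = 100$ over 100
seeds ($\ge$ 95% required); and top-5% recovery of 5 planted $|\beta| = 1.5$
genes among 200 nulls at $n = 120$ over 50 seeds ($\ge$ 80% required).
These sizes were chosen to make each property statistically decisive while
keeping the whole suite around two minutes.

## Known limitations

- $O(N^3)$ per gene means genome-wide scoring of cohorts beyond a few
  hundred patients is compute-heavy; the design targets the 20–300 patient
  cohorts typical of survival-annotated expression datasets.
- Scores are not calibrated across cohort sizes; cross-dataset use should
  go through the Liptak combination or a null-SD standardization.
- Heavy expression ties make individual $Z_{ij}$ depend on the stable
  sort's tie orientation; the invariant-gene filter bounds, but does not
  eliminate, this.
- Per-element p-values are not retained, only z-scores; the IPP matrix is
  a signature, not a multiple-testing-corrected test battery.
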