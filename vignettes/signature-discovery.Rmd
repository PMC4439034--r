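---
title: "Methods: stable signature discovery with sigselect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stable signature discovery with sigselect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model behind `sigselect`, the
choices made where the procedures admit more than one reasonable
formalization, and what the synthetic-data tests do and do not demonstrate
about real data.

## The problem and the data model

The input is a genes × samples matrix of log2 expression ratios (M
values) with a class label per sample — ordered disease stages or tumor
subtypes.  A *signature* is a small gene subset whose expression patterns
discriminate the classes.  Because subset search on noisy, high-dimensional
data is unstable, every search strategy here is wrapped in external k-fold
resampling: the selector runs k times on k−1/k of the samples, the
held-out fold measures accuracy, and the k selected subsets measure
*stability* (NAHD) and feed a frequency ensemble.

## Information-theoretic machinery

Expression vectors are discretized before any mutual-information
computation.  The default is equal-frequency binning into 3 bins: bin
boundaries at empirical terciles, ties broken by stable (original) order so
bin sizes differ by at most one; a constant vector collapses to a single
bin.  Three bins is a robust choice for the small sample counts typical of
these designs — finer grids inflate the plug-in MI bias, which grows like
(bins−1)²/(2n ln 2).  A `sign_threshold` mode cuts at M = ±1 instead,
the natural two-fold points on the log2 scale.  All MI values use base-2
logarithms and are reported in bits.

The RFE exclusion coefficient interprets "sample-by-sample MI" as the MI
between the discretized expression profiles of two samples, taken over the
currently retained genes.  Excluding gene *g* only decrements one cell of
each sample pair's joint bin-count table, which is what makes the
per-iteration coefficient computation tractable (a 3×3 table update per
pair rather than a full recount).

Genes with the *smallest* coefficient are removed: a small coefficient
means the classes remain well separated without the gene.  The convention
is fixed here because the source procedure does not state the sign.

## Search strategies: open points and how they are fixed

- **RFE schedule (x, y).**  The first pass runs up to `x` iterations
  removing `m` genes each; refinement then restarts from the best subset
  found and removes one gene at a time for `y` iterations.  This realizes
  "refinement around the selection solution" without re-specifying the
  coarse pass.
- **Coefficient II.**  Redundancy is *added* to the base coefficient with a
  sign per mode: `−w·red` for `mi` and `go_min` (redundant genes become
  cheaper to remove), `+w·red` for `go_max` (shared-pathway genes are
  protected).  `w` defaults to 1 and is freely configurable.
- **GS1 / GS2.**  The cited definitions are not recoverable, so GS1 is
  fixed as Golub-style signal-to-noise maximized over class pairs and GS2
  as BSS/WSS.  Both denominators carry ε = 1e−12 so zero-variance genes
  score finitely rather than erroring.
- **MRMR empty-set redundancy.**  ε_red = 1e−6 bits, so the first pick is
  exactly the maximum-relevance gene.
- **GA.**  Elitism keeps the single best chromosome; roulette selection
  uses fitness 1 − error shifted to be positive (distance-matrix scores
  can exceed 1); uniform crossover resolves duplicate genes from the
  parents' pooled genes, then from the unused universe; mutation draws
  replacements from unused genes, so chromosomes never contain duplicates.
  Termination follows the stated rule — past `max_generations` (default
  100), stop when the least-squares slope of per-generation minimum error
  is below `slope_threshold` (default 0.05) — computed over the last 20
  generations (the window is not specified by the source procedure).
  Because that conjunction may never trigger on rough fitness landscapes, a
  `hard_cap` (default 4 × `max_generations`) bounds the run; it is a
  safety net, not a tuning knob.
- **Tie-breaking** everywhere (coefficient ranks, frequency ranks, argmax
  picks) falls back to lexicographic gene id, so every trace is exactly
  reproducible.

## Evaluators

Three regimes score a candidate subset, always as an error (lower is
better):

1. **Wrapper**: stratified k-fold CV (5-fold by default; 10-fold for the
   univariate-hybrid methods) of a classifier trained on the subset's rows.
   The roster is a linear SVM, Gaussian naïve Bayes, kernel-density naïve
   Bayes (the "two configurations" of naïve Bayes, which the source never
   pins down), and a tree-augmented naïve Bayes network.  The TAN
   discretizes features into equal-width thirds of the training range —
   equal-frequency cuts would split well-separated expression modes through
   their centers — and learns its tree by Chow–Liu on class-conditional MI.
2. **Distance matrix**: mean between-class minus mean within-class sample
   distance on the subset's rows, reported as `error = −score`.  Pearson
   distance (1 − r) is the default.  A one-gene profile has no shape, so
   its Pearson score is defined as 0 (no separation evidence); this keeps
   prefix scores comparable across sizes instead of silently switching
   metrics.  Note the distance score saturates once a few strongly
   class-patterned genes are in the subset, so forward searches evaluated
   this way tend to stop early; wrapper CV is the better choice when the
   goal is to recover a full planted signature.
3. **Supervised clustering with external validity**: every algorithm in the
   pool partitions the samples into as many clusters as classes; the best
   partition by Dunn index (maximize) or figure of merit (minimize) is
   scored against the known classes by optimal one-to-one matching
   (an O(n³) Hungarian assignment, verified in tests against exhaustive
   permutation).  The FOM is adapted to sample clustering by leaving *genes*
   out: cluster on all genes but one, accumulate the RMS deviation of the
   held-out gene around its cluster means.  "agnes", "diana", "clara" map
   to the `cluster` package's implementations; "sota" is a compact
   self-organizing (grid) competitive learner — faithful historical
   re-implementations are out of scope.

Degenerate cases are fixed by convention: all-singleton partitions give
Dunn = +Inf (zero diameter), a class of size one contributes no
within-class pairs, and a fold whose training part lacks a class aborts
with advice to lower k.

## Stability, ensembles, smoothing

NAHD is the mean symmetric-difference size over subset pairs, divided by
the size of the gene universe, giving [0, 1]; the undivided mean is
reported alongside because other normalizations exist in the literature
(printed ANHD values above 1 cannot be reproduced from any normalization by
universe size, so both conventions are exposed).

Frequency aggregation ranks the union of the k subsets by descending
selection frequency, breaking ties by mean within-subset insertion rank and
then gene id, evaluates growing prefixes on the full data, stops at the
first strict error increase and returns the best prefix seen.  "First
strict increase" (rather than "first non-decrease") makes the rule robust
to plateaus.  Cross-method aggregation reapplies the same rule with each
method's ensemble as one vote, so frequencies are multiples of 1/(number of
methods).

Trend smoothing treats each gene's values along the stage-ordered samples
as a time series and replaces it with a centred weighted moving average
(window 4 samples = one disease stage by default, uniform weights — the
weighting is configurable since only "weighted" is specified).  Edges use
the truncated window with renormalized weights; no data is invented beyond
the series ends.  Everything the average removes is treated as random plus
cyclic variation.  A full seasonal decomposition is unidentifiable with
4-sample stages, which is why the trend component is defined directly as
the moving average.

## Enrichment, cluster support, survival

Pathway over-representation uses the upper-tail hypergeometric test
P(X ≥ overlap) with *no* multiple-testing correction by default, matching
the p < 0.05 convention of the source analyses (a Benjamini–Hochberg
option exists but is off).  The gene universe is the post-filter gene list,
not the whole platform: subsets are drawn from the filtered genes, so that
is the correct reference population.

Cluster support resamples *genes* (rows) with replacement at ratios
r = 0.5 … 1.4, reclusters the samples, and counts how often each original
node's exact sample set reappears (BP_r).  The AU support comes from the
weighted least-squares probit fit z_r = v√r + c/√r with binomial
delta-method weights n·φ(z)²/(BP(1−BP)), AU = 1 − Φ(v − c); BP_r is
clipped to [1/(2n_boot), 1 − 1/(2n_boot)] before the probit, and nodes with
all-or-nothing profiles fall back to AU = BP with a degenerate-fit flag.
1000 replicates per scale is the default ("thousands" is the only guidance
given); fewer than 100 is refused because the fit is unstable.

Survival validation uses the product-limit estimator and the standard
log-rank chi-square (via the `survival` package; events precede censorings
at tied times).  The DEG filter is a pooled-variance two-sample t test
(Welch optional); a gene with zero pooled variance and zero mean difference
gets p = 1.  Signature validation clusters the independent cohort on the
signature genes (complete linkage, Pearson distance) cut at 3 clusters by
default, mirroring the three-subtype structure the validation design
anticipates.

## The synthetic-data generator

`generate_progression()` plants `n_informative` genes whose class means
step monotonically by `effect_size` (log2 units) across the ordered stages,
with a random up/down direction per gene and the staircase centred so null
genes and planted genes share a grand mean near 0.  Redundant blocks are
`ρ·source + √(1−ρ²)·sd(source)·ε` copies of randomly chosen planted genes,
giving approximately the target Pearson correlation.  All noise is Gaussian
on the M-value scale (M values are approximately symmetric around 0 under
the null).  `generate_survival()` assigns two latent subtypes, shifts the
designated signature genes in *opposite directions* in the two subtypes
(half the effect each way — a uniform one-sided shift would be invisible
to correlation distance and does not match the up-in-A/down-in-B patterns
these signatures describe), and draws exponential event times whose rates
differ by `hazard_ratio`, with independent uniform censoring calibrated in
closed form to the requested censored fraction.  `generate_genesets()`
concentrates `enriched_fraction` of the planted genes into designated true
pathways and fills the rest by uniform sampling, capping memberships at 3
sets per gene.

Defaults describe a small staged cohort: 4 ordered stages, 5–10 samples
per stage, noise SD 0.5 on the log2 scale, effect 1–1.5 × noise SD, 500
genes with 10 planted.  What the generator does *not* emulate: probe-level
artifacts, batch effects, heavy-tailed noise, correlated noise across
samples, censoring that depends on risk.  Passing tests therefore show the
algorithms are implemented correctly and behave as designed under their own
assumptions — not that they will rank genes correctly under real
microarray artifacts.

## Test and verification sizes

The packaged checks use deliberately small problems so a complete run
finishes in a couple of minutes on one CPU: oracle equivalences on 3–6
gene toys; calibration at 5000 null genes, 1000 log-rank replicates, and
40 pathways × 25 runs; recovery of 10 planted genes among 500 at effect
1.5 × noise SD with 10 samples per stage across the full method grid;
smoothing stabilization over 20 seeded replicates of a 150-gene,
4-samples-per-stage design; and AU support with 1000 bootstrap replicates
per scale on a 200-gene two-cluster design.  The recovery checks evaluate
the searches under wrapper CV (the GA under its default distance
criterion), for the reason given above.  `scripts/acceptance.R` recomputes
the same quantities from scratch under a caller-supplied seed.

## Known limitations

- The RFE coefficient costs O(samples² · bins²) per iteration plus the
  evaluator; it is fine for dozens of samples but not thousands.
- Plug-in MI is biased upward at small n; scores are comparable within a
  run but not absolute information estimates.
- The GA explores a combinatorially large space with a small population;
  on weak signals it benefits from the continuous distance-matrix fitness
  rather than discrete CV error.
- GO redundancy is set-overlap (Jaccard) only; no information-content
  semantic similarity.
- Log-rank p-values rely on the chi-square approximation, which is mildly
  anti-conservative around 40 samples (type-I ≈ 6% at nominal 5% — a
  property of the test, observable with any implementation).
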