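# sigselect — stable gene-expression signature discovery

`sigselect` is an R package for discovering *signatures*: minimal gene (or
pathway) subsets whose expression discriminates phenotype classes in
microarray-style log2-ratio data (M values), such as ordered disease stages
(normal → steatosis → NASH → HCC) or tumor subtypes with different
prognoses.  It is aimed at computational biologists who want
feature-selection results that are not only accurate but *stable* under
resampling, and validated downstream by pathway enrichment, cluster
support and survival analysis.

## What it implements

**Search strategies** (all operating on an `ExpressionDataset`, a genes ×
samples matrix of M values with class labels):

- **RFE** — backward recursive feature elimination.  With gene *g* excluded
  from the current subset, every sample becomes the discretized profile of
  the remaining genes and *g*'s coefficient is
  `I(g) = Σ MI(sample pairs between classes) − Σ MI(sample pairs within classes)`;
  the *m* smallest-coefficient genes are dropped per iteration.
  Redundancy-aware variants add a weighted redundancy term to the
  coefficient: mean pairwise mutual information (`rfe_mr`) or mean pairwise
  GO-term Jaccard similarity, penalized (`rfe_minr_mingo`) or rewarded
  (`rfe_maxr_maxgo`).
- **MRMR** — forward minimum-redundancy maximum-relevance: at each step the
  gene maximizing `NMI(g, class) / meanMI(g, selected)` is appended, where
  `NMI = I(x;y)/√(H(x)H(y))`.
- **GS1 / GS2 / F-TEST** — univariate forward selection by Golub
  signal-to-noise `max |μi−μj|/(si+sj)`, BSS/WSS, or the one-way ANOVA F.
- **GA** — a genetic algorithm over fixed-length gene subsets with elitism,
  roulette-wheel selection, uniform crossover and unused-gene mutation.

**Evaluation criteria**: wrapper k-fold CV of a linear SVM, Gaussian or
kernel-density naïve Bayes, or a tree-augmented Bayes network;
distance-matrix class separation (mean between-class minus within-class
sample distance); and supervised clustering with external validity, where
the clustering algorithm (k-means, PAM, CLARA, AGNES, DIANA, SOTA-style,
four hierarchical linkages) is chosen by the Dunn index or the figure of
merit and compared to the known classes by optimal (Hungarian) matching.

**Stability and ensembles**: external k-fold resampling around any method,
Normalized Average Hamming Distance (NAHD) between the k selected subsets,
per-gene selection frequencies, and frequency-based aggregation ("rank
summation") that adds genes in frequency order until performance degrades —
within one method and across methods.

**Downstream validation**: upper-tail hypergeometric pathway enrichment
with per-run pathway frequencies; hierarchical clustering of samples with
multiscale-bootstrap support (BP, and AU via the weighted probit fit
`z_r = v√r + c/√r`, `AU = 1 − Φ(v − c)`); and Kaplan–Meier / log-rank
validation of cluster-derived survival subtypes, including a two-sample-t
DEG filter and cross-species ortholog integration.

**Synthetic data**: a seeded generator (`simulation_spec()`,
`generate_progression()`, `generate_survival()`, `generate_genesets()`)
producing staged progression signatures, correlated redundant gene blocks,
pathway collections enriched for the planted genes and latent survival
subtypes — so the entire pipeline is testable offline.

## Worked example

```r
library(sigselect)

spec <- simulation_spec(n_genes = 300, n_samples_per_class = 10,
                        n_informative = 10, effect_size = 0.75,
                        noise_sd = 0.5, seed = 42)
g <- generate_progression(spec)
g$dataset
#> ExpressionDataset: 300 genes x 40 samples; classes: HCC, NASH, normal, steatosis

trace <- run_selection("mrmr", g$dataset, evaluator = "wrapper_svm",
                       max_iter = 20, seed = 1)
trace
#> SelectionTrace: 20 steps; best |subset| = 16, best error = 0.025
mean(g$truth %in% trace$best_subset)
#> [1] 0.6

rep <- run_stability(g$dataset, method = "ftest", evaluator = "wrapper_svm_10",
                     k = 5, seed = 1, max_iter = 15)
rep
#> StabilityReport [ftest]: 5 folds; NAHD = 0.015 (raw 4.400);
#>   ensemble: 4 genes, error 0; mean fold error 0.025
head(rep$frequencies, 5)
#> g00001 g00004 g00006 g00010 g00005
#>    1.0    1.0    1.0    1.0    0.8
```

Reading: MRMR's best subset (16 genes, 2.5% wrapper-CV error) recovers 6 of
the 10 planted genes on this draw; the externally cross-validated F-test
selector is highly stable (NAHD 0.015 — the five fold subsets differ by
4.4 genes on average over a 300-gene universe) and its frequency ensemble
reaches zero CV error with 4 genes, all selected in every fold
(frequency 1.0).

Two orchestrated pipelines tie the stages together:
`run_progression_pipeline()` (fold-change filter → optional
moving-average smoothing → external CV selection per method → cross-method
ensemble → pathway signature → AU-supported clustering) and
`run_survival_pipeline()` (DEG filter between subtypes → five selection
methods → ensemble signature → log-rank validation on an independent
cohort).  Both accept an in-memory config list or a YAML file and write a
deterministic `report.json`.  A minimal CLI wrapper lives in
`inst/scripts/sigselect.R` (`simulate` and `pipeline` subcommands).

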