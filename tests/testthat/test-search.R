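# Explicit sample-pair enumeration oracle for the RFE exclusion coefficient.
oracle_rfe_coefficient <- function(dataset, labels, excluded, subset, spec) {
  rest <- setdiff(subset, excluded)
  d <- apply(dataset$values[rest, , drop = FALSE], 1, discretize, spec = spec)
  d <- matrix(d, ncol = length(rest))   # samples x genes
  rownames(d) <- colnames(dataset$values)
  total <- 0
  ids <- rownames(d)
  for (i in seq_along(ids)[-length(ids)]) for (j in seq(i + 1, length(ids))) {
    mi <- oracle_mi(d[i, ], d[j, ])
    total <- total + if (labels[ids[i]] == labels[ids[j]]) -mi else mi
  }
  total
}

test_that("RFE coefficient matches explicit pair enumeration", {
  set.seed(5)
  vals <- matrix(rnorm(3 * 4), 3, dimnames = list(c("a", "b", "c"), paste0("s", 1:4)))
  labs <- setNames(c("x", "x", "y", "y"), paste0("s", 1:4))
  ds <- expression_dataset(vals, labs)
  spec <- discretization_spec(3)
  for (g in c("a", "b", "c"))
    expect_equal(rfe_coefficient(ds, excluded_gene = g,
                                 current_subset = c("a", "b", "c"), disc = spec),
                 oracle_rfe_coefficient(ds, labs, g, c("a", "b", "c"), spec))
})

test_that("RFE coefficient degenerates to the single between-class pair MI", {
  vals <- matrix(c(1, 5, 2, 6), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  labs <- setNames(c("x", "y"), c("s1", "s2"))
  ds <- expression_dataset(vals, labs)
  spec <- discretization_spec(2)
  got <- rfe_coefficient(ds, excluded_gene = "b", current_subset = c("a", "b"),
                         disc = spec)
  d <- apply(vals["a", , drop = FALSE], 1, discretize, spec = spec)
  expect_equal(got, oracle_mi(d[1, ], d[2, ]))
  # invariant to class relabeling
  ds2 <- expression_dataset(vals, setNames(c("q", "p"), c("s1", "s2")))
  expect_equal(rfe_coefficient(ds2, excluded_gene = "b",
                               current_subset = c("a", "b"), disc = spec), got)
})

test_that("RFE schedule: m = n_genes - 1 evaluates exactly two subsets", {
  g <- planted_progression(n_genes = 12, seed = 4)
  ev <- make_evaluator("distance_pearson")
  tr <- rfe_search(g$dataset, spec = rfe_spec(m = 11), evaluator = ev)
  expect_length(tr$steps, 2)
  expect_length(tr$steps[[1]]$subset, 12)
  expect_length(tr$steps[[2]]$subset, 1)
})

test_that("RFE subset sizes strictly decrease by m until the floor", {
  g <- planted_progression(n_genes = 20, seed = 4)
  ev <- make_evaluator("distance_pearson")
  tr <- rfe_search(g$dataset, spec = rfe_spec(m = 6), evaluator = ev)
  sizes <- lengths(lapply(tr$steps, `[[`, "subset"))
  expect_equal(sizes, c(20, 14, 8, 2))
  # refinement iterations shrink one at a time from the best subset
  tr2 <- rfe_search(g$dataset, spec = rfe_spec(m = 6, y = 3), evaluator = ev)
  sizes2 <- lengths(lapply(tr2$steps, `[[`, "subset"))
  b <- length(tr$best_subset)
  expect_equal(sizes2, c(sizes, setdiff(pmax(b - 1:3, 1), c(sizes, 0))))
})

test_that("redundancy-aware RFE penalizes correlated duplicates", {
  set.seed(6)
  n <- 24
  base <- rnorm(n)
  vals <- rbind(sig = rep(c(-1, 1), each = n / 2) + rnorm(n, 0, 0.3),
                dup1 = base, dup2 = base + rnorm(n, 0, 0.01),
                noise = rnorm(n))
  colnames(vals) <- paste0("s", 1:n)
  labs <- setNames(rep(c("A", "B"), each = n / 2), colnames(vals))
  ds <- expression_dataset(vals, labs)
  ev <- make_evaluator("distance_pearson")
  tr_plain <- rfe_search(ds, spec = rfe_spec(m = 1, x = 2), evaluator = ev)
  tr_mr <- rfe_search(ds, spec = rfe_spec(m = 1, x = 2, redundancy_mode = "mi",
                                          redundancy_weight = 50), evaluator = ev)
  removed_mr <- setdiff(tr_mr$steps[[1]]$subset, tr_mr$steps[[2]]$subset)
  expect_true(removed_mr %in% c("dup1", "dup2"))
  expect_length(tr_plain$steps, 3)
})

test_that("GO-driven RFE modes move coefficients in opposite directions", {
  g <- planted_progression(n_genes = 10, seed = 8)
  genes <- gene_ids(g$dataset)
  ann <- gene_annotation(setNames(
    c(lapply(genes[1:5], function(x) c("GO:1", "GO:2")),
      lapply(genes[6:10], function(x) paste0("GO:", x))), genes))
  ev <- make_evaluator("distance_pearson")
  tr_min <- rfe_search(g$dataset, spec = rfe_spec(m = 2, x = 1, redundancy_mode = "go_min",
                                                  redundancy_weight = 100),
                       evaluator = ev, annotation = ann)
  tr_max <- rfe_search(g$dataset, spec = rfe_spec(m = 2, x = 1, redundancy_mode = "go_max",
                                                  redundancy_weight = 100),
                       evaluator = ev, annotation = ann)
  removed_min <- setdiff(genes, tr_min$steps[[2]]$subset)
  removed_max <- setdiff(genes, tr_max$steps[[2]]$subset)
  # with a dominating weight, go_min removes the shared-term genes first,
  # go_max keeps them
  expect_true(all(removed_min %in% genes[1:5]))
  expect_true(all(removed_max %in% genes[6:10]))
  expect_error(rfe_search(g$dataset, spec = rfe_spec(redundancy_mode = "go_min"),
                          evaluator = ev), "GeneAnnotation")
})

test_that("MRMR first picks the max-NMI gene and shuns exact copies", {
  g <- planted_progression(n_genes = 15, effect = 2, noise_sd = 0.3, seed = 10)
  ds <- g$dataset
  spec <- discretization_spec(3)
  cls <- as.integer(factor(ds$labels[sample_ids(ds)])) - 1L
  nmis <- apply(ds$values, 1, function(v) normalized_mi(discretize(v, spec), cls))
  ev <- make_evaluator("distance_pearson")
  tr <- mrmr_search(ds, disc = spec, evaluator = ev, max_iter = 5)
  first <- tr$steps[[1]]$subset
  expect_equal(first, names(nmis)[order(-nmis, names(nmis))][1])

  # append an exact copy of the first pick: it must not be chosen second
  vals2 <- rbind(ds$values, copy_of_first = ds$values[first, ])
  ds2 <- expression_dataset(vals2, ds$labels)
  tr2 <- mrmr_search(ds2, disc = spec, evaluator = ev, max_iter = 3)
  # whichever twin is picked first, the other must not follow immediately:
  # its redundancy with the selected set is maximal
  expect_false(setequal(tr2$steps[[2]]$subset, c(first, "copy_of_first")))
})

test_that("MRMR coefficients match a hand-rolled oracle on 4 genes", {
  set.seed(14)
  vals <- matrix(rnorm(4 * 12), 4, dimnames = list(letters[1:4], paste0("s", 1:12)))
  labs <- setNames(rep(c("X", "Y"), 6), paste0("s", 1:12))
  ds <- expression_dataset(vals, labs)
  spec <- discretization_spec(3)
  ev <- function(dataset, labels, subset) 0   # constant evaluator
  tr <- mrmr_search(ds, disc = spec, evaluator = ev, max_iter = 4)
  picks <- vapply(tr$steps, function(s) utils::tail(s$subset, 1), character(1))

  # oracle: greedy max of NMI / mean-MI-with-selected
  d <- apply(vals, 1, discretize, spec = spec)
  cls <- as.integer(factor(labs)) - 1L
  nmi <- apply(d, 2, function(col) {
    ha <- sigselect:::entropy_bits(col); hb <- sigselect:::entropy_bits(cls)
    if (ha == 0 || hb == 0) 0 else oracle_mi(col, cls) / sqrt(ha * hb)
  })
  sel <- character(0)
  for (k in 1:4) {
    cand <- setdiff(letters[1:4], sel)
    red <- vapply(cand, function(g) {
      if (!length(sel)) 1e-6
      else max(mean(vapply(sel, function(s) oracle_mi(d[, g], d[, s]), numeric(1))), 1e-6)
    }, numeric(1))
    coef <- nmi[cand] / red
    sel <- c(sel, cand[order(-coef, cand)][1])
  }
  expect_equal(picks, sel)
})

test_that("MRMR subsets grow by one with no repeats", {
  g <- planted_progression(n_genes = 25, seed = 2)
  ev <- make_evaluator("distance_pearson")
  tr <- mrmr_search(g$dataset, evaluator = ev, max_iter = 10)
  sizes <- lengths(lapply(tr$steps, `[[`, "subset"))
  expect_equal(sizes, 1:10)
  expect_false(anyDuplicated(tr$steps[[10]]$subset) > 0)
})

test_that("univariate forward search honors ranking and max_iter", {
  g <- planted_progression(n_genes = 40, n_informative = 1, effect = 3,
                           noise_sd = 0.3, seed = 20)
  ev <- make_evaluator("distance_pearson")
  tr1 <- univariate_forward_search(g$dataset, score_id = "f", evaluator = ev,
                                   max_iter = 1)
  expect_length(tr1$steps, 1)
  expect_equal(tr1$steps[[1]]$subset, g$truth)   # planted gene ranked first
  tr <- univariate_forward_search(g$dataset, score_id = "f", evaluator = ev,
                                  max_iter = 5)
  for (s in tr$steps)
    expect_equal(s$error, ev(g$dataset, g$dataset$labels, s$subset))
})

test_that("GA: degenerate spec leaves the chromosome unchanged", {
  g <- planted_progression(n_genes = 10, seed = 5)
  ev <- make_evaluator("distance_pearson")
  spec <- ga_spec(population_size = 1, chromosome_length = 4,
                  crossover_prob = 0, mutation_prob = 0, elitism_count = 1,
                  max_generations = 5, hard_cap = 6, seed = 3)
  tr <- ga_search(g$dataset, spec = spec, evaluator = ev)
  expect_length(tr$steps, 1)   # the single chromosome never changes
})

test_that("GA best-ever error is non-increasing and reproducible", {
  g <- planted_progression(n_genes = 30, seed = 6)
  ev <- make_evaluator("distance_pearson")
  spec <- ga_spec(population_size = 8, chromosome_length = 6,
                  mutation_prob = 0.1, max_generations = 15, hard_cap = 25, seed = 9)
  tr <- ga_search(g$dataset, spec = spec, evaluator = ev)
  errs <- vapply(tr$steps, `[[`, numeric(1), "error")
  expect_true(all(diff(cummin(errs)) <= 0))
  expect_equal(tr$best_error, min(errs))
  tr2 <- ga_search(g$dataset, spec = spec, evaluator = ev)
  expect_identical(lapply(tr$steps, `[[`, "subset"),
                   lapply(tr2$steps, `[[`, "subset"))
})

test_that("a perfectly separating gene drives every method to zero error", {
  ds <- perfect_separator()
  ev <- make_evaluator("wrapper_svm", seed = 2)
  for (m in c("ftest", "gs1", "gs2", "mrmr")) {
    tr <- run_selection(m, ds, evaluator = "wrapper_svm", max_iter = 4, seed = 2)
    expect_equal(tr$best_error, 0)
    expect_true("sep" %in% tr$best_subset)
  }
  tr <- rfe_search(ds, spec = rfe_spec(m = 2), evaluator = ev)
  expect_equal(tr$best_error, 0)
  tr <- ga_search(ds, spec = ga_spec(population_size = 10, chromosome_length = 3,
                                     mutation_prob = 0.2, max_generations = 10,
                                     hard_cap = 20, seed = 4), evaluator = ev)
  expect_equal(tr$best_error, 0)
})

test_that("trace invariants hold across method runs", {
  g <- planted_progression(n_genes = 20, seed = 12)
  for (m in c("ftest", "mrmr")) {
    tr <- run_selection(m, g$dataset, evaluator = "distance_pearson", max_iter = 8)
    errs <- vapply(tr$steps, `[[`, numeric(1), "error")
    expect_equal(tr$best_error, min(errs))
    keys <- vapply(tr$steps, function(s) paste(sort(s$subset), collapse = "|"),
                   character(1))
    expect_false(anyDuplicated(keys) > 0)
    expect_true(paste(sort(tr$best_subset), collapse = "|") %in% keys)
  }
})

test_that("unknown method ids fail fast with the valid list", {
  g <- planted_progression(n_genes = 10, seed = 1)
  expect_error(run_selection("bogus", g$dataset), "valid")
})
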