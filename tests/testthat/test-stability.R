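test_that("NAHD matches hand values and a brute-force pair loop", {
  expect_equal(nahd(list(c("a", "b"), c("a", "b"), c("a", "b")), 10)$nahd, 0)
  hand <- nahd(list("g1", "g2"), 2)
  expect_equal(hand$ahd_raw, 2)
  expect_equal(hand$nahd, 1.0)
  set.seed(3)
  universe <- paste0("g", 1:30)
  subsets <- replicate(5, sample(universe, sample(3:12, 1)), simplify = FALSE)
  got <- nahd(subsets, 30)
  brute <- c()
  for (i in 1:4) for (j in (i + 1):5)
    brute <- c(brute, length(setdiff(subsets[[i]], subsets[[j]])) +
                        length(setdiff(subsets[[j]], subsets[[i]])))
  expect_equal(got$ahd_raw, mean(brute))
  expect_equal(got$nahd, mean(brute) / 30)
  # invariant to subset ordering
  expect_equal(nahd(rev(subsets), 30), got)
  expect_error(nahd(subsets, 0), "positive")
})

test_that("external folds are mutually exclusive, exhaustive and stratified", {
  g <- planted_progression(n_genes = 40, n_per_class = 5, seed = 31)
  cv <- external_cv_select(g$dataset, method = "ftest",
                           evaluator = "distance_pearson", k = 5, seed = 9,
                           max_iter = 6)
  expect_length(cv$fold_subsets, 5)
  expect_setequal(names(cv$folds), sample_ids(g$dataset))
  expect_equal(sort(unique(cv$folds)), 1:5)
  for (f in 1:5)  # each fold holds one sample of each of the 4 stages
    expect_equal(as.integer(table(g$dataset$labels[names(cv$folds)[cv$folds == f]])),
                 rep(1L, 4))
  # reproducible bit-for-bit
  cv2 <- external_cv_select(g$dataset, method = "ftest",
                            evaluator = "distance_pearson", k = 5, seed = 9,
                            max_iter = 6)
  expect_identical(cv, cv2)
  # a class with a single sample must abort: some training fold misses it
  vals <- g$dataset$values[, 1:6]
  labs <- setNames(c(rep("big", 5), "rare"), colnames(vals))
  tiny <- expression_dataset(vals, labs)
  expect_error(external_cv_select(tiny, method = "ftest",
                                  evaluator = "distance_euclidean", k = 2,
                                  max_iter = 2),
               "fewer folds")
})

test_that("identical folds from duplicated data give identical subsets and NAHD 0", {
  ds0 <- perfect_separator(n_per_class = 2, n_noise = 5)
  vals <- ds0$values
  big <- do.call(cbind, lapply(1:5, function(i) {
    v <- vals; colnames(v) <- paste0(colnames(vals), "_r", i); v
  }))
  labs <- setNames(rep(ds0$labels, 5), colnames(big))
  ds <- expression_dataset(big, labs)
  # one dominant gene: every fold ranks it first whatever copies it holds
  cv <- external_cv_select(ds, method = "ftest", evaluator = "distance_pearson",
                           k = 5, seed = 4, max_iter = 1)
  st <- nahd(cv$fold_subsets, nrow(big))
  expect_equal(st$nahd, 0)
  expect_true(all(vapply(cv$fold_subsets, identical, logical(1), "sep")))
})

test_that("frequency aggregation ranks, stops and reports per contract", {
  ds <- perfect_separator(n_per_class = 6)
  ev <- make_evaluator("wrapper_svm", seed = 2)
  subsets <- list(c("sep", "noise1"), c("sep", "noise2"), c("sep", "noise1"),
                  c("sep", "noise3"), c("sep", "noise1"))
  agg <- aggregate_by_frequency(subsets, ds, evaluator = ev)
  expect_equal(unname(agg$frequencies["sep"]), 1)
  expect_equal(unname(agg$frequencies["noise1"]), 3 / 5)
  # frequencies are multiples of 1/k
  expect_true(all(abs(agg$frequencies * 5 - round(agg$frequencies * 5)) < 1e-12))
  expect_equal(agg$ensemble_subset[1], "sep")
  expect_equal(agg$ensemble_error, min(agg$prefix_errors))
  expect_true(all(agg$ensemble_subset %in% unlist(subsets)))
})

test_that("single-subset aggregation preserves order and membership", {
  ds <- perfect_separator()
  ev <- make_evaluator("wrapper_svm", seed = 1)
  agg <- aggregate_by_frequency(list(c("sep", "noise2", "noise1")), ds,
                                evaluator = ev)
  expect_true(all(agg$ensemble_subset %in% c("sep", "noise2", "noise1")))
  # ties at frequency 1 fall back to insertion rank: original order kept
  expect_equal(agg$ensemble_subset,
               c("sep", "noise2", "noise1")[seq_along(agg$ensemble_subset)])
})

test_that("run_stability assembles a coherent report", {
  g <- planted_progression(n_genes = 40, n_per_class = 5, effect = 1.5, seed = 8)
  rep1 <- run_stability(g$dataset, method = "ftest",
                        evaluator = "wrapper_svm_10", k = 5, seed = 3,
                        max_iter = 8)
  expect_s3_class(rep1, "StabilityReport")
  expect_length(rep1$fold_subsets, 5)
  expect_true(all(rep1$per_fold_errors >= 0 & rep1$per_fold_errors <= 1))
  expect_true(all(rep1$ensemble_subset %in% unlist(rep1$fold_subsets)))
  expect_true(all(abs(rep1$frequencies * 5 - round(rep1$frequencies * 5)) < 1e-12))
  expect_equal(nahd(rep1$fold_subsets, nrow(g$dataset$values))$nahd, rep1$nahd)
  # deterministic replay
  rep2 <- run_stability(g$dataset, method = "ftest",
                        evaluator = "wrapper_svm_10", k = 5, seed = 3,
                        max_iter = 8)
  expect_identical(rep1$ensemble_subset, rep2$ensemble_subset)
  expect_identical(rep1$per_fold_errors, rep2$per_fold_errors)
})

test_that("cross-method aggregation of agreeing methods returns their subset", {
  ds <- perfect_separator(n_per_class = 6)
  mk <- function(sub) structure(list(method = "m", fold_subsets = list(sub),
                                     per_fold_errors = 0, nahd = 0, ahd_raw = 0,
                                     frequencies = setNames(rep(1, length(sub)), sub),
                                     ensemble_subset = sub, ensemble_error = 0),
                                class = "StabilityReport")
  reps <- list(mk(c("sep", "noise1")), mk(c("sep", "noise1")), mk(c("sep", "noise1")))
  out <- cross_method_aggregate(reps, ds, evaluator = "wrapper_svm", seed = 2)
  expect_true(all(out$frequencies[out$ensemble_subset] == 1))
  expect_true(all(out$ensemble_subset %in% c("sep", "noise1")))
  expect_equal(out$nahd, 0)
  expect_error(cross_method_aggregate(reps[1], ds), ">= 2")
})
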