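#' External k-fold resampling around a selection method
#'
#' Partitions the samples into k mutually exclusive stratified folds; for
#' each fold the search method runs on the remaining k-1 folds only (the
#' selection is external to the accuracy estimation) and its best subset is
#' recorded together with the held-out error: a classifier trained on the
#' training folds restricted to the selected genes, scored on the held-out
#' fold.
#'
#' @param dataset An `ExpressionDataset`.
#' @param labels Named class labels (default: the dataset's).
#' @param method Selection method id (see [selection_methods()]).
#' @param evaluator Optional evaluator id or function passed to the method.
#' @param k Number of folds (default 5).
#' @param seed Integer seed (fold assignment and stochastic components).
#' @param holdout_classifier Classifier id scoring held-out folds; defaults
#'   to the wrapper evaluator's classifier when `evaluator` is a wrapper id,
#'   else a linear SVM.
#' @param ... Passed to [run_selection()] (`max_iter`, `rfe`, `ga`,
#'   `annotation`, `disc`).
#' @return List with `fold_subsets` (k best subsets, in selection order),
#'   `per_fold_errors` (held-out error rates) and `folds` (assignment).
#' @export
external_cv_select <- function(dataset, labels = dataset$labels, method,
                               evaluator = NULL, k = 5L, seed = 1L,
                               holdout_classifier = NULL, ...) {
  stopifnot(k >= 2)
  labels <- labels[sample_ids(dataset)]
  folds <- stratified_folds(labels, k, derive_seed(seed, "folds"))
  if (is.null(holdout_classifier)) {
    holdout_classifier <- "svm"
    if (is.character(evaluator) && startsWith(evaluator, "wrapper_"))
      holdout_classifier <- sub("_10$", "", sub("^wrapper_", "", evaluator))
  }
  present <- sort(unique(folds))   # tiny cohorts may leave a fold empty
  fold_subsets <- vector("list", length(present))
  per_fold_errors <- numeric(length(present))
  for (i in seq_along(present)) {
    f <- present[i]
    train_ids <- names(folds)[folds != f]
    test_ids <- names(folds)[folds == f]
    if (length(unique(labels[train_ids])) < length(unique(labels)))
      stop("training fold ", f, " misses a class; use fewer folds")
    train <- subset_dataset(dataset, samples = train_ids)
    trace <- run_selection(method, train, labels[train_ids], evaluator = evaluator,
                           seed = derive_seed(seed, paste0("fold", f)), ...)
    fold_subsets[[i]] <- trace$best_subset
    model <- fit_classifier(t(train$values[trace$best_subset, , drop = FALSE]),
                            labels[train_ids], holdout_classifier)
    pred <- model(t(dataset$values[trace$best_subset, test_ids, drop = FALSE]))
    per_fold_errors[i] <- mean(pred != labels[test_ids])
  }
  list(fold_subsets = fold_subsets, per_fold_errors = per_fold_errors, folds = folds)
}

#' Normalized average Hamming distance between selected subsets
#'
#' The mean, over unordered subset pairs, of the size of their symmetric
#' difference (the minimum number of substitutions turning one subset into
#' the other), divided by the gene-universe size to land in \[0, 1\].  The
#' raw (undivided) mean is reported alongside.
#'
#' @param subsets List of >= 2 gene-id vectors.
#' @param universe_size Number of genes in the selection universe (> 0).
#' @return List with `nahd` (normalized) and `ahd_raw`.
#' @export
nahd <- function(subsets, universe_size) {
  if (length(subsets) < 2) stop("need >= 2 subsets")
  if (universe_size <= 0) stop("universe_size must be positive")
  if (universe_size < max(lengths(subsets))) stop("universe smaller than a subset")
  pairs <- utils::combn(length(subsets), 2)
  hd <- apply(pairs, 2, function(ij) {
    a <- unique(subsets[[ij[1]]]); b <- unique(subsets[[ij[2]]])
    length(setdiff(a, b)) + length(setdiff(b, a))
  })
  list(nahd = mean(hd) / universe_size, ahd_raw = mean(hd))
}

#' Selection frequency of each gene across subsets
#' @param subsets List of gene-id vectors.
#' @return Named numeric vector of frequencies in (0, 1\], multiples of
#'   1/length(subsets), descending.
#' @export
gene_frequencies <- function(subsets) {
  k <- length(subsets)
  tab <- table(unlist(lapply(subsets, unique)))
  sort(stats::setNames(as.numeric(tab) / k, names(tab)), decreasing = TRUE)
}

#' Frequency-based ensemble aggregation (rank summation)
#'
#' Ranks the union of genes by descending selection frequency (ties broken
#' by mean within-subset insertion rank, then gene id), adds genes one at a
#' time evaluating each prefix on the full data, stops at the first strict
#' error increase, and returns the best prefix seen.
#'
#' @param subsets List of gene-id vectors in selection order.
#' @param dataset An `ExpressionDataset`.
#' @param labels Named class labels (default: the dataset's).
#' @param evaluator An evaluator function (or id).
#' @param max_size Optional cap on the ensemble size.
#' @return List with `ensemble_subset`, `ensemble_error`, `frequencies`,
#'   `prefix_errors`.
#' @export
aggregate_by_frequency <- function(subsets, dataset, labels = dataset$labels,
                                   evaluator, max_size = Inf) {
  if (!length(subsets)) stop("no subsets to aggregate")
  if (is.character(evaluator)) evaluator <- make_evaluator(evaluator)
  labels <- labels[sample_ids(dataset)]
  freq <- gene_frequencies(subsets)
  genes <- names(freq)
  mean_rank <- vapply(genes, function(g) {
    r <- vapply(subsets, function(s) match(g, s), numeric(1))
    mean(r, na.rm = TRUE)
  }, numeric(1))
  ord <- order(-freq, mean_rank, genes)
  ranked <- genes[ord]

  errors <- numeric(0)
  for (i in seq_len(min(length(ranked), max_size))) {
    errors[i] <- evaluator(dataset, labels, ranked[seq_len(i)])
    if (i > 1 && errors[i] > errors[i - 1]) break
  }
  best <- which.min(errors)
  list(ensemble_subset = ranked[seq_len(best)],
       ensemble_error = errors[best],
       frequencies = freq,
       prefix_errors = errors)
}

#' Stability report for one method under external resampling
#'
#' Runs [external_cv_select()] and [aggregate_by_frequency()] and assembles
#' the per-fold subsets, NAHD stability, gene frequencies and the ensemble
#' subset with its error into a `StabilityReport`.
#'
#' @inheritParams external_cv_select
#' @param ensemble_evaluator Evaluator (id or function) scoring ensemble
#'   prefixes on the full data; defaults to `evaluator` or the method's
#'   default.
#' @param ... Passed to [run_selection()].
#' @return An object of class `StabilityReport`.
#' @export
run_stability <- function(dataset, labels = dataset$labels, method,
                          evaluator = NULL, k = 5L, seed = 1L,
                          ensemble_evaluator = NULL, ...) {
  cv <- external_cv_select(dataset, labels, method, evaluator, k, seed, ...)
  ee <- ensemble_evaluator %||% evaluator %||% "wrapper_svm"
  if (is.character(ee)) ee <- make_evaluator(ee, seed = derive_seed(seed, "ensemble"))
  agg <- aggregate_by_frequency(cv$fold_subsets, dataset, labels, ee)
  st <- nahd(cv$fold_subsets, nrow(dataset$values))
  structure(list(method = method,
                 fold_subsets = cv$fold_subsets,
                 per_fold_errors = cv$per_fold_errors,
                 nahd = st$nahd, ahd_raw = st$ahd_raw,
                 frequencies = agg$frequencies,
                 ensemble_subset = agg$ensemble_subset,
                 ensemble_error = agg$ensemble_error),
            class = "StabilityReport")
}

#' @export
print.StabilityReport <- function(x, ...) {
  cat(sprintf("StabilityReport [%s]: %d folds; NAHD = %.3f (raw %.3f);\n",
              x$method %||% "?", length(x$fold_subsets), x$nahd, x$ahd_raw))
  cat(sprintf("  ensemble: %d genes, error %.4g; mean fold error %.4g\n",
              length(x$ensemble_subset), x$ensemble_error, mean(x$per_fold_errors)))
  invisible(x)
}

#' Cross-method ensemble aggregation
#'
#' Treats each method's ensemble subset as one vote and reapplies the
#' frequency aggregation over methods, yielding a unique convergent
#' signature; frequencies are multiples of 1/(number of methods).
#'
#' @param reports List of >= 2 `StabilityReport`s.
#' @param dataset An `ExpressionDataset`.
#' @param labels Named class labels (default: the dataset's).
#' @param evaluator Evaluator (id or function) for the prefix evaluation.
#' @param seed Integer seed.
#' @return A `StabilityReport` whose "folds" are the per-method ensembles.
#' @export
cross_method_aggregate <- function(reports, dataset, labels = dataset$labels,
                                   evaluator = "wrapper_svm", seed = 1L) {
  if (length(reports) < 2) stop("need >= 2 method reports")
  subsets <- lapply(reports, `[[`, "ensemble_subset")
  if (is.character(evaluator)) evaluator <- make_evaluator(evaluator, seed = seed)
  agg <- aggregate_by_frequency(subsets, dataset, labels, evaluator)
  st <- nahd(subsets, nrow(dataset$values))
  structure(list(method = "cross_method",
                 fold_subsets = subsets,
                 per_fold_errors = vapply(reports, `[[`, numeric(1), "ensemble_error"),
                 nahd = st$nahd, ahd_raw = st$ahd_raw,
                 frequencies = agg$frequencies,
                 ensemble_subset = agg$ensemble_subset,
                 ensemble_error = agg$ensemble_error),
            class = "StabilityReport")
}
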