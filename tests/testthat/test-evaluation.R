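test_that("wrapper CV is zero on a perfect separator and deterministic", {
  ds <- perfect_separator()
  spec <- evaluator_spec("wrapper", "svm", seed = 5)
  expect_equal(wrapper_cv_error(ds, subset = "sep", spec = spec), 0)
  e1 <- wrapper_cv_error(ds, subset = gene_ids(ds), spec = spec)
  e2 <- wrapper_cv_error(ds, subset = gene_ids(ds), spec = spec)
  expect_identical(e1, e2)
  expect_error(wrapper_cv_error(ds, subset = character(0), spec = spec), "non-empty")
})

test_that("every classifier learns the planted two-class structure", {
  ds <- perfect_separator(n_per_class = 10)
  for (clf in c("svm", "nb_gauss", "nb_kde", "bayes_net")) {
    spec <- evaluator_spec("wrapper", clf, seed = 3)
    err <- wrapper_cv_error(ds, subset = c("sep", "noise1"), spec = spec)
    expect_lte(err, 0.1)
  }
  expect_error(evaluator_spec("wrapper", "boosted_stump"), "classifier_id")
})

test_that("wrapper CV on permuted labels hovers near chance", {
  set.seed(44)
  errs <- replicate(15, {
    vals <- matrix(rnorm(10 * 20), 10,
                   dimnames = list(paste0("g", 1:10), paste0("s", 1:20)))
    labs <- setNames(sample(rep(c("A", "B"), 10)), colnames(vals))
    ds <- expression_dataset(vals, labs)
    wrapper_cv_error(ds, subset = gene_ids(ds),
                     spec = evaluator_spec("wrapper", "svm", seed = 1))
  })
  expect_lt(abs(mean(errs) - 0.5), 0.1)
})

test_that("wrapper CV with k = n reduces to leave-one-out", {
  ds <- perfect_separator(n_per_class = 4, n_noise = 3)
  n <- ncol(ds$values)
  spec <- evaluator_spec("wrapper", "svm", k_folds = n, seed = 2)
  loo <- mean(vapply(seq_len(n), function(i) {
    x <- t(ds$values)
    model <- sigselect:::fit_classifier(x[-i, , drop = FALSE],
                                        ds$labels[-i], "svm")
    model(x[i, , drop = FALSE]) != ds$labels[i]
  }, logical(1)))
  expect_equal(wrapper_cv_error(ds, subset = gene_ids(ds), spec = spec), loo)
})

test_that("distance-matrix score recovers a hand-computed separation", {
  # two tight 1-D clusters at 0 and 10 with jitter 0.1
  set.seed(9)
  vals <- matrix(c(rnorm(5, 0, 0.1), rnorm(5, 10, 0.1)), 1,
                 dimnames = list("g", paste0("s", 1:10)))
  labs <- setNames(rep(c("lo", "hi"), each = 5), colnames(vals))
  ds <- expression_dataset(vals, labs)
  sc <- distance_matrix_score(ds, subset = "g", distance = "euclidean")
  expect_lt(abs(sc - 10), 0.3)
  # identical samples: zero separation
  vals0 <- matrix(1, 2, 6, dimnames = list(c("g1", "g2"), paste0("s", 1:6)))
  ds0 <- expression_dataset(vals0, setNames(rep(c("A", "B"), 3), paste0("s", 1:6)))
  expect_equal(distance_matrix_score(ds0, subset = c("g1", "g2"),
                                     distance = "euclidean"), 0)
  # invariant to sample order
  perm <- sample(colnames(vals))
  ds_p <- subset_dataset(ds, samples = perm)
  expect_equal(distance_matrix_score(ds_p, subset = "g", distance = "euclidean"), sc)
})

test_that("Dunn index matches direct arithmetic and conventions", {
  pts <- c(0, 1, 10, 11)
  d <- as.matrix(dist(pts))
  expect_equal(dunn_index(d, c(1, 1, 2, 2)), 9 / 1)
  expect_equal(dunn_index(d, 1:4), Inf)          # all singletons
  expect_equal(dunn_index(as.matrix(dist(pts * 2)), c(1, 1, 2, 2)), 9)  # scale-free
  expect_error(dunn_index(d, rep(1, 4)), "2 clusters")
})

test_that("figure of merit honors its closed forms", {
  set.seed(7)
  vals <- matrix(rnorm(4 * 8), 4, dimnames = list(paste0("g", 1:4), paste0("s", 1:8)))
  ds <- expression_dataset(vals)
  # singletons: deviations from singleton means vanish
  expect_equal(figure_of_merit(ds, function(d) seq_len(ncol(d$values))), 0)
  # one cluster: mean over genes of the population SD
  pop_sd <- mean(apply(vals, 1, function(v) sqrt(mean((v - mean(v))^2))))
  expect_equal(figure_of_merit(ds, function(d) rep(1, ncol(d$values))), pop_sd)
})

test_that("FOM prefers the true partition of a 2-block dataset", {
  set.seed(15)
  vals <- matrix(rnorm(20 * 10, 0, 0.3), 20,
                 dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  vals[, 6:10] <- vals[, 6:10] + 3
  ds <- expression_dataset(vals)
  true_part <- rep(1:2, each = 5)
  rand_part <- rep(1:2, 5)
  fom_true <- figure_of_merit(ds, function(d) true_part[match(colnames(d$values),
                                                              paste0("s", 1:10))])
  fom_rand <- figure_of_merit(ds, function(d) rand_part[match(colnames(d$values),
                                                              paste0("s", 1:10))])
  expect_lt(fom_true, fom_rand)
})

test_that("cluster-class matching equals exhaustive permutation search", {
  set.seed(23)
  perms <- function(v) if (length(v) == 1) list(v) else
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  for (rep in 1:10) {
    k <- sample(2:5, 1)
    n <- 30
    part <- sample(seq_len(k), n, replace = TRUE)
    labs <- sample(letters[seq_len(k)], n, replace = TRUE)
    got <- cluster_match_error(part, labs)
    best <- Inf
    for (p in perms(letters[seq_len(k)]))
      best <- min(best, mean(p[part] != labs))
    expect_equal(got, best)
  }
})

test_that("supervised clustering scores well-separated classes as zero", {
  set.seed(5)
  vals <- matrix(rnorm(30 * 12, 0, 0.3), 30,
                 dimnames = list(paste0("g", 1:30), paste0("s", 1:12)))
  # per-gene directions: a constant offset would be invisible to 1 - r
  dirs <- sample(c(-2, 2), 10, replace = TRUE)
  vals[1:10, 7:12] <- vals[1:10, 7:12] + dirs
  vals[1:10, 1:6] <- vals[1:10, 1:6] - dirs
  labs <- setNames(rep(c("A", "B"), each = 6), colnames(vals))
  ds <- expression_dataset(vals, labs)
  spec <- evaluator_spec("cluster_external", index = "dunn",
                         clustering_pool = c("kmeans", "pam", "hier_complete",
                                             "hier_average", "diana", "agnes",
                                             "clara", "sota", "hier_single",
                                             "hier_ward"),
                         seed = 8)
  err <- cluster_external_error(ds, subset = paste0("g", 1:10), spec = spec)
  expect_equal(err, 0)
  expect_gte(err, 0); expect_lte(err, 1)
})

test_that("cluster_external with FOM choice runs and stays within [0,1]", {
  set.seed(6)
  vals <- matrix(rnorm(8 * 10, 0, 0.4), 8,
                 dimnames = list(paste0("g", 1:8), paste0("s", 1:10)))
  vals[1:4, 6:10] <- vals[1:4, 6:10] + 3
  labs <- setNames(rep(c("A", "B"), each = 5), colnames(vals))
  ds <- expression_dataset(vals, labs)
  spec <- evaluator_spec("cluster_external", index = "fom",
                         clustering_pool = c("kmeans", "hier_complete"), seed = 4)
  err <- cluster_external_error(ds, subset = paste0("g", 1:4), spec = spec)
  expect_gte(err, 0); expect_lte(err, 1)
})

test_that("evaluator ids map to working evaluators", {
  ds <- perfect_separator()
  for (id in c("wrapper_svm", "wrapper_svm_10", "distance_pearson",
               "distance_euclidean", "cluster_dunn")) {
    ev <- make_evaluator(id, seed = 3)
    expect_true(is.finite(ev(ds, ds$labels, c("sep", "noise1"))))
  }
  expect_error(make_evaluator("nope"), "unknown evaluator")
})
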