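#' Evaluator specification
#'
#' The three evaluation regimes: `"wrapper"` (stratified k-fold CV of a
#' classifier trained on the candidate subset), `"distance_matrix"`
#' (inter-class minus intra-class mean sample distance) and
#' `"cluster_external"` (the best of a pool of unsupervised clustering
#' algorithms, chosen by Dunn index or figure of merit, compared against the
#' known classes).
#'
#' @param kind `"wrapper"`, `"distance_matrix"` or `"cluster_external"`.
#' @param classifier_id For wrappers: `"svm"`, `"nb_gauss"`, `"nb_kde"` or
#'   `"bayes_net"`.
#' @param k_folds CV folds (5 by default; 10 for the univariate-hybrid
#'   methods).
#' @param index For cluster_external: `"dunn"` (maximize) or `"fom"`
#'   (minimize).
#' @param clustering_pool Algorithm ids among `"kmeans"`, `"diana"`,
#'   `"sota"`, `"pam"`, `"clara"`, `"hier_average"`, `"hier_complete"`,
#'   `"hier_single"`, `"hier_ward"`, `"agnes"`.
#' @param distance `"pearson"` (1 - Pearson r) or `"euclidean"`.
#' @param seed Integer seed driving fold assignment and stochastic
#'   clustering.
#' @return An object of class `EvaluatorSpec`.
#' @export
evaluator_spec <- function(kind = c("wrapper", "distance_matrix", "cluster_external"),
                           classifier_id = "svm", k_folds = 5L,
                           index = c("dunn", "fom"),
                           clustering_pool = c("kmeans", "pam", "hier_average",
                                               "hier_complete", "hier_ward"),
                           distance = c("pearson", "euclidean"), seed = 1L) {
  kind <- match.arg(kind)
  index <- match.arg(index)
  distance <- match.arg(distance)
  valid_pool <- c("kmeans", "diana", "sota", "pam", "clara", "hier_average",
                  "hier_complete", "hier_single", "hier_ward", "agnes")
  if (!all(clustering_pool %in% valid_pool))
    stop("unknown clustering algorithm: ",
         paste(setdiff(clustering_pool, valid_pool), collapse = ", "))
  if (k_folds < 2) stop("k_folds must be >= 2")
  if (!classifier_id %in% c("svm", "nb_gauss", "nb_kde", "bayes_net"))
    stop("unknown classifier_id '", classifier_id, "'")
  structure(list(kind = kind, classifier_id = classifier_id,
                 k_folds = as.integer(k_folds), index = index,
                 clustering_pool = clustering_pool, distance = distance,
                 seed = as.integer(seed)),
            class = "EvaluatorSpec")
}

#' Build an evaluator function from an id
#'
#' Evaluators are closures `function(dataset, labels, subset) -> error`
#' (lower is better).  Recognized ids: `wrapper_svm`, `wrapper_svm_10`,
#' `wrapper_nb_gauss`, `wrapper_nb_kde`, `wrapper_bayes_net`,
#' `distance_pearson`, `distance_euclidean`, `cluster_dunn`, `cluster_fom`.
#'
#' @param id Evaluator id.
#' @param seed Integer seed.
#' @return An evaluator function.
#' @export
make_evaluator <- function(id, seed = 1L) {
  spec <- switch(id,
    wrapper_svm = evaluator_spec("wrapper", "svm", seed = seed),
    wrapper_svm_10 = evaluator_spec("wrapper", "svm", k_folds = 10L, seed = seed),
    wrapper_nb_gauss = evaluator_spec("wrapper", "nb_gauss", seed = seed),
    wrapper_nb_kde = evaluator_spec("wrapper", "nb_kde", seed = seed),
    wrapper_bayes_net = evaluator_spec("wrapper", "bayes_net", seed = seed),
    distance_pearson = evaluator_spec("distance_matrix", distance = "pearson", seed = seed),
    distance_euclidean = evaluator_spec("distance_matrix", distance = "euclidean", seed = seed),
    cluster_dunn = evaluator_spec("cluster_external", index = "dunn", seed = seed),
    cluster_fom = evaluator_spec("cluster_external", index = "fom", seed = seed),
    stop("unknown evaluator id '", id, "'"))
  evaluator_function(spec)
}

#' Turn an `EvaluatorSpec` into an evaluator function
#' @param spec An `EvaluatorSpec`.
#' @return A function `(dataset, labels, subset) -> error`.
#' @export
evaluator_function <- function(spec) {
  force(spec)
  function(dataset, labels, subset) {
    switch(spec$kind,
      wrapper = wrapper_cv_error(dataset, labels, subset, spec),
      distance_matrix = -distance_matrix_score(dataset, labels, subset, spec$distance),
      cluster_external = cluster_external_error(dataset, labels, subset, spec))
  }
}

# Stratified fold assignment: within each class, shuffled samples are dealt
# to folds round-robin.  Degrades gracefully when a class is smaller than k.
stratified_folds <- function(labels, k, seed) {
  withr_seed(seed, {
    fold <- stats::setNames(integer(length(labels)), names(labels))
    for (cl in unique(labels)) {
      ids <- names(labels)[labels == cl]
      ids <- ids[sample.int(length(ids))]
      fold[ids] <- rep(seq_len(k), length.out = length(ids))
    }
    fold
  })
}

#' Wrapper cross-validation error of a classifier on a gene subset
#'
#' Mean misclassification rate over stratified k-fold CV of the named
#' classifier trained on the subset's rows only.  Folds are derived
#' deterministically from the spec's seed.
#'
#' @param dataset An `ExpressionDataset`.
#' @param labels Named class labels.
#' @param subset Non-empty character vector of gene ids.
#' @param spec An `EvaluatorSpec` of kind `"wrapper"`.
#' @return Error rate in \[0, 1\].
#' @export
wrapper_cv_error <- function(dataset, labels = dataset$labels, subset,
                             spec = evaluator_spec("wrapper")) {
  if (length(subset) == 0) stop("subset must be non-empty")
  labels <- labels[sample_ids(dataset)]
  x <- t(dataset$values[subset, , drop = FALSE])   # samples x genes
  fold <- stratified_folds(labels, spec$k_folds, spec$seed)
  wrong <- 0L
  for (f in sort(unique(fold))) {
    test <- fold == f
    model <- fit_classifier(x[!test, , drop = FALSE], labels[!test], spec$classifier_id)
    pred <- model(x[test, , drop = FALSE])
    wrong <- wrong + sum(pred != labels[test])
  }
  wrong / length(labels)
}

# Classifier factory: returns predict(x_new) -> character labels.
fit_classifier <- function(x, y, id) {
  y <- as.character(y)
  if (length(unique(y)) < 2) {
    only <- y[1]
    return(function(x_new) rep(only, nrow(x_new)))
  }
  switch(id,
    svm = {
      fit <- e1071::svm(x, factor(y), kernel = "linear", scale = FALSE)
      function(x_new) as.character(stats::predict(fit, x_new))
    },
    nb_gauss = {
      fit <- e1071::naiveBayes(x, factor(y))
      function(x_new) as.character(stats::predict(fit, x_new))
    },
    nb_kde = fit_nb_kde(x, y),
    bayes_net = fit_tan(x, y),
    stop("unknown classifier_id '", id, "'"))
}

# Naive Bayes with per-class, per-feature Gaussian-kernel density estimates.
fit_nb_kde <- function(x, y) {
  classes <- sort(unique(y))
  prior <- table(factor(y, classes)) / length(y)
  train <- lapply(classes, function(cl) x[y == cl, , drop = FALSE])
  names(train) <- classes
  bw <- lapply(train, function(m) {
    apply(m, 2, function(v) {
      b <- tryCatch(stats::bw.nrd0(v), error = function(e) NA_real_)
      if (!is.finite(b) || b <= 0) max(stats::sd(v), 1e-3) * 0.5 + 1e-3 else b
    })
  })
  function(x_new) {
    ll <- vapply(classes, function(cl) {
      m <- train[[cl]]; b <- bw[[cl]]
      apply(x_new, 1, function(row) {
        sum(vapply(seq_along(row), function(j) {
          log(mean(stats::dnorm(row[j], mean = m[, j], sd = b[j])) + 1e-300)
        }, numeric(1)))
      }) + log(as.numeric(prior[cl]))
    }, numeric(nrow(x_new)))
    ll <- matrix(ll, nrow = nrow(x_new))
    classes[max.col(ll, ties.method = "first")]
  }
}

# Tree-augmented naive Bayes on discretized features: a Chow-Liu tree over
# class-conditional MI gives each feature one feature parent.  Bins are
# equal-width thirds of the training range, which keeps well-separated
# expression modes in distinct bins (equal-frequency cuts would split them).
fit_tan <- function(x, y) {
  classes <- sort(unique(y))
  p <- ncol(x)
  n_bins <- 3L
  breaks <- lapply(seq_len(p), function(j) {
    rng <- range(x[, j])
    if (diff(rng) == 0) return(rng[1])
    rng[1] + diff(rng) * c(1, 2) / 3
  })
  bin <- function(m) vapply(seq_len(p), function(j)
    findInterval(m[, j], breaks[[j]]) + 1L, integer(nrow(m)))
  xb <- matrix(bin(x), ncol = p)

  parent <- rep(0L, p)
  if (p > 1) {
    cmi <- matrix(0, p, p)
    for (cl in classes) {
      rows <- y == cl
      wc <- sum(rows) / length(y)
      for (i in seq_len(p - 1)) for (j in seq(i + 1, p)) {
        m <- mi_from_counts(table(factor(xb[rows, i], 1:3), factor(xb[rows, j], 1:3)))
        cmi[i, j] <- cmi[i, j] + wc * m
      }
    }
    # Prim's algorithm for the maximum-weight spanning tree rooted at 1
    in_tree <- c(TRUE, rep(FALSE, p - 1))
    cmi <- cmi + t(cmi)
    for (step in seq_len(p - 1)) {
      w <- cmi[in_tree, !in_tree, drop = FALSE]
      best <- which(w == max(w), arr.ind = TRUE)[1, ]
      from <- which(in_tree)[best[1]]; to <- which(!in_tree)[best[2]]
      parent[to] <- from
      in_tree[to] <- TRUE
    }
  }

  laplace <- 1
  cpt <- lapply(classes, function(cl) {
    rows <- which(y == cl)
    lapply(seq_len(p), function(j) {
      if (parent[j] == 0L) {
        cnt <- tabulate(xb[rows, j], n_bins) + laplace
        log(cnt / sum(cnt))
      } else {
        tab <- table(factor(xb[rows, parent[j]], 1:3), factor(xb[rows, j], 1:3)) + laplace
        log(tab / rowSums(tab))
      }
    })
  })
  names(cpt) <- classes
  prior <- log((table(factor(y, classes)) + laplace) / (length(y) + laplace * length(classes)))

  function(x_new) {
    xnb <- matrix(bin(x_new), ncol = p)
    score <- vapply(classes, function(cl) {
      apply(xnb, 1, function(row) {
        s <- as.numeric(prior[cl])
        for (j in seq_len(p)) {
          s <- s + if (parent[j] == 0L) cpt[[cl]][[j]][row[j]]
                   else cpt[[cl]][[j]][row[parent[j]], row[j]]
        }
        s
      })
    }, numeric(nrow(x_new)))
    score <- matrix(score, nrow = nrow(x_new))
    classes[max.col(score, ties.method = "first")]
  }
}

# Sample x sample distance matrix on a gene subset.
sample_distances <- function(values, distance) {
  if (distance == "pearson") {
    if (nrow(values) < 2)
      stop("pearson distance needs >= 2 genes")
    sds <- apply(values, 2, stats::sd)
    if (any(sds == 0))
      stop("zero-variance sample under pearson distance: ",
           colnames(values)[which(sds == 0)[1]])
    1 - stats::cor(values)
  } else {
    as.matrix(stats::dist(t(values)))
  }
}

#' Distance-matrix class-separation score
#'
#' Mean pairwise distance between samples of different classes minus the
#' mean pairwise distance within classes, computed on the subset's rows.
#' Higher is better; evaluators report `-score` as the error.  Classes of
#' size 1 contribute no within pairs.
#'
#' @param dataset An `ExpressionDataset`.
#' @param labels Named class labels.
#' @param subset Gene ids.
#' @param distance `"pearson"` or `"euclidean"`.
#' @return The separation score.
#' @export
distance_matrix_score <- function(dataset, labels = dataset$labels, subset,
                                  distance = "pearson") {
  labels <- labels[sample_ids(dataset)]
  if (length(unique(labels)) < 2) stop("need >= 2 classes")
  # a single-gene profile has no shape, so 1 - r is undefined: score 0
  if (length(subset) < 2 && distance == "pearson") return(0)
  d <- sample_distances(dataset$values[subset, , drop = FALSE], distance)
  same <- outer(labels, labels, "==")
  ut <- upper.tri(d)
  between <- d[ut & !same]
  within <- d[ut & same]
  mean(between) - if (length(within)) mean(within) else 0
}

#' Dunn cluster-validity index
#'
#' Minimum between-cluster distance divided by the maximum cluster diameter.
#' All-singleton partitions (zero diameters everywhere) return `Inf`.
#'
#' @param distances Sample x sample distance matrix.
#' @param partition Cluster assignment vector (>= 2 clusters).
#' @return Non-negative index (higher = better separation).
#' @export
dunn_index <- function(distances, partition) {
  distances <- as.matrix(distances)
  ks <- unique(partition)
  if (length(ks) < 2) stop("Dunn index needs >= 2 clusters")
  diam <- vapply(ks, function(k) {
    idx <- which(partition == k)
    if (length(idx) < 2) 0 else max(distances[idx, idx])
  }, numeric(1))
  sep <- Inf
  for (i in seq_along(ks)[-length(ks)]) for (j in seq(i + 1, length(ks))) {
    a <- which(partition == ks[i]); b <- which(partition == ks[j])
    sep <- min(sep, min(distances[a, b, drop = FALSE]))
  }
  if (max(diam) == 0) return(Inf)
  sep / max(diam)
}

#' Figure of merit of a sample-clustering procedure
#'
#' Adapted to sample clustering by leaving genes out: for each gene, the
#' samples are clustered on all other genes and the root-mean-square
#' deviation of the held-out gene's values from their cluster means is
#' accumulated; the FOM is the mean over genes (lower = better).
#'
#' @param dataset An `ExpressionDataset`.
#' @param partition_fn Function taking an `ExpressionDataset` and returning
#'   a cluster assignment over its samples.
#' @return Non-negative FOM.
#' @export
figure_of_merit <- function(dataset, partition_fn) {
  genes <- gene_ids(dataset)
  if (ncol(dataset$values) < 2) stop("need >= 2 samples")
  fom_g <- vapply(genes, function(g) {
    # a single-gene dataset cannot leave its gene out; cluster on it directly
    rest <- if (length(genes) > 1) setdiff(genes, g) else genes
    part <- tryCatch(partition_fn(subset_dataset(dataset, genes = rest)),
                     error = function(e) stop("clustering failed leaving out gene '",
                                              g, "': ", conditionMessage(e)))
    v <- dataset$values[g, ]
    dev2 <- unlist(lapply(unique(part), function(k) {
      vk <- v[part == k]
      (vk - mean(vk))^2
    }))
    sqrt(mean(dev2))
  }, numeric(1))
  mean(fom_g)
}

# Run one pool algorithm; returns an integer partition over samples.
cluster_partition <- function(values, algorithm, k, distance, seed) {
  n <- ncol(values)
  if (k > n) stop("more clusters than samples")
  x <- t(values)
  if (distance == "pearson") {
    # standardized profiles make euclidean distance monotone in 1 - r
    x <- t(scale(values))
    x[!is.finite(x)] <- 0
  }
  d <- stats::as.dist(sample_distances(values, distance))
  part <- withr_seed(seed, switch(algorithm,
    kmeans = stats::kmeans(x, centers = k, nstart = 5)$cluster,
    pam = cluster::pam(d, k = k, cluster.only = TRUE),
    clara = cluster::clara(x, k = k)$clustering,
    agnes = stats::cutree(stats::as.hclust(cluster::agnes(d, method = "average")), k),
    diana = stats::cutree(stats::as.hclust(cluster::diana(d)), k),
    sota = sota_partition(x, k),
    hier_average = stats::cutree(stats::hclust(d, method = "average"), k),
    hier_complete = stats::cutree(stats::hclust(d, method = "complete"), k),
    hier_single = stats::cutree(stats::hclust(d, method = "single"), k),
    hier_ward = stats::cutree(stats::hclust(d, method = "ward.D2"), k),
    stop("unknown clustering algorithm '", algorithm, "'")))
  stats::setNames(as.integer(part), colnames(values))
}

# Minimal self-organizing (grid) clustering: k prototypes on a line updated
# by competitive learning with a shrinking neighborhood.
sota_partition <- function(x, k, epochs = 20) {
  n <- nrow(x)
  proto <- x[round(seq(1, n, length.out = k)), , drop = FALSE]
  for (e in seq_len(epochs)) {
    lr <- 0.5 * (1 - (e - 1) / epochs)
    radius <- max(0, (k / 2) * (1 - (e - 1) / epochs))
    for (i in sample.int(n)) {
      dists <- rowSums(sweep(proto, 2, x[i, ])^2)
      win <- which.min(dists)
      infl <- exp(-((seq_len(k) - win)^2) / (2 * (radius + 0.5)^2))
      proto <- proto + lr * infl * matrix(rep(x[i, ], each = k), nrow = k) -
        lr * infl * proto
    }
  }
  apply(x, 1, function(row) which.min(rowSums(sweep(proto, 2, row)^2)))
}

# O(n^3) Hungarian algorithm (augmenting paths with potentials) minimizing
# the total cost of a square assignment.
hungarian_assignment <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1); way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]; delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
          if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) { u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta; v[j + 1] <- v[j + 1] - delta }
        else minv[j + 1] <- minv[j + 1] - delta
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(n)) if (p[j + 1] > 0) assign[p[j + 1]] <- j
  assign
}

#' Match clusters to classes and count disagreements
#'
#' Optimal one-to-one matching of cluster ids to class labels on the
#' contingency table (Hungarian assignment maximizing agreement), returning
#' the misclassification rate.
#'
#' @param partition Cluster assignment vector.
#' @param labels Class labels (same order).
#' @return Error rate in \[0, 1\].
#' @export
cluster_match_error <- function(partition, labels) {
  pf <- factor(partition); lf <- factor(labels)
  tab <- table(pf, lf)
  n <- max(nlevels(pf), nlevels(lf))
  m <- matrix(0, n, n)
  m[seq_len(nrow(tab)), seq_len(ncol(tab))] <- tab
  assign <- hungarian_assignment(max(m) - m)
  agree <- sum(m[cbind(seq_len(n), assign)])
  1 - agree / length(labels)
}

#' Supervised-clustering external-validity error
#'
#' Runs every algorithm in the pool on the subset's rows with as many
#' clusters as classes, picks the partition with the best internal index
#' (max Dunn or min FOM) and scores it against the known classes by optimal
#' cluster-to-class matching.
#'
#' @param dataset An `ExpressionDataset`.
#' @param labels Named class labels.
#' @param subset Gene ids.
#' @param spec An `EvaluatorSpec` of kind `"cluster_external"`.
#' @return Error rate in \[0, 1\].
#' @export
cluster_external_error <- function(dataset, labels = dataset$labels, subset,
                                   spec = evaluator_spec("cluster_external")) {
  labels <- labels[sample_ids(dataset)]
  k <- length(unique(labels))
  values <- dataset$values[subset, , drop = FALSE]
  distance <- if (nrow(values) < 2 && spec$distance == "pearson") "euclidean" else spec$distance
  d <- sample_distances(values, distance)
  results <- list(); failures <- character(0)
  for (alg in spec$clustering_pool) {
    part <- tryCatch(cluster_partition(values, alg, k, distance,
                                       derive_seed(spec$seed, alg)),
                     error = function(e) conditionMessage(e))
    if (is.character(part)) { failures[alg] <- part; next }
    score <- if (spec$index == "dunn") {
      dunn_index(d, part)
    } else {
      sub_ds <- expression_dataset(values, NULL)
      -figure_of_merit(sub_ds, function(ds)
        cluster_partition(ds$values, alg, k, distance, derive_seed(spec$seed, alg)))
    }
    results[[alg]] <- list(partition = part, score = score)
  }
  if (!length(results))
    stop("all clustering algorithms failed: ",
         paste(names(failures), failures, sep = ": ", collapse = "; "))
  scores <- vapply(results, `[[`, numeric(1), "score")
  best <- results[[which.max(scores)]]
  cluster_match_error(best$partition, labels)
}
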