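#' Selection trace
#'
#' Ordered record of the candidate subsets a search run evaluated, with
#' their evaluation errors.  The best subset is the minimum-error subset
#' (first occurrence on ties).
#'
#' @param steps List of `list(subset = <gene ids>, error = <numeric>)`.
#' @return An object of class `SelectionTrace` with `steps`, `best_subset`,
#'   `best_error`.
#' @export
selection_trace <- function(steps) {
  if (!length(steps)) stop("a selection trace needs at least one step")
  errors <- vapply(steps, `[[`, numeric(1), "error")
  if (any(!is.finite(errors))) stop("non-finite evaluation error in trace")
  best <- which.min(errors)
  structure(list(steps = steps,
                 best_subset = steps[[best]]$subset,
                 best_error = errors[best]),
            class = "SelectionTrace")
}

#' @export
print.SelectionTrace <- function(x, ...) {
  cat(sprintf("SelectionTrace: %d steps; best |subset| = %d, best error = %.4g\n",
              length(x$steps), length(x$best_subset), x$best_error))
  invisible(x)
}

subset_key <- function(genes) paste(sort(genes), collapse = "\r")

# ---------------------------------------------------------------------------
# Pairwise-MI machinery (vectorized over genes via bin-indicator products)

# Gene x gene plug-in MI matrix (bits) from a discretized genes x samples
# matrix.  O(n_bins^2) matrix products of size n_genes x n_samples.
pairwise_mi_matrix <- function(disc, n_bins) {
  n_s <- ncol(disc)
  ind <- lapply(seq_len(n_bins) - 1L, function(b) (disc == b) * 1)
  marg <- vapply(ind, rowSums, numeric(nrow(disc))) / n_s   # n_g x n_bins
  marg <- matrix(marg, nrow = nrow(disc))
  mi <- matrix(0, nrow(disc), nrow(disc), dimnames = list(rownames(disc), rownames(disc)))
  for (a in seq_len(n_bins)) for (b in seq_len(n_bins)) {
    pab <- (ind[[a]] %*% t(ind[[b]])) / n_s
    denom <- outer(marg[, a], marg[, b])
    pos <- pab > 0
    mi[pos] <- mi[pos] + pab[pos] * log2(pab[pos] / denom[pos])
  }
  mi
}

# MI of every row of `disc` against a single discretized vector `vec`.
mi_vs_vector <- function(disc, vec, n_bins) {
  n_s <- ncol(disc)
  out <- numeric(nrow(disc))
  pa <- vapply(seq_len(n_bins) - 1L, function(b) rowSums(disc == b), numeric(nrow(disc))) / n_s
  pa <- matrix(pa, nrow = nrow(disc))
  for (a in seq_len(n_bins)) for (b in seq_len(n_bins)) {
    nb <- sum(vec == b - 1L)
    if (nb == 0) next
    pab <- rowSums(disc[, vec == b - 1L, drop = FALSE] == a - 1L) / n_s
    denom <- pa[, a] * (nb / n_s)
    pos <- pab > 0
    out[pos] <- out[pos] + pab[pos] * log2(pab[pos] / denom[pos])
  }
  stats::setNames(out, rownames(disc))
}

# ---------------------------------------------------------------------------
# RFE coefficients

# Coefficient I for every gene of the current (discretized) subset: with
# gene g excluded, each sample is the discretized profile of the remaining
# genes; I(g) = sum of sample-pair MI between classes minus within classes.
# Exploits that excluding g only decrements one cell of each sample pair's
# joint bin-count table, so each pair costs n_bins^2 small MI evaluations.
rfe_coefficients_all <- function(disc, labels, n_bins) {
  n_g <- nrow(disc); n_s <- ncol(disc)
  coef <- stats::setNames(numeric(n_g), rownames(disc))
  cells <- n_bins * n_bins
  for (u in seq_len(n_s - 1)) {
    du <- disc[, u]
    for (v in seq(u + 1, n_s)) {
      cell <- du * n_bins + disc[, v] + 1L
      counts <- tabulate(cell, cells)
      mi_ex <- numeric(cells)
      for (cc in which(counts > 0)) {
        nc <- counts
        nc[cc] <- nc[cc] - 1L
        mi_ex[cc] <- mi_from_counts(matrix(nc, n_bins, n_bins))
      }
      s <- if (labels[u] == labels[v]) -1 else 1
      coef <- coef + s * mi_ex[cell]
    }
  }
  coef
}

#' RFE exclusion coefficient of one gene
#'
#' With the gene removed from the current subset, every sample becomes the
#' discretized expression profile of the remaining genes; the coefficient is
#' the sum of sample-by-sample MI over between-class sample pairs minus the
#' sum over within-class pairs.  A small coefficient means the gene's
#' exclusion leaves the classes well separated, i.e. the gene is least
#' needed.
#'
#' @param dataset An `ExpressionDataset`.
#' @param labels Named class labels (default: the dataset's).
#' @param excluded_gene Gene id, member of `current_subset`.
#' @param current_subset Character vector of >= 2 gene ids.
#' @param disc A `DiscretizationSpec`.
#' @return The coefficient (bits).
#' @export
rfe_coefficient <- function(dataset, labels = dataset$labels, excluded_gene,
                            current_subset, disc = discretization_spec()) {
  if (!excluded_gene %in% current_subset) stop("excluded_gene not in current_subset")
  if (length(current_subset) < 2) stop("current subset must have >= 2 genes")
  d <- discretize_matrix(dataset$values[current_subset, , drop = FALSE], disc)
  labels <- labels[colnames(d)]
  rfe_coefficients_all(d, labels, disc$n_bins)[[excluded_gene]]
}

#' RFE search specification
#'
#' @param m Genes removed per first-pass iteration (>= 1).
#' @param x First-pass iterations; default enough to reach the floor.
#' @param y Refinement iterations around the best first-pass subset,
#'   removing one gene at a time (default 0).
#' @param redundancy_mode `"none"`, `"mi"` (penalize MI redundancy),
#'   `"go_min"` (penalize GO similarity) or `"go_max"` (reward it).
#' @param redundancy_weight Non-negative weight of the redundancy term.
#' @return An object of class `RfeSpec`.
#' @export
rfe_spec <- function(m = 1L, x = 10000L, y = 0L,
                     redundancy_mode = c("none", "mi", "go_min", "go_max"),
                     redundancy_weight = 1) {
  redundancy_mode <- match.arg(redundancy_mode)
  stopifnot(m >= 1, x >= 1, y >= 0, redundancy_weight >= 0)
  structure(list(m = as.integer(m), x = as.integer(x), y = as.integer(y),
                 redundancy_mode = redundancy_mode,
                 redundancy_weight = redundancy_weight),
            class = "RfeSpec")
}

# Pairwise Jaccard similarity matrix of GO term sets for a gene universe.
go_jaccard_matrix <- function(genes, ann) {
  terms <- unique(unlist(lapply(genes, function(g) if (g %in% names(ann)) ann[[g]] else character(0))))
  if (!length(terms)) {
    m <- matrix(0, length(genes), length(genes), dimnames = list(genes, genes))
    return(m)
  }
  memb <- vapply(genes, function(g) terms %in% (if (g %in% names(ann)) ann[[g]] else character(0)),
                 logical(length(terms)))
  memb <- matrix(memb * 1, nrow = length(terms), dimnames = list(terms, genes))
  inter <- t(memb) %*% memb
  sizes <- colSums(memb)
  uni <- outer(sizes, sizes, "+") - inter
  out <- inter / ifelse(uni == 0, 1, uni)   # both-empty pairs contribute 0
  dimnames(out) <- list(genes, genes)
  out
}

#' Backward recursive feature elimination
#'
#' Starts from the full gene set; at each iteration evaluates the current
#' subset, computes the exclusion coefficient of every gene (coefficient I;
#' redundancy-aware modes add a weighted redundancy term, forming
#' coefficient II) and removes the `m` genes with the smallest
#' coefficients.  After `x` first-pass iterations (or when `<= m` genes
#' remain), `y` refinement iterations restart from the best subset found and
#' remove one gene at a time.  Returns the minimum-error subset.
#'
#' @param dataset An `ExpressionDataset`.
#' @param labels Named class labels (default: the dataset's).
#' @param spec An `RfeSpec`.
#' @param evaluator An evaluator function (see [make_evaluator()]).
#' @param disc A `DiscretizationSpec`.
#' @param annotation A `GeneAnnotation`, required by the GO redundancy modes.
#' @return A `SelectionTrace`.
#' @export
rfe_search <- function(dataset, labels = dataset$labels, spec = rfe_spec(),
                       evaluator, disc = discretization_spec(),
                       annotation = NULL) {
  stopifnot(inherits(spec, "RfeSpec"))
  genes <- gene_ids(dataset)
  if (length(genes) <= spec$m) stop("need more genes than the removal step m")
  labels <- labels[sample_ids(dataset)]
  disc_all <- discretize_matrix(dataset$values, disc)
  use_go <- spec$redundancy_mode %in% c("go_min", "go_max")
  if (use_go) {
    if (is.null(annotation)) stop("GO redundancy modes need a GeneAnnotation")
    go_sim <- go_jaccard_matrix(genes, annotation)
  }

  steps <- list()
  seen <- character(0)
  record <- function(subset) {
    key <- subset_key(subset)
    if (key %in% seen) return(invisible(NULL))
    seen <<- c(seen, key)
    steps[[length(steps) + 1L]] <<- list(subset = subset,
                                         error = evaluator(dataset, labels, subset))
    invisible(NULL)
  }

  coefficient <- function(subset) {
    d <- disc_all[subset, , drop = FALSE]
    cf <- rfe_coefficients_all(d, labels, disc$n_bins)
    if (spec$redundancy_mode == "none") return(cf)
    red <- if (spec$redundancy_mode == "mi") {
      mi <- pairwise_mi_matrix(d, disc$n_bins)
      (rowSums(mi) - diag(mi)) / (length(subset) - 1)
    } else {
      gs <- go_sim[subset, subset, drop = FALSE]
      (rowSums(gs) - diag(gs)) / (length(subset) - 1)
    }
    sgn <- if (spec$redundancy_mode == "go_max") 1 else -1
    cf + sgn * spec$redundancy_weight * red
  }

  eliminate <- function(subset, n_remove) {
    cf <- coefficient(subset)
    # deterministic: ties broken by gene id
    ord <- order(cf, names(cf))
    setdiff(subset, names(cf)[ord[seq_len(n_remove)]])
  }

  current <- genes
  for (i in seq_len(spec$x)) {
    record(current)
    if (length(current) <= spec$m) break
    current <- eliminate(current, spec$m)
  }
  record(current)

  if (spec$y > 0) {
    best <- steps[[which.min(vapply(steps, `[[`, numeric(1), "error"))]]$subset
    current <- best
    for (i in seq_len(spec$y)) {
      if (length(current) <= 1) break
      current <- eliminate(current, 1L)
      record(current)
    }
  }
  selection_trace(steps)
}

#' Forward minimum-redundancy maximum-relevance search
#'
#' Starts from an empty set; at each step every remaining gene gets the
#' coefficient NMI(gene, class) / (mean MI with the already-selected genes),
#' with an epsilon redundancy of 1e-6 bits for the empty set so the first
#' pick is the maximum-relevance gene.  The argmax gene is appended, the
#' subset evaluated, and the minimum-error prefix returned.
#'
#' @param dataset An `ExpressionDataset`.
#' @param labels Named class labels (default: the dataset's).
#' @param disc A `DiscretizationSpec`.
#' @param evaluator An evaluator function.
#' @param max_iter Number of genes to add (<= number of genes).
#' @return A `SelectionTrace`.
#' @export
mrmr_search <- function(dataset, labels = dataset$labels,
                        disc = discretization_spec(), evaluator,
                        max_iter = 30L) {
  eps_red <- 1e-6
  genes <- gene_ids(dataset)
  max_iter <- min(max_iter, length(genes))
  labels <- labels[sample_ids(dataset)]
  cls <- as.integer(factor(labels)) - 1L
  disc_all <- discretize_matrix(dataset$values, disc)
  relevance <- vapply(genes, function(g) normalized_mi(disc_all[g, ], cls), numeric(1))

  selected <- character(0)
  red_sum <- stats::setNames(numeric(length(genes)), genes)
  steps <- list()
  for (i in seq_len(max_iter)) {
    candidates <- setdiff(genes, selected)
    red <- if (length(selected) == 0) rep(eps_red, length(candidates))
           else pmax(red_sum[candidates] / length(selected), eps_red)
    coef <- relevance[candidates] / red
    pick <- candidates[order(-coef, candidates)][1]
    selected <- c(selected, pick)
    red_sum <- red_sum + mi_vs_vector(disc_all, disc_all[pick, ], disc$n_bins)
    steps[[i]] <- list(subset = selected,
                       error = evaluator(dataset, labels, selected))
  }
  selection_trace(steps)
}

#' Univariate forward selection
#'
#' Ranks all genes once by a univariate score (GS1, GS2 or the ANOVA F),
#' adds them greedily in rank order, evaluates each prefix and returns the
#' minimum-error prefix.
#'
#' @param dataset An `ExpressionDataset`.
#' @param labels Named class labels (default: the dataset's).
#' @param score_id `"gs1"`, `"gs2"` or `"f"`.
#' @param evaluator An evaluator function.
#' @param max_iter Longest prefix evaluated.
#' @return A `SelectionTrace`.
#' @export
univariate_forward_search <- function(dataset, labels = dataset$labels,
                                      score_id = "f", evaluator, max_iter = 30L) {
  scores <- univariate_scores(dataset, labels, score_id)
  ranked <- names(scores)[order(-scores, names(scores))]
  max_iter <- min(max_iter, length(ranked))
  labels <- labels[sample_ids(dataset)]
  steps <- lapply(seq_len(max_iter), function(i) {
    prefix <- ranked[seq_len(i)]
    list(subset = prefix, error = evaluator(dataset, labels, prefix))
  })
  selection_trace(steps)
}

#' Genetic-algorithm search specification
#'
#' @param population_size Chromosomes per generation.
#' @param chromosome_length Genes per chromosome (fixed subset size,
#'   default 70).
#' @param crossover_prob Probability a non-elite slot pair undergoes uniform
#'   crossover (parents pass through otherwise).
#' @param mutation_prob Per-position probability of swapping a gene for a
#'   uniformly drawn unused gene.
#' @param elitism_count Fittest chromosomes copied intact (default 1).
#' @param max_generations Generation threshold before the convergence test
#'   applies (default 100).
#' @param slope_threshold Stop once past `max_generations` when the absolute
#'   least-squares slope of per-generation minimum error over the last
#'   `slope_window` generations falls below this (default 0.05).
#' @param slope_window Generations entering the slope fit (default 20).
#' @param hard_cap Absolute generation limit (default 4 * max_generations).
#' @param seed Integer seed for the evolutionary randomness.
#' @return An object of class `GaSpec`.
#' @export
ga_spec <- function(population_size = 20L, chromosome_length = 70L,
                    crossover_prob = 0.8, mutation_prob = 0.02,
                    elitism_count = 1L, max_generations = 100L,
                    slope_threshold = 0.05, slope_window = 20L,
                    hard_cap = 4L * max_generations, seed = 1L) {
  stopifnot(population_size >= 1, chromosome_length >= 1,
            crossover_prob >= 0, crossover_prob <= 1,
            mutation_prob >= 0, mutation_prob <= 1,
            elitism_count >= 0, max_generations >= 1, slope_window >= 2)
  structure(list(population_size = as.integer(population_size),
                 chromosome_length = as.integer(chromosome_length),
                 crossover_prob = crossover_prob, mutation_prob = mutation_prob,
                 elitism_count = as.integer(elitism_count),
                 max_generations = as.integer(max_generations),
                 slope_threshold = slope_threshold,
                 slope_window = as.integer(slope_window),
                 hard_cap = as.integer(hard_cap), seed = as.integer(seed)),
            class = "GaSpec")
}

#' Genetic-algorithm subset search
#'
#' Evolves fixed-length gene subsets with fitness 1 - evaluation error.
#' Elitism keeps the fittest chromosome intact; roulette-wheel selection
#' makes fitter chromosomes parent more offspring; uniform crossover makes
#' two children from two parents (applied with probability
#' `crossover_prob`, parents copied otherwise); mutation swaps positions for
#' unused genes.  Chromosomes never contain a duplicated gene.  The search
#' stops after `max_generations` once the recent minimum-error trend is
#' flat (see [ga_spec()]), returning the best chromosome ever seen.
#'
#' @param dataset An `ExpressionDataset`.
#' @param labels Named class labels (default: the dataset's).
#' @param spec A `GaSpec`.
#' @param evaluator An evaluator function.
#' @return A `SelectionTrace` (one step per distinct per-generation best).
#' @export
ga_search <- function(dataset, labels = dataset$labels, spec = ga_spec(), evaluator) {
  stopifnot(inherits(spec, "GaSpec"))
  genes <- gene_ids(dataset)
  if (spec$chromosome_length > length(genes))
    stop("chromosome_length exceeds the number of genes")
  labels <- labels[sample_ids(dataset)]

  cache <- new.env(parent = emptyenv())
  evaluate <- function(chrom) {
    key <- subset_key(chrom)
    if (!is.null(cache[[key]])) return(cache[[key]])
    e <- evaluator(dataset, labels, chrom)
    if (!is.finite(e)) stop("non-finite fitness for a chromosome")
    cache[[key]] <- e
    e
  }

  withr_seed(spec$seed, {
    pop <- replicate(spec$population_size,
                     sample(genes, spec$chromosome_length), simplify = FALSE)
    steps <- list(); seen <- character(0)
    gen_min <- numeric(0)
    best_chrom <- NULL; best_err <- Inf
    gen <- 0L
    repeat {
      gen <- gen + 1L
      errs <- vapply(pop, evaluate, numeric(1))
      if (any(!is.finite(errs))) stop("non-finite fitness at generation ", gen)
      gbest <- which.min(errs)
      gen_min[gen] <- errs[gbest]
      if (errs[gbest] < best_err) {
        best_err <- errs[gbest]
        best_chrom <- pop[[gbest]]
      }
      key <- subset_key(pop[[gbest]])
      if (!key %in% seen) {
        seen <- c(seen, key)
        steps[[length(steps) + 1L]] <- list(subset = pop[[gbest]], error = errs[gbest])
      }

      if (gen >= spec$hard_cap) break
      if (gen > spec$max_generations) {
        w <- min(spec$slope_window, gen)
        idx <- seq(gen - w + 1L, gen)
        slope <- stats::coef(stats::lm(gen_min[idx] ~ idx))[2]
        if (is.na(slope) || abs(slope) < spec$slope_threshold) break
      }

      fitness <- 1 - errs
      w <- fitness - min(fitness) + 1e-9
      elite <- pop[order(errs)][seq_len(min(spec$elitism_count, length(pop)))]
      children <- list()
      while (length(children) < spec$population_size - length(elite)) {
        parents <- pop[sample.int(length(pop), 2, replace = TRUE, prob = w)]
        if (stats::runif(1) < spec$crossover_prob) {
          kids <- ga_crossover(parents[[1]], parents[[2]], genes)
        } else kids <- parents
        kids <- lapply(kids, ga_mutate, genes = genes, p = spec$mutation_prob)
        children <- c(children, kids)
      }
      pop <- c(elite, children[seq_len(spec$population_size - length(elite))])
    }
    selection_trace(steps)
  })
}

# Uniform crossover over two equal-length duplicate-free chromosomes; each
# position takes a parent's gene at random, duplicates resolved from the
# parents' pooled genes, then from the full unused universe.
ga_crossover <- function(p1, p2, genes) {
  L <- length(p1)
  make_child <- function() {
    take1 <- stats::runif(L) < 0.5
    child <- character(L)
    for (i in seq_len(L)) {
      cand <- if (take1[i]) c(p1[i], p2[i]) else c(p2[i], p1[i])
      pick <- cand[!cand %in% child[seq_len(i - 1)]]
      if (length(pick) == 0) {
        pool <- setdiff(union(p1, p2), child[seq_len(i - 1)])
        if (length(pool) == 0) pool <- setdiff(genes, child[seq_len(i - 1)])
        pick <- sample(pool, 1)
      }
      child[i] <- pick[1]
    }
    child
  }
  list(make_child(), make_child())
}

ga_mutate <- function(chrom, genes, p) {
  hit <- which(stats::runif(length(chrom)) < p)
  for (i in hit) {
    unused <- setdiff(genes, chrom)
    if (length(unused) == 0) break
    chrom[i] <- sample(unused, 1)
  }
  chrom
}

#' Available selection method ids
#'
#' The method grid combines a search strategy with a default evaluator:
#' `rfe`, `rfe_mr`, `rfe_minr_mingo`, `rfe_maxr_maxgo`, `mrmr`, `ga` use the
#' distance-matrix criterion; `rfe_svm`, `rfe_nb`, `rfe_bn` wrap 5-fold CV
#' of the named classifier; `gs1`, `gs2`, `ftest` use 10-fold CV of a linear
#' SVM.  Appending `_clust_dunn` or `_clust_fom` to any base id switches to
#' supervised clustering with external validity, choosing the clustering
#' algorithm by Dunn index or figure of merit.
#'
#' @return Character vector of base method ids.
#' @export
selection_methods <- function() {
  c("rfe", "rfe_mr", "rfe_minr_mingo", "rfe_maxr_maxgo",
    "rfe_svm", "rfe_nb", "rfe_bn", "mrmr", "ga", "gs1", "gs2", "ftest")
}

#' Run a named selection method
#'
#' @param method A method id (see [selection_methods()]), optionally with a
#'   `_clust_dunn` / `_clust_fom` suffix.
#' @param dataset An `ExpressionDataset`.
#' @param labels Named class labels (default: the dataset's).
#' @param evaluator Optional evaluator (id string or function) overriding
#'   the method's default.
#' @param max_iter Forward-search length / RFE budget control.
#' @param rfe Optional `RfeSpec` override for the RFE family.
#' @param ga Optional `GaSpec` override for the genetic algorithm.
#' @param disc A `DiscretizationSpec`.
#' @param annotation `GeneAnnotation` for the GO-driven RFE variants.
#' @param seed Integer seed used for stochastic components.
#' @return A `SelectionTrace`.
#' @export
run_selection <- function(method, dataset, labels = dataset$labels,
                          evaluator = NULL, max_iter = 30L, rfe = NULL,
                          ga = NULL, disc = discretization_spec(),
                          annotation = NULL, seed = 1L) {
  base <- sub("_clust_(dunn|fom)$", "", method)
  suffix <- if (grepl("_clust_dunn$", method)) "cluster_dunn"
            else if (grepl("_clust_fom$", method)) "cluster_fom" else NULL
  if (!base %in% selection_methods())
    stop("unknown method '", method, "'; valid: ",
         paste(selection_methods(), collapse = ", "))
  default_eval <- if (!is.null(suffix)) suffix else switch(base,
    rfe_svm = "wrapper_svm", rfe_nb = "wrapper_nb_gauss", rfe_bn = "wrapper_bayes_net",
    gs1 = , gs2 = , ftest = "wrapper_svm_10", "distance_pearson")
  ev <- evaluator %||% default_eval
  if (is.character(ev)) ev <- make_evaluator(ev, seed = seed)

  n_genes <- nrow(dataset$values)
  if (is.null(rfe)) {
    m <- max(1L, n_genes %/% 25L)
    rfe <- rfe_spec(m = m,
                    redundancy_mode = switch(base, rfe_mr = "mi",
                                             rfe_minr_mingo = "go_min",
                                             rfe_maxr_maxgo = "go_max", "none"))
  }
  if (is.null(ga)) ga <- ga_spec(chromosome_length = min(70L, n_genes %/% 2L),
                                 seed = derive_seed(seed, "ga"))

  switch(base,
    rfe = , rfe_mr = , rfe_svm = , rfe_nb = , rfe_bn = ,
    rfe_minr_mingo = , rfe_maxr_maxgo =
      rfe_search(dataset, labels, rfe, ev, disc, annotation),
    mrmr = mrmr_search(dataset, labels, disc, ev, max_iter),
    ga = ga_search(dataset, labels, ga, ev),
    gs1 = univariate_forward_search(dataset, labels, "gs1", ev, max_iter),
    gs2 = univariate_forward_search(dataset, labels, "gs2", ev, max_iter),
    ftest = univariate_forward_search(dataset, labels, "f", ev, max_iter))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
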