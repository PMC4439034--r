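#' Hierarchical clustering of samples
#'
#' Agglomerative dendrogram over samples with Pearson (1 - r) or euclidean
#' distance between sample expression profiles.
#'
#' @param dataset An `ExpressionDataset` (>= 2 samples).
#' @param linkage `"complete"` (default), `"average"`, `"single"` or
#'   `"ward"`.
#' @param distance `"pearson"` (default) or `"euclidean"`.
#' @return An object of class `ClusterTree`: the `hclust` object, the list
#'   of internal-node sample sets (merge order), and empty support slots.
#' @export
hcluster <- function(dataset, linkage = c("complete", "average", "single", "ward"),
                     distance = c("pearson", "euclidean")) {
  linkage <- match.arg(linkage)
  distance <- match.arg(distance)
  if (ncol(dataset$values) < 2) stop("need >= 2 samples")
  d <- stats::as.dist(sample_distances(dataset$values, distance))
  hc <- stats::hclust(d, method = if (linkage == "ward") "ward.D2" else linkage)
  structure(list(hclust = hc, linkage = linkage, distance = distance,
                 nodes = hclust_node_sets(hc), support = NULL,
                 n_boot = NULL, scales = NULL),
            class = "ClusterTree")
}

# Sample-id sets of the internal nodes, in merge order (last = root).
hclust_node_sets <- function(hc) {
  n <- length(hc$labels)
  sets <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    members <- integer(0)
    for (j in hc$merge[i, ]) {
      members <- c(members, if (j < 0) -j else NULL)
      if (j > 0) members <- c(members, match(sets[[j]], hc$labels))
    }
    sets[[i]] <- sort(hc$labels[members])
  }
  sets
}

#' @export
print.ClusterTree <- function(x, ...) {
  cat(sprintf("ClusterTree: %d samples, %s linkage, %s distance",
              length(x$hclust$labels), x$linkage, x$distance))
  if (!is.null(x$support))
    cat(sprintf("; AU/BP support from %d x %d bootstrap replicates",
                length(x$scales), x$n_boot))
  cat("\n")
  invisible(x)
}

#' Multiscale bootstrap support (BP and AU) for a cluster tree
#'
#' For each resampling ratio r, draws `n_boot` gene resamples of size
#' `ceiling(r * n_genes)` with replacement, reclusters the samples, and
#' records per original node the proportion of replicates containing an
#' identical sample set (BP_r).  `bp` is BP at r = 1.  The probit-transformed
#' profile z_r = qnorm(1 - BP_r) is fitted by weighted least squares to
#' v*sqrt(r) + c/sqrt(r) (binomial delta-method weights), and the
#' approximately unbiased support is au = 1 - pnorm(v - c).  Nodes with
#' BP_r in {0, 1} at every scale get au = bp and a degenerate-fit flag.
#'
#' @param dataset The `ExpressionDataset` the tree was built from.
#' @param tree A `ClusterTree` from [hcluster()].
#' @param n_boot Replicates per scale (>= 100).
#' @param scales Resampling ratios spanning 1 (default 0.5 to 1.4 by 0.1).
#' @param seed Integer seed.
#' @return The `ClusterTree` with a `support` data frame (`bp`, `au`, `v`,
#'   `c`, `degenerate` per node) plus the per-scale BP table.
#' @export
bootstrap_support <- function(dataset, tree, n_boot = 1000L,
                              scales = seq(0.5, 1.4, by = 0.1), seed = 1L) {
  stopifnot(inherits(tree, "ClusterTree"))
  if (n_boot < 100) stop("n_boot must be >= 100 for a stable multiscale fit")
  if (!any(abs(scales - 1) < 1e-9)) scales <- sort(c(scales, 1))
  n_genes <- nrow(dataset$values)
  node_keys <- vapply(tree$nodes, paste, character(1), collapse = "\r")
  bp_mat <- matrix(0, length(node_keys), length(scales),
                   dimnames = list(NULL, sprintf("r=%.2f", scales)))

  withr_seed(seed, {
    for (s in seq_along(scales)) {
      size <- ceiling(scales[s] * n_genes)
      hits <- numeric(length(node_keys))
      for (b in seq_len(n_boot)) {
        rows <- sample.int(n_genes, size, replace = TRUE)
        keys <- tryCatch({
          v <- dataset$values[rows, , drop = FALSE]
          d <- stats::as.dist(sample_distances(v, tree$distance))
          hc <- stats::hclust(d, method = if (tree$linkage == "ward") "ward.D2" else tree$linkage)
          vapply(hclust_node_sets(hc), paste, character(1), collapse = "\r")
        }, error = function(e) character(0))
        hits <- hits + (node_keys %in% keys)
      }
      bp_mat[, s] <- hits / n_boot
    }
  })

  r1 <- which(abs(scales - 1) < 1e-9)[1]
  fits <- lapply(seq_along(node_keys), function(i)
    fit_au(bp_mat[i, ], scales, n_boot, bp1 = bp_mat[i, r1]))
  support <- data.frame(node = seq_along(node_keys),
                        size = lengths(tree$nodes),
                        bp = bp_mat[, r1],
                        au = vapply(fits, `[[`, numeric(1), "au"),
                        v = vapply(fits, `[[`, numeric(1), "v"),
                        c = vapply(fits, `[[`, numeric(1), "c"),
                        degenerate = vapply(fits, `[[`, logical(1), "degenerate"))
  tree$support <- support
  tree$bp_table <- bp_mat
  tree$n_boot <- as.integer(n_boot)
  tree$scales <- scales
  tree
}

# Weighted probit fit of a single node's BP profile across scales.
fit_au <- function(bp, scales, n_boot, bp1) {
  if (all(bp %in% c(0, 1)))
    return(list(au = bp1, v = NA_real_, c = NA_real_, degenerate = TRUE))
  lo <- 1 / (2 * n_boot)
  bpc <- pmin(pmax(bp, lo), 1 - lo)
  z <- stats::qnorm(1 - bpc)
  w <- n_boot * stats::dnorm(z)^2 / (bpc * (1 - bpc))
  X <- cbind(sqrt(scales), 1 / sqrt(scales))
  fit <- stats::lm.wfit(X, z, w)
  v <- unname(fit$coefficients[1]); cc <- unname(fit$coefficients[2])
  if (any(!is.finite(c(v, cc))))
    return(list(au = bp1, v = NA_real_, c = NA_real_, degenerate = TRUE))
  list(au = 1 - stats::pnorm(v - cc), v = unname(v), c = unname(cc),
       degenerate = FALSE)
}

#' Highlight well-supported clusters
#'
#' The maximal internal nodes (excluding the root) whose AU support exceeds
#' the threshold, outermost (largest) first; no returned set contains
#' another.
#'
#' @param tree A `ClusterTree` with computed support.
#' @param threshold AU threshold (default 0.95, the conventional highlight
#'   cut).
#' @return List of sample-id vectors.
#' @export
highlight_clusters <- function(tree, threshold = 0.95) {
  if (is.null(tree$support)) stop("supports not computed; run bootstrap_support() first")
  n_nodes <- length(tree$nodes)
  cand <- which(tree$support$au > threshold & seq_len(n_nodes) < n_nodes)
  if (!length(cand)) return(list())
  sets <- tree$nodes[cand]
  ord <- order(-lengths(sets))
  sets <- sets[ord]
  keep <- list()
  for (s in sets) {
    contained <- any(vapply(keep, function(k) all(s %in% k), logical(1)))
    if (!contained) keep[[length(keep) + 1]] <- s
  }
  keep
}

#' Export a supported tree as node table
#' @param tree A `ClusterTree` with support.
#' @return Data frame with node id, size, member ids, bp and au.
#' @export
cluster_tree_table <- function(tree) {
  if (is.null(tree$support)) stop("supports not computed")
  data.frame(node = tree$support$node,
             size = tree$support$size,
             members = vapply(tree$nodes, paste, character(1), collapse = ","),
             bp = tree$support$bp, au = tree$support$au,
             stringsAsFactors = FALSE)
}
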