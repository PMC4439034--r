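#' Discretization specification
#'
#' @param n_bins Number of bins (>= 2, default 3).
#' @param strategy `"equal_frequency"` (bin boundaries at empirical
#'   quantiles, ties broken by stable order) or `"sign_threshold"` (the
#'   natural two-fold cuts on log2 ratios: M <= -1, -1 < M < 1, M >= 1;
#'   3 bins only).
#' @return An object of class `DiscretizationSpec`.
#' @export
discretization_spec <- function(n_bins = 3L, strategy = c("equal_frequency", "sign_threshold")) {
  strategy <- match.arg(strategy)
  n_bins <- as.integer(n_bins)
  if (n_bins < 2) stop("n_bins must be >= 2")
  if (strategy == "sign_threshold" && n_bins != 3)
    stop("sign_threshold discretization is defined for 3 bins")
  structure(list(n_bins = n_bins, strategy = strategy), class = "DiscretizationSpec")
}

#' Discretize a numeric vector into bin indices
#'
#' Equal-frequency binning assigns values to `n_bins` bins of near-equal
#' size (differing by at most 1 when values are distinct); ties are broken
#' by stable (original) order.  A constant vector collapses to a single bin.
#'
#' @param values Non-empty numeric vector.
#' @param spec A `DiscretizationSpec`.
#' @return Integer vector of 0-based bin indices.
#' @export
discretize <- function(values, spec = discretization_spec()) {
  if (length(values) == 0) stop("cannot discretize an empty vector")
  if (spec$strategy == "sign_threshold")
    return(ifelse(values <= -1, 0L, ifelse(values >= 1, 2L, 1L)))
  if (length(unique(values)) == 1) return(rep(0L, length(values)))
  r <- rank(values, ties.method = "first")
  as.integer(((r - 1L) * spec$n_bins) %/% length(values))
}

# Discretize every gene (row) of a matrix across samples.
discretize_matrix <- function(values, spec = discretization_spec()) {
  out <- t(apply(values, 1, discretize, spec = spec))
  dimnames(out) <- dimnames(values)
  out
}

# Plug-in MI in bits from a joint count table (matrix or vector of counts
# with known dimensions).
mi_from_counts <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts / n
  rp <- rowSums(p); cp <- colSums(p)
  pos <- p > 0
  sum(p[pos] * log2(p[pos] / outer(rp, cp)[pos]))
}

#' Mutual information between two discrete vectors
#'
#' Plug-in estimate from the joint empirical distribution, in bits
#' (base-2 logarithm).
#'
#' @param x,y Integer (bin index) vectors of equal length >= 2.
#' @return Non-negative MI in bits; symmetric in its arguments.
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (length(x) < 2) stop("need at least two observations")
  mi_from_counts(table(x, y))
}

# Entropy in bits of a discrete vector.
entropy_bits <- function(x) {
  p <- tabulate(as.integer(factor(x)))
  p <- p / sum(p)
  -sum(p[p > 0] * log2(p[p > 0]))
}

#' Normalized mutual information
#'
#' I(x; y) / sqrt(H(x) H(y)); defined as 0 when either entropy vanishes.
#' Lies in \[0, 1\].
#'
#' @inheritParams mutual_information
#' @return NMI in \[0, 1\].
#' @export
normalized_mi <- function(x, y) {
  hx <- entropy_bits(x); hy <- entropy_bits(y)
  if (hx == 0 || hy == 0) return(0)
  min(1, max(0, mutual_information(x, y) / sqrt(hx * hy)))
}

#' Mutual-information redundancy of a gene subset
#'
#' The mean pairwise MI over all unordered gene pairs in the subset, each
#' gene discretized across samples.
#'
#' @param subset Character vector of >= 2 gene ids.
#' @param dataset An `ExpressionDataset`.
#' @param disc A `DiscretizationSpec`.
#' @return Mean pairwise MI in bits.
#' @export
mi_redundancy <- function(subset, dataset, disc = discretization_spec()) {
  if (length(subset) < 2) stop("redundancy needs at least two genes")
  d <- discretize_matrix(dataset$values[subset, , drop = FALSE], disc)
  pairs <- utils::combn(length(subset), 2)
  mean(apply(pairs, 2, function(ij) mutual_information(d[ij[1], ], d[ij[2], ])))
}

# Mean MI of each row of disc_mat against a fixed discretized vector.
mi_against <- function(disc_mat, vec) {
  apply(disc_mat, 1, mutual_information, y = vec)
}

#' Construct a gene -> GO term annotation
#' @param terms Named list mapping gene id to a character vector of GO term
#'   ids (possibly empty).
#' @return An object of class `GeneAnnotation`.
#' @export
gene_annotation <- function(terms) {
  if (length(terms) && is.null(names(terms))) stop("annotation must be named by gene id")
  terms <- lapply(terms, function(x) unique(as.character(x)))
  structure(terms, class = "GeneAnnotation")
}

#' GO-similarity redundancy of a gene subset
#'
#' The mean pairwise Jaccard index |A n B| / |A u B| of the genes' GO term
#' sets; a pair where both sets are empty contributes 0.  Genes absent from
#' the annotation are treated as unannotated.
#'
#' @param subset Character vector of >= 2 gene ids.
#' @param ann A `GeneAnnotation`.
#' @return Mean pairwise similarity in \[0, 1\].
#' @export
go_redundancy <- function(subset, ann) {
  if (length(subset) < 2) stop("redundancy needs at least two genes")
  sets <- lapply(subset, function(g) if (g %in% names(ann)) ann[[g]] else character(0))
  pairs <- utils::combn(length(subset), 2)
  mean(apply(pairs, 2, function(ij) {
    a <- sets[[ij[1]]]; b <- sets[[ij[2]]]
    u <- union(a, b)
    if (length(u) == 0) 0 else length(intersect(a, b)) / length(u)
  }))
}

#' Univariate relevance scores
#'
#' Per-gene class-separation scores; higher means more relevant.
#' `"f"` is the one-way ANOVA F statistic; `"gs1"` is the Golub-style
#' signal-to-noise, maximized over class pairs: max |mu_i - mu_j|/(s_i + s_j);
#' `"gs2"` is the ratio of between-class to within-class sums of squares
#' (BSS/WSS).  Denominators carry an epsilon of 1e-12 so degenerate
#' zero-variance genes score finitely.
#'
#' @param dataset An `ExpressionDataset`.
#' @param labels Named character vector of class labels (defaults to the
#'   dataset's own labels).
#' @param score_id One of `"gs1"`, `"gs2"`, `"f"`.
#' @return Named numeric vector of scores, one per gene.
#' @export
univariate_scores <- function(dataset, labels = dataset$labels,
                              score_id = c("f", "gs1", "gs2")) {
  score_id <- match.arg(score_id)
  stopifnot(!is.null(labels))
  labels <- labels[sample_ids(dataset)]
  cls <- unique(labels)
  if (length(cls) < 2) stop("need at least two classes")
  x <- dataset$values
  n <- ncol(x)
  eps <- 1e-12

  ns <- vapply(cls, function(c) sum(labels == c), numeric(1))
  means <- vapply(cls, function(c) rowMeans(x[, labels == c, drop = FALSE]), numeric(nrow(x)))
  means <- matrix(means, nrow = nrow(x), dimnames = list(rownames(x), cls))
  vars <- vapply(cls, function(c) {
    xc <- x[, labels == c, drop = FALSE]
    if (ncol(xc) < 2) rep(0, nrow(x)) else apply(xc, 1, stats::var)
  }, numeric(nrow(x)))
  vars <- matrix(vars, nrow = nrow(x), dimnames = list(rownames(x), cls))

  if (score_id == "gs1") {
    pairs <- utils::combn(length(cls), 2)
    s <- apply(pairs, 2, function(ij) {
      abs(means[, ij[1]] - means[, ij[2]]) /
        (sqrt(vars[, ij[1]]) + sqrt(vars[, ij[2]]) + eps)
    })
    s <- matrix(s, nrow = nrow(x))
    return(stats::setNames(apply(s, 1, max), rownames(x)))
  }

  grand <- rowMeans(x)
  bss <- as.vector((means - grand)^2 %*% ns)
  wss <- as.vector(vars %*% (ns - 1))
  if (score_id == "gs2") return(stats::setNames(bss / (wss + eps), rownames(x)))
  if (any(ns < 2)) stop("F score needs >= 2 samples per class")
  k <- length(cls)
  stats::setNames((bss / (k - 1)) / (wss / (n - k) + eps), rownames(x))
}
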