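#' Fold-change prefilter
#'
#' Keeps exactly the genes showing at least `fold_threshold`-fold regulation
#' (|M| >= log2(fold_threshold)) in at least
#' `ceil(sample_fraction * n_samples)` samples; the boundary is inclusive
#' ("or more").  Gene order is preserved and the filter is idempotent.
#'
#' @param dataset An `ExpressionDataset` of log2 ratios.
#' @param fold_threshold Fold-change cut (> 1); default 2 (two-fold).
#' @param sample_fraction Required fraction of samples (default 0.20).
#' @return The filtered `ExpressionDataset`.
#' @export
fold_change_filter <- function(dataset, fold_threshold = 2, sample_fraction = 0.20) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  if (fold_threshold <= 1) stop("fold_threshold must exceed 1")
  if (sample_fraction <= 0 || sample_fraction > 1)
    stop("sample_fraction must be in (0, 1]")
  m_cut <- log2(fold_threshold)
  need <- ceiling(sample_fraction * ncol(dataset$values))
  keep <- rowSums(abs(dataset$values) >= m_cut) >= need
  if (!any(keep))
    stop("fold-change filter removed every gene; relax fold_threshold or sample_fraction")
  subset_dataset(dataset, genes = gene_ids(dataset)[keep])
}

#' Integrate two datasets over an ortholog map
#'
#' Joins datasets from two species row-wise over ortholog pairs: the output
#' has one row per map pair whose both members are present, columns are the
#' union of the two sample sets, and gene ids are reported as
#' `"a_id|b_id"`.  One-to-many pairs are kept as separate rows.
#'
#' @param a,b `ExpressionDataset`s for the two species.
#' @param map A `HomologMap` with ids of `a` in the first column.
#' @return The integrated `ExpressionDataset`; labels (when present on both
#'   inputs) are concatenated.
#' @export
map_orthologs <- function(a, b, map) {
  stopifnot(inherits(a, "ExpressionDataset"), inherits(b, "ExpressionDataset"),
            inherits(map, "HomologMap"))
  present <- map$species_a %in% gene_ids(a) & map$species_b %in% gene_ids(b)
  pairs <- map[present, , drop = FALSE]
  if (nrow(pairs) == 0) stop("no ortholog pair present in both datasets")
  dup <- intersect(sample_ids(a), sample_ids(b))
  if (length(dup))
    stop("sample ids shared between datasets: ", paste(utils::head(dup, 5), collapse = ", "))
  values <- cbind(a$values[pairs$species_a, , drop = FALSE],
                  b$values[pairs$species_b, , drop = FALSE])
  rownames(values) <- paste0(pairs$species_a, "|", pairs$species_b)
  if (anyDuplicated(rownames(values)))
    values <- values[!duplicated(rownames(values)), , drop = FALSE]
  labels <- NULL
  if (!is.null(a$labels) && !is.null(b$labels)) labels <- c(a$labels, b$labels)
  expression_dataset(values, labels)
}

#' Moving-average smoothing specification
#'
#' @param window Window length in samples (default 4, one disease stage).
#' @param weights Optional non-negative weights of length `window` summing to
#'   1; default uniform.
#' @return An object of class `SmoothingSpec`.
#' @export
smoothing_spec <- function(window = 4L, weights = NULL) {
  window <- as.integer(window)
  if (window < 1) stop("window must be >= 1")
  if (!is.null(weights)) {
    if (length(weights) != window) stop("weights length must equal window")
    if (any(weights < 0)) stop("weights must be non-negative")
    if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  }
  structure(list(window = window, weights = weights), class = "SmoothingSpec")
}

#' Weighted moving-average trend smoothing
#'
#' Treats each gene's expression along the supplied stage ordering as a time
#' series and replaces it with its trend component: a centred weighted moving
#' average of length `window`.  Edge positions use the truncated window with
#' renormalized weights (no padding).  What the average removes is treated
#' as random plus cyclic variation and discarded.
#'
#' @param dataset An `ExpressionDataset`.
#' @param spec A `SmoothingSpec`.
#' @param sample_order Permutation of the sample ids in progression order;
#'   default is the current column order.
#' @return An `ExpressionDataset` of identical shape with smoothed values
#'   (original column order preserved).
#' @export
smooth_trend <- function(dataset, spec = smoothing_spec(), sample_order = NULL) {
  stopifnot(inherits(dataset, "ExpressionDataset"), inherits(spec, "SmoothingSpec"))
  ids <- sample_ids(dataset)
  if (is.null(sample_order)) sample_order <- ids
  if (!identical(sort(sample_order), sort(ids)))
    stop("sample_order must be a permutation of the dataset's sample ids")
  n <- length(ids)
  if (spec$window > n) stop("window exceeds the number of samples")
  w <- if (is.null(spec$weights)) rep(1 / spec$window, spec$window) else spec$weights

  x <- dataset$values[, sample_order, drop = FALSE]
  # centred window: offsets for window k are -floor((k-1)/2) .. +ceiling((k-1)/2)
  offs <- seq_len(spec$window) - 1L - (spec$window - 1L) %/% 2L
  out <- matrix(0, nrow(x), n, dimnames = dimnames(x))
  for (j in seq_len(n)) {
    pos <- j + offs
    ok <- pos >= 1 & pos <= n
    wj <- w[ok] / sum(w[ok])
    out[, j] <- x[, pos[ok], drop = FALSE] %*% wj
  }
  out <- out[, ids, drop = FALSE]
  expression_dataset(out, dataset$labels)
}
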