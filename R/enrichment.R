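#' Upper-tail hypergeometric p-value
#'
#' P(X >= overlap) for the overlap between a selected gene subset and a gene
#' set drawn from a finite universe.
#'
#' @param overlap Observed overlap count.
#' @param subset_size Size of the selected subset.
#' @param set_size_in_universe Members of the gene set present in the
#'   universe.
#' @param universe_size Total genes in the universe.
#' @return p in (0, 1\].
#' @export
hypergeometric_p <- function(overlap, subset_size, set_size_in_universe, universe_size) {
  if (overlap < 0 || subset_size < 0 || set_size_in_universe < 0 || universe_size <= 0)
    stop("counts must be non-negative and universe positive")
  if (overlap > min(subset_size, set_size_in_universe))
    stop("overlap exceeds subset or set size")
  if (subset_size > universe_size || set_size_in_universe > universe_size)
    stop("subset or set larger than the universe")
  if (overlap == 0) return(1)
  stats::phyper(overlap - 1, set_size_in_universe,
                universe_size - set_size_in_universe, subset_size,
                lower.tail = FALSE)
}

#' Gene sets over-represented in a selected subset
#'
#' One upper-tail hypergeometric test per set (membership intersected with
#' the universe); sets with p < alpha are returned sorted ascending by p.
#' No multiple-testing correction is applied by default; `adjust = "BH"`
#' switches the cut to Benjamini-Hochberg-adjusted p-values.
#'
#' @param subset Gene ids, a subset of `universe`.
#' @param collection A `GeneSetCollection`.
#' @param universe Character vector of all candidate gene ids.
#' @param alpha Significance level (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Data frame with columns `set_name`, `overlap`, `p` (and
#'   `p_adjusted` when adjusting), sorted by p.
#' @export
enrich_subset <- function(subset, collection, universe, alpha = 0.05,
                          adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (!length(universe)) stop("empty gene universe")
  extra <- setdiff(subset, universe)
  if (length(extra))
    stop("subset gene(s) outside the universe: ", paste(utils::head(extra, 5), collapse = ", "))
  res <- enrich_all(subset, collection, universe)
  keep <- if (adjust == "BH") {
    res$p_adjusted <- stats::p.adjust(res$p, "BH")
    res$p_adjusted < alpha
  } else res$p < alpha
  res <- res[keep, , drop = FALSE]
  res[order(res$p, res$set_name), , drop = FALSE]
}

# p-value for every set, unfiltered.
enrich_all <- function(subset, collection, universe) {
  subset <- intersect(subset, universe)
  rows <- lapply(names(collection$sets), function(nm) {
    members <- intersect(collection$sets[[nm]], universe)
    ov <- length(intersect(subset, members))
    p <- if (length(members) == 0) 1
         else hypergeometric_p(ov, length(subset), length(members), length(universe))
    data.frame(set_name = nm, overlap = ov, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(set_name = character(0), overlap = integer(0),
                                      p = numeric(0))
  rownames(out) <- NULL
  out
}

#' Pathway-frequency signature across selection runs
#'
#' For each gene set, records the enrichment p-value in every run, its mean
#' and standard deviation, and the frequency: the number of runs in which
#' the set was significant at `alpha`.  Sets never significant are omitted.
#'
#' @param run_subsets List of gene-id vectors (one per selection run).
#' @param collection A `GeneSetCollection`.
#' @param universe Character vector of candidate gene ids.
#' @param alpha Significance level (default 0.05).
#' @return An object of class `PathwaySignature`: a data frame with columns
#'   `set_name`, `mean_p`, `sd_p`, `frequency`, plus a `p_matrix` attribute
#'   (sets x runs).
#' @export
pathway_signature <- function(run_subsets, collection, universe, alpha = 0.05) {
  if (!length(run_subsets)) stop("need >= 1 run")
  pmat <- vapply(run_subsets, function(s) enrich_all(s, collection, universe)$p,
                 numeric(length(collection$sets)))
  pmat <- matrix(pmat, nrow = length(collection$sets),
                 dimnames = list(names(collection$sets), NULL))
  freq <- rowSums(pmat < alpha)
  keep <- freq > 0
  out <- data.frame(set_name = rownames(pmat)[keep],
                    mean_p = rowMeans(pmat[keep, , drop = FALSE]),
                    sd_p = apply(pmat[keep, , drop = FALSE], 1, function(x)
                      if (length(x) > 1) stats::sd(x) else 0),
                    frequency = as.integer(freq[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$frequency, out$mean_p, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "p_matrix") <- pmat
  class(out) <- c("PathwaySignature", "data.frame")
  out
}
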