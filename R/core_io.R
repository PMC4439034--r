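#' Construct an expression dataset
#'
#' The universal currency of the pipeline: a genes x samples matrix of log2
#' expression ratios (M values) with optional per-sample class labels
#' (disease stage or tumor subtype).
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).  All values must be finite.
#' @param labels Optional named character vector mapping every sample id to a
#'   class label; at least two distinct classes are required when given.
#' @return An object of class `ExpressionDataset` with elements `values` and
#'   `labels`.
#' @export
expression_dataset <- function(values, labels = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite value at gene '%s', sample '%s'",
                 rownames(values)[bad[1]], colnames(values)[bad[2]]))
  }
  if (!is.null(labels)) {
    labels <- vapply(labels, as.character, character(1))
    if (is.null(names(labels)) ||
        !setequal(names(labels), colnames(values)) ||
        length(labels) != ncol(values))
      stop("`labels` must name every sample exactly once")
    labels <- labels[colnames(values)]
    if (length(unique(labels)) < 2)
      stop("labels must contain at least two classes")
  }
  structure(list(values = values, labels = labels), class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset: %d genes x %d samples", nrow(x$values), ncol(x$values)))
  if (!is.null(x$labels))
    cat(sprintf("; classes: %s", paste(names(table(x$labels)), collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' @export
dim.ExpressionDataset <- function(x) dim(x$values)

#' Gene and sample identifiers of a dataset
#' @param dataset An `ExpressionDataset`.
#' @return Character vector of ids.
#' @export
gene_ids <- function(dataset) rownames(dataset$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(dataset) colnames(dataset$values)

#' Subset an expression dataset
#'
#' @param dataset An `ExpressionDataset`.
#' @param genes Optional character vector of gene ids to keep (order kept).
#' @param samples Optional character vector of sample ids to keep.
#' @return The subsetted `ExpressionDataset`.
#' @export
subset_dataset <- function(dataset, genes = NULL, samples = NULL) {
  v <- dataset$values
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(v))
    if (length(missing))
      stop("unknown gene ids: ", paste(utils::head(missing, 5), collapse = ", "))
    v <- v[genes, , drop = FALSE]
  }
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(v))
    if (length(missing))
      stop("unknown sample ids: ", paste(utils::head(missing, 5), collapse = ", "))
    v <- v[, samples, drop = FALSE]
  }
  labels <- dataset$labels
  if (!is.null(labels)) labels <- labels[colnames(v)]
  structure(list(values = v, labels = labels), class = "ExpressionDataset")
}

#' Read an expression matrix (and optional labels) from TSV
#'
#' The canonical format is tab-separated UTF-8 with '.' as decimal mark: a
#' header row of sample ids, first column gene ids, one gene per row.
#' Duplicate gene rows (multiple probes per gene) are collapsed by the
#' arithmetic mean of their values.
#'
#' @param path Path to the expression TSV.
#' @param labels_path Optional path to a two-column TSV (sample_id, label).
#' @return An `ExpressionDataset`.
#' @export
read_expression <- function(path, labels_path = NULL) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", quote = "")
  if (ncol(raw) < 2) stop("malformed header in ", path, ": need gene-id column plus >=1 sample")
  genes <- raw[[1]]
  samples <- colnames(raw)[-1]
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell '%s' for gene '%s', sample '%s'",
                 vals[bad[1], bad[2]], genes[bad[1]], samples[bad[2]]))
  }
  collapsed <- collapse_duplicate_genes(genes, num)
  rownames(collapsed) <- attr(collapsed, "gene_ids")
  colnames(collapsed) <- samples
  labels <- NULL
  if (!is.null(labels_path)) {
    lab <- utils::read.delim(labels_path, header = TRUE, sep = "\t",
                             colClasses = "character", quote = "")
    if (ncol(lab) < 2) stop("labels file must have columns sample_id, label")
    unknown <- setdiff(lab[[1]], samples)
    if (length(unknown))
      stop("label for unknown sample: ", paste(unknown, collapse = ", "))
    labels <- stats::setNames(lab[[2]], lab[[1]])
  }
  expression_dataset(collapsed, labels)
}

# Mean-collapse rows sharing a gene id; first-appearance order is kept, so the
# result is invariant to the order of the duplicated rows themselves.
collapse_duplicate_genes <- function(genes, values) {
  ord <- unique(genes)
  if (length(ord) == length(genes)) {
    out <- values
  } else {
    out <- rowsum(values, group = genes, reorder = FALSE) /
      as.vector(table(factor(genes, levels = unique(genes))))
  }
  attr(out, "gene_ids") <- ord
  out
}

#' Write an expression dataset (and optional labels) to TSV
#'
#' @param dataset An `ExpressionDataset`.
#' @param path Output path for the matrix TSV.
#' @param labels_path Optional output path for the labels TSV.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(dataset, path, labels_path = NULL) {
  df <- data.frame(gene_id = gene_ids(dataset),
                   dataset$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(labels_path)) {
    if (is.null(dataset$labels)) stop("dataset has no labels to write")
    utils::write.table(
      data.frame(sample_id = names(dataset$labels), label = unname(dataset$labels)),
      labels_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (set name -> member gene ids).
#' @param descriptions Optional named character vector of free-text
#'   descriptions, one per set.
#' @return An object of class `GeneSetCollection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (length(sets) && is.null(names(sets))) stop("sets must be named")
  if (anyDuplicated(names(sets))) stop("duplicate set names")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (any(lengths(sets) == 0) && length(sets)) stop("empty gene set")
  if (is.null(descriptions)) descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  structure(list(sets = sets, descriptions = descriptions), class = "GeneSetCollection")
}

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT dialect: per line, set name, description, then tab-separated
#' member ids.  Duplicated members within a line are stored once.
#'
#' @param path Path to the GMT file.
#' @return A `GeneSetCollection`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop(sprintf("GMT line %d has %d fields; need name, description, >=1 member",
                   i, length(fields)))
    sets[[fields[1]]] <- unique(fields[-(1:2)])
    desc[fields[1]] <- fields[2]
  }
  gene_set_collection(sets, desc)
}

#' Write a gene-set collection to GMT
#' @param collection A `GeneSetCollection`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Construct an ortholog (homolog) map
#'
#' @param species_a Character vector of gene ids in the first species.
#' @param species_b Character vector of paired gene ids in the second species.
#' @return An object of class `HomologMap` (a two-column data frame).
#' @export
homolog_map <- function(species_a, species_b) {
  if (length(species_a) != length(species_b)) stop("id vectors must have equal length")
  if (any(!nzchar(species_a)) || any(!nzchar(species_b))) stop("empty gene id in map")
  pairs <- data.frame(species_a = as.character(species_a),
                      species_b = as.character(species_b),
                      stringsAsFactors = FALSE)
  pairs <- pairs[!duplicated(pairs), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(pairs, class = c("HomologMap", "data.frame"))
}

#' Read a two-column ortholog map from TSV
#' @param path Path to a TSV with a header and two id columns.
#' @return A `HomologMap`.
#' @export
read_homolog_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "")
  if (ncol(df) < 2) stop("ortholog map needs two columns")
  homolog_map(df[[1]], df[[2]])
}

#' Construct a survival table
#'
#' @param sample_id Character vector of unique sample ids.
#' @param time Non-negative follow-up times (days).
#' @param event Event indicator: 1 = death observed, 0 = censored.
#' @param group Optional cluster/subtype label per sample.
#' @return An object of class `SurvivalTable` (a data frame).
#' @export
survival_table <- function(sample_id, time, event, group = NULL) {
  if (anyDuplicated(sample_id)) stop("duplicate sample ids in survival table")
  if (any(time < 0)) stop("negative survival time")
  if (!all(event %in% c(0, 1))) stop("event must be 0 (censored) or 1 (death)")
  df <- data.frame(sample_id = as.character(sample_id),
                   time = as.numeric(time), event = as.integer(event),
                   stringsAsFactors = FALSE)
  if (!is.null(group)) df$group <- as.character(group)
  structure(df, class = c("SurvivalTable", "data.frame"))
}

#' Read a survival table from TSV
#' @param path TSV with header columns sample_id, time, event and optionally
#'   group.
#' @return A `SurvivalTable`.
#' @export
read_survival_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "")
  survival_table(df$sample_id, df$time, df$event,
                 group = if ("group" %in% names(df)) df$group else NULL)
}

#' Write a survival table to TSV
#' @param table A `SurvivalTable`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_survival_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Global pipeline configuration
#'
#' Collects the constants shared across the pipeline: resampling folds, the
#' fold-change prefilter, significance levels for enrichment and DEG
#' filtering, the AU support highlight threshold and the smoothing window.
#'
#' @param random_seed Integer master seed; all per-stage randomness is
#'   derived deterministically from it.
#' @param n_folds External cross-validation folds (default 5).
#' @param fold_threshold Fold-change prefilter threshold (default 2, i.e.
#'   two-fold regulation = |M| >= 1).
#' @param sample_fraction Fraction of samples that must pass the fold-change
#'   cut (default 0.20).
#' @param alpha_enrich Significance level for pathway enrichment (default 0.05).
#' @param alpha_deg Significance level for the DEG t filter (default 0.001).
#' @param au_highlight AU support threshold for highlighting clusters
#'   (default 0.95).
#' @param smoothing_window Moving-average window in samples (default 4, one
#'   disease stage).
#' @param methods Character vector of selection method ids (see
#'   [selection_methods()]).
#' @param evaluator Evaluator id (see [make_evaluator()]).
#' @return An object of class `PipelineConfig`.
#' @export
pipeline_config <- function(random_seed = 1L, n_folds = 5L, fold_threshold = 2,
                            sample_fraction = 0.20, alpha_enrich = 0.05,
                            alpha_deg = 0.001, au_highlight = 0.95,
                            smoothing_window = 4L,
                            methods = c("ftest", "mrmr"),
                            evaluator = "wrapper_svm") {
  stopifnot(n_folds >= 2, sample_fraction > 0, sample_fraction <= 1,
            alpha_enrich > 0, alpha_enrich < 1, alpha_deg > 0, alpha_deg < 1,
            au_highlight > 0, au_highlight <= 1, smoothing_window >= 1,
            fold_threshold > 1)
  structure(list(random_seed = as.integer(random_seed), n_folds = as.integer(n_folds),
                 fold_threshold = fold_threshold, sample_fraction = sample_fraction,
                 alpha_enrich = alpha_enrich, alpha_deg = alpha_deg,
                 au_highlight = au_highlight, smoothing_window = as.integer(smoothing_window),
                 methods = methods, evaluator = evaluator),
            class = "PipelineConfig")
}

# Deterministic sub-seed for a named stage, so that a full pipeline is
# replayable and any stage can be re-run in isolation.  Kept below 2^31.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

log_stage <- function(stage, ..., seed = NULL) {
  msg <- paste0("[", stage, "] ", sprintf(...))
  if (!is.null(seed)) msg <- paste0(msg, " (seed=", seed, ")")
  message(msg)
}
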