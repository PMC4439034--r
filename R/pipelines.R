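#' Run the progression-signature pipeline
#'
#' End-to-end discovery of a staged-disease signature: fold-change
#' prefilter, optional moving-average smoothing, external k-fold selection
#' per configured method, per-method stability reports, cross-method
#' frequency aggregation, pathway enrichment of every selection run, and
#' AU-supported hierarchical clustering of the samples on the ensemble
#' subset.
#'
#' @param config A named list (or path to a YAML file) with entries:
#'   `expression` (path or `ExpressionDataset`), `labels` (path, when
#'   `expression` is a path), `genesets` (path or `GeneSetCollection`,
#'   optional), `seed`, `n_folds`, `fold_threshold`, `sample_fraction`,
#'   `alpha_enrich`, `smoothing` (list: `enabled`, `window`,
#'   `sample_order`), `methods`, `evaluator` (optional id), `max_iter`,
#'   `n_boot`, `au_highlight`.
#' @param out_dir Optional output directory; when given, a deterministic
#'   `report.json`, TSV side files and a `manifest.json` (timings, file
#'   list) are written.
#' @return The report: a named list with `filtered_genes`, per-method
#'   stability reports, `ensemble`, `pathways`, `cluster`, `highlights`.
#' @export
run_progression_pipeline <- function(config, out_dir = NULL) {
  t0 <- Sys.time()
  cfg <- load_config(config, defaults = list(
    seed = 1L, n_folds = 5L, fold_threshold = 2, sample_fraction = 0.20,
    alpha_enrich = 0.05, methods = c("ftest", "mrmr"), evaluator = NULL,
    max_iter = 25L, n_boot = 1000L, au_highlight = 0.95,
    smoothing = list(enabled = FALSE, window = 4L, sample_order = NULL)))
  timings <- list()
  tic <- function() Sys.time()
  toc <- function(start, stage) timings[[stage]] <<- as.numeric(Sys.time() - start, units = "secs")

  s <- tic()
  dataset <- if (inherits(cfg$expression, "ExpressionDataset")) cfg$expression
             else read_expression(cfg$expression, cfg$labels)
  if (is.null(dataset$labels)) stop("progression pipeline needs class labels")
  genesets <- NULL
  if (!is.null(cfg$genesets))
    genesets <- if (inherits(cfg$genesets, "GeneSetCollection")) cfg$genesets
                else read_gmt(cfg$genesets)
  toc(s, "load")

  s <- tic()
  log_stage("filter", "fold-change >= %g in %g%% of samples",
            cfg$fold_threshold, 100 * cfg$sample_fraction)
  dataset <- fold_change_filter(dataset, cfg$fold_threshold, cfg$sample_fraction)
  if (isTRUE(cfg$smoothing$enabled)) {
    log_stage("smooth", "window %d", cfg$smoothing$window)
    dataset <- smooth_trend(dataset, smoothing_spec(cfg$smoothing$window),
                            cfg$smoothing$sample_order)
  }
  toc(s, "preprocess")

  s <- tic()
  reports <- list()
  for (m in cfg$methods) {
    log_stage("select", "method %s, %d-fold external CV", m, cfg$n_folds,
              seed = cfg$seed)
    reports[[m]] <- run_stability(dataset, dataset$labels, m,
                                  evaluator = cfg$evaluator, k = cfg$n_folds,
                                  seed = derive_seed(cfg$seed, m),
                                  max_iter = cfg$max_iter)
  }
  toc(s, "selection")

  s <- tic()
  ensemble <- if (length(reports) >= 2) {
    cross_method_aggregate(reports, dataset, dataset$labels,
                           evaluator = cfg$evaluator %||% "wrapper_svm",
                           seed = derive_seed(cfg$seed, "cross"))
  } else reports[[1]]
  toc(s, "ensemble")

  pathways <- NULL
  if (!is.null(genesets)) {
    s <- tic()
    run_subsets <- unlist(lapply(reports, `[[`, "fold_subsets"), recursive = FALSE)
    pathways <- pathway_signature(run_subsets, genesets, gene_ids(dataset),
                                  cfg$alpha_enrich)
    toc(s, "enrichment")
  }

  s <- tic()
  log_stage("cluster-boot", "%d replicates per scale", cfg$n_boot,
            seed = cfg$seed)
  cl_data <- subset_dataset(dataset, genes = ensemble$ensemble_subset)
  # correlation needs >= 2 genes; a 1-gene signature clusters on its value
  tree <- hcluster(cl_data, distance = if (nrow(cl_data$values) >= 2)
    "pearson" else "euclidean")
  tree <- bootstrap_support(cl_data, tree, n_boot = cfg$n_boot,
                            seed = derive_seed(cfg$seed, "boot"))
  highlights <- highlight_clusters(tree, cfg$au_highlight)
  toc(s, "clustering")

  report <- list(
    filtered_genes = gene_ids(dataset),
    methods = lapply(reports, report_summary),
    ensemble = report_summary(ensemble),
    pathways = pathways,
    cluster = cluster_tree_table(tree),
    highlights = highlights)

  if (!is.null(out_dir))
    write_pipeline_outputs(report, cfg, out_dir, timings, t0,
                           frequencies = ensemble$frequencies,
                           pathways = pathways)
  invisible(report)
}

report_summary <- function(r) {
  list(method = r$method,
       fold_subsets = lapply(r$fold_subsets, as.character),
       per_fold_errors = r$per_fold_errors,
       nahd = r$nahd, ahd_raw = r$ahd_raw,
       frequencies = as.list(r$frequencies),
       ensemble_subset = as.character(r$ensemble_subset),
       ensemble_error = r$ensemble_error)
}

#' Run the survival-signature pipeline
#'
#' Builds a prognostic signature from a training dataset whose samples carry
#' subtype labels: two-sample t DEG filter between the two subtypes,
#' external k-fold selection with the configured methods, cross-method
#' frequency aggregation, and validation on an independent dataset by
#' signature-gene clustering plus the log-rank test.
#'
#' @param config A named list (or YAML path) with entries: `training`
#'   (`ExpressionDataset` with two-class subtype labels, or path),
#'   `training_labels` (path), `validation` (`ExpressionDataset` or path),
#'   `survival` (`SurvivalTable` or path), `alpha_deg` (default 0.001),
#'   `methods` (default gs1, gs2, ftest, rfe_svm, mrmr), `evaluator`,
#'   `n_folds`, `max_iter`, `n_clusters` (default 3), `alpha` (default
#'   0.05), `seed`.
#' @param out_dir Optional output directory (as in
#'   [run_progression_pipeline()]).
#' @return List with `degs`, per-method reports, `signature` (the ensemble
#'   `StabilityReport`) and `validation` (see [validate_signature()]).
#' @export
run_survival_pipeline <- function(config, out_dir = NULL) {
  t0 <- Sys.time()
  cfg <- load_config(config, defaults = list(
    alpha_deg = 0.001, methods = c("gs1", "gs2", "ftest", "rfe_svm", "mrmr"),
    evaluator = NULL, n_folds = 5L, max_iter = 25L, n_clusters = 3L,
    alpha = 0.05, seed = 1L))
  timings <- list()

  training <- if (inherits(cfg$training, "ExpressionDataset")) cfg$training
              else read_expression(cfg$training, cfg$training_labels)
  if (is.null(training$labels) || length(unique(training$labels)) != 2)
    stop("training data needs exactly two subtype labels")
  validation <- if (inherits(cfg$validation, "ExpressionDataset")) cfg$validation
                else read_expression(cfg$validation)
  surv_tab <- if (inherits(cfg$survival, "SurvivalTable")) cfg$survival
              else read_survival_table(cfg$survival)

  s <- Sys.time()
  cls <- unique(training$labels)
  degs <- t_test_deg(training,
                     names(training$labels)[training$labels == cls[1]],
                     names(training$labels)[training$labels == cls[2]],
                     alpha = cfg$alpha_deg)
  log_stage("deg", "%d DEGs at p < %g", nrow(degs), cfg$alpha_deg)
  if (nrow(degs) < 2) stop("fewer than 2 DEGs; relax alpha_deg")
  train_deg <- subset_dataset(training, genes = degs$gene_id)
  timings$deg <- as.numeric(Sys.time() - s, units = "secs")

  s <- Sys.time()
  reports <- list()
  for (m in cfg$methods) {
    log_stage("select", "method %s", m, seed = cfg$seed)
    reports[[m]] <- run_stability(train_deg, train_deg$labels, m,
                                  evaluator = cfg$evaluator, k = cfg$n_folds,
                                  seed = derive_seed(cfg$seed, m),
                                  max_iter = cfg$max_iter)
  }
  timings$selection <- as.numeric(Sys.time() - s, units = "secs")

  s <- Sys.time()
  signature <- if (length(reports) >= 2) {
    cross_method_aggregate(reports, train_deg, train_deg$labels,
                           evaluator = cfg$evaluator %||% "wrapper_svm",
                           seed = derive_seed(cfg$seed, "cross"))
  } else reports[[1]]
  timings$ensemble <- as.numeric(Sys.time() - s, units = "secs")

  s <- Sys.time()
  validation_res <- validate_signature(signature$ensemble_subset, validation,
                                       surv_tab, cfg$n_clusters, cfg$alpha)
  log_stage("validate", "log-rank chi2 = %.3f, p = %.4g",
            validation_res$logrank$chi_square, validation_res$logrank$p)
  timings$validation <- as.numeric(Sys.time() - s, units = "secs")

  report <- list(degs = degs,
                 methods = lapply(reports, report_summary),
                 signature = report_summary(signature),
                 validation = list(
                   assignment = as.list(validation_res$assignment),
                   chi_square = validation_res$logrank$chi_square,
                   df = validation_res$logrank$df,
                   p = validation_res$logrank$p,
                   significant = validation_res$significant,
                   genes_used = validation_res$genes_used))
  if (!is.null(out_dir))
    write_pipeline_outputs(report, cfg, out_dir, timings, t0,
                           frequencies = signature$frequencies)
  invisible(report)
}

load_config <- function(config, defaults) {
  if (is.character(config) && length(config) == 1) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML path")
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  if (is.list(defaults$smoothing) && is.list(config$smoothing))
    for (nm in names(defaults$smoothing))
      if (is.null(config$smoothing[[nm]])) config$smoothing[[nm]] <- defaults$smoothing[[nm]]
  config
}

# Deterministic JSON (sorted keys, full precision) plus TSV side files; the
# manifest carries timings and the file list and is the only
# non-reproducible output.
write_pipeline_outputs <- function(report, cfg, out_dir, timings, t0,
                                   frequencies = NULL, pathways = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(strip_for_json(report), report_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, report_path)
  if (!is.null(frequencies)) {
    p <- file.path(out_dir, "gene_frequencies.tsv")
    utils::write.table(data.frame(gene = names(frequencies),
                                  frequency = as.numeric(frequencies)),
                       p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(pathways)) {
    p <- file.path(out_dir, "pathway_signature.tsv")
    utils::write.table(as.data.frame(pathways)[, c("set_name", "mean_p", "sd_p", "frequency")],
                       p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  manifest <- list(seed = cfg$seed,
                   version = as.character(utils::packageVersion("sigselect")),
                   timings_sec = timings,
                   elapsed_sec = as.numeric(Sys.time() - t0, units = "secs"),
                   outputs = paths)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

# Drop attributes/classes jsonlite would serialize unstably.
strip_for_json <- function(x) {
  if (is.data.frame(x)) {
    attr(x, "p_matrix") <- NULL
    class(x) <- "data.frame"
    return(x)
  }
  if (is.list(x)) {
    nms <- names(x)
    x <- lapply(x, strip_for_json)
    names(x) <- nms
    return(x)
  }
  if (is.null(x)) return(x)
  unname(unclass(x))
}
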