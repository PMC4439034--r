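#' Differentially expressed genes by two-sample t test
#'
#' Per gene, a two-sided two-sample t test (pooled variance by default)
#' between two sample groups; genes with p < alpha are returned sorted by
#' p.  A gene with zero pooled variance and zero mean difference gets
#' p = 1.
#'
#' @param dataset An `ExpressionDataset`.
#' @param groupA,groupB Disjoint sample-id vectors (each >= 2).
#' @param alpha Significance level (default 0.001).
#' @param welch Use Welch's unequal-variance t instead of the pooled test.
#' @return Data frame with columns `gene_id`, `t`, `p` (p < alpha only).
#' @export
t_test_deg <- function(dataset, groupA, groupB, alpha = 0.001, welch = FALSE) {
  if (length(groupA) < 2 || length(groupB) < 2)
    stop("both groups need >= 2 samples")
  if (length(intersect(groupA, groupB))) stop("groups overlap")
  xa <- dataset$values[, groupA, drop = FALSE]
  xb <- dataset$values[, groupB, drop = FALSE]
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- apply(xa, 1, stats::var); vb <- apply(xb, 1, stats::var)
  if (welch) {
    se2 <- va / na + vb / nb
    tstat <- (ma - mb) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    tstat <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(tstat))
  }
  degenerate <- !is.finite(tstat)
  tstat[degenerate] <- 0
  p <- 2 * stats::pt(-abs(tstat), df)
  p[degenerate] <- 1
  out <- data.frame(gene_id = gene_ids(dataset), t = tstat, p = p,
                    stringsAsFactors = FALSE)
  out <- out[out$p < alpha, , drop = FALSE]
  out <- out[order(out$p, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Kaplan-Meier survival curve
#'
#' The product-limit estimator S(t) for one group of a survival table.
#' Ties between events and censorings at the same time follow the standard
#' convention (events first).
#'
#' @param table A `SurvivalTable`.
#' @param group Optional group label; default uses all rows.
#' @return An object of class `KmCurve`: data frame with columns `time`
#'   (starting at 0), `surv`, `n_risk`, `n_event`, `group`.
#' @export
kaplan_meier <- function(table, group = NULL) {
  rows <- if (is.null(group)) table else table[table$group == group, , drop = FALSE]
  if (!nrow(rows)) stop("empty group")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = rows)
  out <- data.frame(time = c(0, fit$time),
                    surv = c(1, fit$surv),
                    n_risk = c(nrow(rows), fit$n.risk),
                    n_event = c(0, fit$n.event),
                    group = if (is.null(group)) "all" else group,
                    stringsAsFactors = FALSE)
  class(out) <- c("KmCurve", "data.frame")
  out
}

#' Log-rank test across survival groups
#'
#' The standard log-rank statistic: at each distinct event time, observed
#' minus expected events per group under the hypergeometric model;
#' chi-square with (groups - 1) degrees of freedom.
#'
#' @param table A `SurvivalTable` with a `group` column (or `groups`
#'   supplied).
#' @param groups Optional group labels overriding the table's column.
#' @return List with `chi_square`, `df`, `p`.
#' @export
logrank_test <- function(table, groups = NULL) {
  g <- groups %||% table$group
  if (is.null(g)) stop("no group assignment")
  g <- as.character(g)
  if (length(unique(g)) < 2) stop("need >= 2 non-empty groups")
  if (sum(table$event) == 0) stop("no events observed; log-rank undefined")
  df_data <- data.frame(time = table$time, event = table$event, group = g)
  sd_fit <- tryCatch(
    survival::survdiff(survival::Surv(time, event) ~ group, data = df_data),
    error = function(e) stop("log-rank test failed: ", conditionMessage(e)))
  df <- length(unique(g)) - 1
  chi <- unname(sd_fit$chisq)
  list(chi_square = chi, df = df,
       p = stats::pchisq(chi, df, lower.tail = FALSE))
}

#' Validate a survival signature on an independent dataset
#'
#' Subsets the independent expression data to the signature genes present,
#' clusters the samples (complete-linkage, Pearson distance) cut at
#' `n_clusters`, and tests for survival differences across the resulting
#' clusters with the log-rank test; Kaplan-Meier curves are returned per
#' cluster.
#'
#' @param signature Character vector of gene ids (>= 1 must be present).
#' @param dataset Independent `ExpressionDataset`.
#' @param table `SurvivalTable` covering the dataset's samples.
#' @param n_clusters Number of subtypes to cut (default 3).
#' @param alpha Significance level reported alongside the attained p.
#' @return List with `assignment` (named cluster labels), `logrank`,
#'   `curves` (list of `KmCurve`), `genes_used`, `alpha`, `significant`.
#' @export
validate_signature <- function(signature, dataset, table, n_clusters = 3L,
                               alpha = 0.05) {
  present <- intersect(signature, gene_ids(dataset))
  if (!length(present)) stop("no signature gene present in the dataset")
  missing <- setdiff(sample_ids(dataset), table$sample_id)
  if (length(missing))
    stop("survival data missing for sample(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  values <- dataset$values[present, , drop = FALSE]
  distance <- if (length(present) < 2) "euclidean" else "pearson"
  d <- stats::as.dist(sample_distances(values, distance))
  hc <- stats::hclust(d, method = "complete")
  assignment <- stats::setNames(paste0("C", stats::cutree(hc, k = n_clusters)),
                                hc$labels)
  tab <- table[match(names(assignment), table$sample_id), , drop = FALSE]
  tab$group <- unname(assignment)
  if (all(table(tab$group) < 2))
    stop("every cluster is a singleton; reduce n_clusters")
  lr <- logrank_test(tab)
  curves <- lapply(sort(unique(tab$group)), function(gr) kaplan_meier(tab, gr))
  names(curves) <- sort(unique(tab$group))
  list(assignment = assignment, logrank = lr, curves = curves,
       genes_used = present, alpha = alpha, significant = lr$p < alpha)
}
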