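#' Specify a synthetic microarray-style study
#'
#' Describes the statistical structure the analysis pipeline assumes: an
#' ordered multi-stage class design with monotone "progression" genes,
#' correlated redundant gene blocks, pathway collections enriched for the
#' planted genes, and two latent tumor subtypes with different survival
#' hazards.  Values are log2 ratios (M values) with Gaussian noise.
#'
#' @param n_genes Total number of genes.
#' @param n_samples_per_class Samples per disease stage.
#' @param classes Ordered character vector of stage labels (progression order).
#' @param n_informative Number of planted signature genes.
#' @param effect_size Mean log2 shift per stage step for planted genes.
#' @param n_redundant_blocks Number of correlated blocks (noisy copies of
#'   planted genes).
#' @param block_size Genes per redundant block.
#' @param block_correlation Target within-block Pearson correlation.
#' @param noise_sd Standard deviation of Gaussian noise on M values.
#' @param n_pathways Number of gene sets to generate.
#' @param pathway_size Members per (non-planted) gene set.
#' @param enriched_fraction Fraction of planted genes concentrated in the
#'   designated "true" pathways.
#' @param n_true_pathways Number of designated enriched pathways.
#' @param max_sets_per_gene Cap on set memberships per gene.
#' @param hazard_ratio Ratio of exponential event rates between latent
#'   survival subtypes.
#' @param censor_fraction Expected fraction of censored samples.
#' @param seed Integer seed; identical specs and seeds give bit-identical data.
#' @return An object of class `SimulationSpec`.
#' @export
simulation_spec <- function(n_genes = 500, n_samples_per_class = 5,
                            classes = c("normal", "steatosis", "NASH", "HCC"),
                            n_informative = 20, effect_size = 1.0,
                            n_redundant_blocks = 4, block_size = 5,
                            block_correlation = 0.8, noise_sd = 0.5,
                            n_pathways = 20, pathway_size = 20,
                            enriched_fraction = 0.8, n_true_pathways = 2,
                            max_sets_per_gene = 3,
                            hazard_ratio = 4, censor_fraction = 0.2,
                            seed = 1L) {
  spec <- structure(as.list(environment()), class = "SimulationSpec")
  if (spec$n_informative + spec$n_redundant_blocks * spec$block_size > spec$n_genes)
    stop("infeasible spec: n_informative + n_redundant_blocks*block_size > n_genes")
  if (spec$effect_size < 0) stop("effect_size must be non-negative")
  if (spec$block_correlation < 0 || spec$block_correlation >= 1)
    stop("block_correlation must be in [0, 1)")
  if (spec$hazard_ratio <= 0) stop("hazard_ratio must be positive")
  if (spec$censor_fraction < 0 || spec$censor_fraction >= 1)
    stop("censor_fraction must be in [0, 1)")
  if (spec$n_redundant_blocks > 0 && spec$n_informative == 0)
    stop("redundant blocks need at least one informative source gene")
  if (length(spec$classes) < 2) stop("need at least two ordered classes")
  spec$seed <- as.integer(spec$seed)
  spec
}

#' Generate a staged-progression expression dataset
#'
#' Planted informative genes have class means stepping monotonically by
#' `effect_size` across the ordered stages (random up/down direction per
#' gene); redundant blocks are noisy copies of randomly chosen informative
#' genes with approximately `block_correlation` Pearson correlation; all
#' remaining genes are pure noise N(0, noise_sd^2).  Gene order is shuffled
#' so position carries no information.
#'
#' @param spec A `SimulationSpec`.
#' @return A list with elements `dataset` (an `ExpressionDataset` with stage
#'   labels) and `truth` (character vector of planted informative gene ids).
#' @export
generate_progression <- function(spec) {
  stopifnot(inherits(spec, "SimulationSpec"))
  withr_seed(spec$seed, {
    n_class <- length(spec$classes)
    n_samp <- n_class * spec$n_samples_per_class
    stage_idx <- rep(seq_len(n_class) - 1L, each = spec$n_samples_per_class)
    sample_id <- paste0(rep(spec$classes, each = spec$n_samples_per_class), "_",
                        sequence(rep(spec$n_samples_per_class, n_class)))
    labels <- stats::setNames(rep(spec$classes, each = spec$n_samples_per_class),
                              sample_id)

    gene_id <- sprintf("g%05d", seq_len(spec$n_genes))
    values <- matrix(stats::rnorm(spec$n_genes * n_samp, 0, spec$noise_sd),
                     nrow = spec$n_genes,
                     dimnames = list(gene_id, sample_id))

    truth <- character(0)
    if (spec$n_informative > 0) {
      truth <- gene_id[seq_len(spec$n_informative)]
      direction <- sample(c(-1, 1), spec$n_informative, replace = TRUE)
      # centre the staircase so the grand mean of a planted gene is ~0
      centred <- stage_idx - (n_class - 1) / 2
      shift <- outer(direction * spec$effect_size, centred)
      values[truth, ] <- values[truth, , drop = FALSE] + shift
    }

    n_block_genes <- spec$n_redundant_blocks * spec$block_size
    if (n_block_genes > 0) {
      block_rows <- gene_id[spec$n_informative + seq_len(n_block_genes)]
      sources <- sample(truth, spec$n_redundant_blocks, replace = TRUE)
      rho <- spec$block_correlation
      k <- 0L
      for (b in seq_len(spec$n_redundant_blocks)) {
        src <- values[sources[b], ]
        s_sd <- stats::sd(src)
        for (j in seq_len(spec$block_size)) {
          k <- k + 1L
          values[block_rows[k], ] <-
            rho * src + sqrt(1 - rho^2) * s_sd * stats::rnorm(n_samp)
        }
      }
    }

    perm <- sample.int(spec$n_genes)
    values <- values[perm, , drop = FALSE]
    list(dataset = expression_dataset(values, labels), truth = sort(truth))
  })
}

#' Overlay two latent survival subtypes on a dataset
#'
#' Samples are split into two latent subtypes; a designated subset of genes
#' receives a mean log2 shift between subtypes; event times are exponential
#' with rates differing by `hazard_ratio` and censoring is independent
#' uniform, calibrated so the expected censored fraction equals
#' `censor_fraction`.
#'
#' @param dataset An `ExpressionDataset`.
#' @param spec A `SimulationSpec` (`hazard_ratio`, `censor_fraction`,
#'   `effect_size`, `n_informative`, `noise_sd`, `seed` are used).
#' @param subtype_genes Optional character vector of genes to shift; default
#'   draws `n_informative` genes at random.
#' @return A list with elements `dataset` (subtype-shifted expression),
#'   `table` (a `SurvivalTable` whose `group` column is the latent subtype)
#'   and `subtype_genes`.
#' @export
generate_survival <- function(dataset, spec, subtype_genes = NULL) {
  stopifnot(inherits(dataset, "ExpressionDataset"), inherits(spec, "SimulationSpec"))
  if (spec$hazard_ratio <= 0) stop("hazard_ratio must be positive")
  withr_seed(derive_seed(spec$seed, "survival"), {
    ids <- sample_ids(dataset)
    n <- length(ids)
    subtype <- stats::setNames(rep(c("A", "B"), length.out = n)[sample.int(n)], ids)

    if (is.null(subtype_genes))
      subtype_genes <- sort(sample(gene_ids(dataset),
                                   min(spec$n_informative, nrow(dataset$values))))
    values <- dataset$values
    # signature genes move in opposite directions in the two subtypes
    # (up in one, down in the other), half the effect on each side
    shift_dir <- sample(c(-1, 1), length(subtype_genes), replace = TRUE)
    is_b <- subtype[colnames(values)] == "B"
    values[subtype_genes, is_b] <- values[subtype_genes, is_b, drop = FALSE] +
      shift_dir * spec$effect_size / 2
    values[subtype_genes, !is_b] <- values[subtype_genes, !is_b, drop = FALSE] -
      shift_dir * spec$effect_size / 2

    base_rate <- 1 / 365                      # low-risk arm: mean survival 365 d
    rate <- ifelse(subtype == "B", base_rate * spec$hazard_ratio, base_rate)
    t_event <- stats::rexp(n, rate)
    if (spec$censor_fraction > 0) {
      u_max <- calibrate_censoring(c(base_rate, base_rate * spec$hazard_ratio),
                                   spec$censor_fraction)
      t_cens <- stats::runif(n, 0, u_max)
      event <- as.integer(t_event <= t_cens)
      time <- pmin(t_event, t_cens)
    } else {
      event <- rep(1L, n)
      time <- t_event
    }
    list(dataset = expression_dataset(values, dataset$labels),
         table = survival_table(ids, time, event, group = unname(subtype)),
         subtype_genes = subtype_genes)
  })
}

# For T ~ Exp(rate) and C ~ U(0, u), P(censored) = (1 - exp(-rate*u))/(rate*u).
# Solve for u so the average over arms hits the target fraction.
calibrate_censoring <- function(rates, target) {
  f <- function(u) mean((1 - exp(-rates * u)) / (rates * u)) - target
  stats::uniroot(f, lower = 1e-6, upper = 1e9, tol = 1e-10)$root
}

#' Generate a gene-set collection around planted genes
#'
#' `enriched_fraction` of the planted genes are concentrated into
#' `n_true_pathways` designated "true" sets; all remaining sets are filled by
#' uniform sampling from the rest of the universe.  No gene joins more than
#' `max_sets_per_gene` sets.
#'
#' @param truth Character vector of planted gene ids.
#' @param universe Character vector of all gene ids.
#' @param spec A `SimulationSpec`.
#' @return A `GeneSetCollection`.  True pathways are named `"true_pw_<i>"`.
#' @export
generate_genesets <- function(truth, universe, spec) {
  stopifnot(inherits(spec, "SimulationSpec"))
  if (spec$n_pathways == 0) return(gene_set_collection(list()))
  withr_seed(derive_seed(spec$seed, "genesets"), {
    n_enr <- round(spec$enriched_fraction * length(truth))
    enriched <- if (n_enr > 0) sample(truth, n_enr) else character(0)
    n_true <- if (n_enr > 0) min(spec$n_true_pathways, n_enr) else 0L

    capacity <- stats::setNames(rep(spec$max_sets_per_gene, length(universe)), universe)
    sets <- list()
    if (n_true > 0) {
      split_idx <- rep(seq_len(n_true), length.out = n_enr)
      for (i in seq_len(n_true)) {
        members <- enriched[split_idx == i]
        sets[[sprintf("true_pw_%d", i)]] <- members
        capacity[members] <- capacity[members] - 1L
      }
    }
    pool0 <- setdiff(universe, enriched)
    n_rand <- spec$n_pathways - n_true
    for (i in seq_len(max(0L, n_rand))) {
      pool <- pool0[capacity[pool0] > 0]
      size <- min(spec$pathway_size, length(pool))
      if (size == 0) break
      members <- sample(pool, size)
      sets[[sprintf("rand_pw_%d", i)]] <- members
      capacity[members] <- capacity[members] - 1L
    }
    desc <- stats::setNames(
      ifelse(grepl("^true_", names(sets)), "planted enriched pathway", "background pathway"),
      names(sets))
    gene_set_collection(sets, desc)
  })
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
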