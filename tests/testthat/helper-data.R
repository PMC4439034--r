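# Shared fixtures, all built in code.

# Small staged-progression dataset with planted signature genes.
planted_progression <- function(n_genes = 120, n_per_class = 5, n_informative = 10,
                                effect = 1.0, noise_sd = 0.5, seed = 7,
                                classes = c("normal", "steatosis", "NASH", "HCC")) {
  n_informative <- min(n_informative, max(1, n_genes %/% 3))
  blocks <- if (n_genes >= n_informative + 6) 2 else 0
  generate_progression(simulation_spec(
    n_genes = n_genes, n_samples_per_class = n_per_class, classes = classes,
    n_informative = n_informative, effect_size = effect,
    n_redundant_blocks = blocks, block_size = 3, block_correlation = 0.8,
    noise_sd = noise_sd, seed = seed))
}

# Two tight, well-separated classes driven by a single perfect gene.
perfect_separator <- function(n_per_class = 6, n_noise = 8, seed = 3) {
  set.seed(seed)
  n <- 2 * n_per_class
  vals <- matrix(rnorm(n * (n_noise + 1), 0, 0.1), nrow = n_noise + 1)
  vals[1, ] <- rep(c(-3, 3), each = n_per_class) + rnorm(n, 0, 0.05)
  rownames(vals) <- c("sep", paste0("noise", seq_len(n_noise)))
  colnames(vals) <- paste0("s", seq_len(n))
  labels <- setNames(rep(c("A", "B"), each = n_per_class), colnames(vals))
  expression_dataset(vals, labels)
}

# A tiny deterministic matrix with known structure.
tiny_dataset <- function() {
  vals <- matrix(c(0, 1, 2, 3,
                   3, 2, 1, 0,
                   1, 1, 1, 1),
                 nrow = 3, byrow = TRUE,
                 dimnames = list(c("gA", "gB", "gC"), paste0("s", 1:4)))
  expression_dataset(vals, setNames(c("x", "x", "y", "y"), paste0("s", 1:4)))
}

# Independent plug-in MI oracle from first principles (natural counts).
oracle_mi <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  total <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    pij <- tab[i, j] / n
    if (pij > 0) total <- total + pij * log2(pij / (sum(tab[i, ]) / n * sum(tab[, j]) / n))
  }
  total
}
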