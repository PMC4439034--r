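test_that("equal-frequency discretization balances bins and honors ties", {
  expect_equal(discretize(c(10, 20, 30, 40, 50, 60)), c(0L, 0L, 1L, 1L, 2L, 2L))
  expect_equal(discretize(rep(5, 8)), rep(0L, 8))
  # ties spanning a quantile: brute-force stable-sort assignment
  x <- c(2, 1, 2, 2, 3, 1)
  spec <- discretization_spec(3)
  got <- discretize(x, spec)
  ord <- order(x, seq_along(x))        # stable sort
  oracle <- integer(length(x))
  oracle[ord] <- ((seq_along(x) - 1L) * 3L) %/% length(x)
  expect_equal(got, oracle)
})

test_that("sign-threshold discretization uses the two-fold cuts", {
  spec <- discretization_spec(3, "sign_threshold")
  expect_equal(discretize(c(-2, -1, -0.5, 0, 0.5, 1, 2), spec),
               c(0L, 0L, 1L, 1L, 1L, 2L, 2L))
  expect_error(discretization_spec(4, "sign_threshold"), "3 bins")
})

test_that("mutual information reproduces hand-computed values", {
  expect_equal(mutual_information(c(0L, 0L, 0L, 0L), c(0L, 1L, 0L, 1L)), 0)
  expect_equal(mutual_information(c(0L, 0L, 1L, 1L), c(0L, 0L, 1L, 1L)), 1.0)
  expect_equal(mutual_information(c(0L, 0L, 1L, 1L), c(0L, 1L, 0L, 1L)), 0)
  expect_error(mutual_information(1:3, 1:4), "equal length")
})

test_that("MI is symmetric, non-negative, and I(x;x) = H(x) on random cases", {
  set.seed(31)
  for (i in 1:25) {
    x <- sample(0:2, 30, replace = TRUE)
    y <- sample(0:2, 30, replace = TRUE)
    expect_equal(mutual_information(x, y), mutual_information(y, x))
    expect_gte(mutual_information(x, y), 0)
    expect_equal(mutual_information(x, x), sigselect:::entropy_bits(x))
    expect_equal(mutual_information(x, y), oracle_mi(x, y))
  }
})

test_that("normalized MI matches its definition and stays in [0,1]", {
  x <- c(0L, 0L, 1L, 1L); y <- c(0L, 1L, 0L, 1L)
  expect_equal(normalized_mi(x, x), 1.0)
  expect_equal(normalized_mi(x, y), 0.0)
  expect_equal(normalized_mi(rep(0L, 6), x), 0)  # zero entropy convention
  set.seed(17)
  for (i in 1:20) {
    a <- sample(0:2, 25, replace = TRUE); b <- sample(0:1, 25, replace = TRUE)
    nmi <- normalized_mi(a, b)
    expect_gte(nmi, 0); expect_lte(nmi, 1)
    ha <- sigselect:::entropy_bits(a); hb <- sigselect:::entropy_bits(b)
    expect_equal(nmi, min(1, oracle_mi(a, b) / sqrt(ha * hb)))
  }
})

test_that("MI redundancy equals the mean of brute-force pair values", {
  set.seed(12)
  vals <- matrix(rnorm(3 * 30), 3, dimnames = list(c("a", "b", "c"), paste0("s", 1:30)))
  ds <- expression_dataset(vals)
  spec <- discretization_spec(3)
  d <- apply(vals, 1, discretize, spec = spec)
  oracle <- mean(c(oracle_mi(d[, "a"], d[, "b"]),
                   oracle_mi(d[, "a"], d[, "c"]),
                   oracle_mi(d[, "b"], d[, "c"])))
  expect_equal(mi_redundancy(c("a", "b", "c"), ds, spec), oracle)
  # duplicated gene: pair MI equals the gene entropy (maximal)
  vals2 <- rbind(vals, a2 = vals["a", ])
  ds2 <- expression_dataset(vals2)
  expect_equal(mi_redundancy(c("a", "a2"), ds2, spec),
               sigselect:::entropy_bits(d[, "a"]))
  expect_error(mi_redundancy("a", ds), "two genes")
})

test_that("two independent noise genes have near-zero redundancy at large n", {
  set.seed(99)
  vals <- matrix(rnorm(2 * 3000), 2, dimnames = list(c("a", "b"), paste0("s", 1:3000)))
  ds <- expression_dataset(vals)
  # plug-in bias bound ~ (bins-1)^2 / (2 n ln 2)
  expect_lt(mi_redundancy(c("a", "b"), ds), 3 * (3 - 1)^2 / (2 * 3000 * log(2)))
})

test_that("GO redundancy is the mean pairwise Jaccard index", {
  ann <- gene_annotation(list(g1 = c("a", "b"), g2 = c("b", "c"),
                              g3 = c("a", "b"), g4 = c("x"), g5 = character(0)))
  expect_equal(go_redundancy(c("g1", "g3"), ann), 1.0)
  expect_equal(go_redundancy(c("g1", "g4"), ann), 0.0)
  expect_equal(go_redundancy(c("g1", "g2"), ann), 1 / 3)
  expect_equal(go_redundancy(c("g5", "g5x"), ann), 0)  # both unannotated
  expect_equal(go_redundancy(c("g1", "g2", "g3"), ann),
               mean(c(1 / 3, 1, 1 / 3)))
})

test_that("univariate scores agree with textbook oracles", {
  # hand-computable one-way ANOVA, 2 classes x 3 samples
  vals <- matrix(c(1, 2, 3, 5, 6, 7), 1,
                 dimnames = list("g", paste0("s", 1:6)))
  labs <- setNames(rep(c("A", "B"), each = 3), paste0("s", 1:6))
  ds <- expression_dataset(vals, labs)
  f <- univariate_scores(ds, score_id = "f")[["g"]]
  expect_equal(f, unname(summary(aov(c(vals) ~ labs))[[1]]$`F value`[1]))
  # two classes: F equals the squared pooled t statistic
  tt <- t.test(vals[1, 1:3], vals[1, 4:6], var.equal = TRUE)$statistic
  expect_equal(f, unname(tt)^2)
  # gs1 = |mean diff| / (sd sum); gs2 = BSS/WSS
  expect_equal(univariate_scores(ds, score_id = "gs1")[["g"]], 4 / 2, tolerance = 1e-9)
  bss <- 3 * (2 - 4)^2 + 3 * (6 - 4)^2
  wss <- sum((c(1, 2, 3) - 2)^2) + sum((c(5, 6, 7) - 6)^2)
  expect_equal(univariate_scores(ds, score_id = "gs2")[["g"]], bss / wss,
               tolerance = 1e-9)
})

test_that("identical class distributions score near zero", {
  vals <- matrix(rep(c(1, 2, 3), 2), 1, dimnames = list("g", paste0("s", 1:6)))
  labs <- setNames(rep(c("A", "B"), each = 3), paste0("s", 1:6))
  ds <- expression_dataset(vals, labs)
  expect_lt(univariate_scores(ds, score_id = "f")[["g"]], 1e-6)
})

test_that("scores are invariant to sample reordering", {
  g <- planted_progression(n_genes = 30, seed = 3)
  ds <- g$dataset
  perm <- sample(sample_ids(ds))
  ds2 <- subset_dataset(ds, samples = perm)
  for (s in c("f", "gs1", "gs2"))
    expect_equal(univariate_scores(ds, score_id = s),
                 univariate_scores(ds2, score_id = s))
})
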