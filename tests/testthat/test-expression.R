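test_that("logcpm matches its closed form and is monotone in count and library", {
  cm <- tiny_counts(c(0L, 1000L), genes = c("g1", "g2"), samples = "s1")
  cm$lib_sizes <- c(s1 = 1e6)
  lc <- logcpm(cm, prior = 0.5)
  # independent arithmetic: log2((0 + .5) / (1e6 + 1) * 1e6)
  expect_equal(lc["g1", "s1"], log2(0.5 / (1e6 + 1) * 1e6), tolerance = 1e-12)
  expect_equal(lc["g1", "s1"], -1.0000014, tolerance = 1e-6)

  # doubling a large count adds ~1 on the log2 scale
  cm2 <- tiny_counts(c(1000L, 2000L), genes = c("a", "b"), samples = "s1")
  cm2$lib_sizes <- c(s1 = 1e6)
  lc2 <- logcpm(cm2)
  expect_equal(unname(diff(lc2[, 1])), 1, tolerance = 1e-3)

  # strictly increasing in count, strictly decreasing in lib size
  vals <- vapply(c(0L, 1L, 5L, 50L), function(k) {
    c1 <- tiny_counts(k, genes = "g", samples = "s")
    c1$lib_sizes <- c(s = 1e6)
    logcpm(c1)[1, 1]
  }, 0)
  expect_true(all(diff(vals) > 0))
  libs <- c(1e5, 1e6, 1e7)
  vals2 <- vapply(libs, function(L) {
    c1 <- tiny_counts(10L, genes = "g", samples = "s")
    c1$lib_sizes <- c(s = L)
    logcpm(c1)[1, 1]
  }, 0)
  expect_true(all(diff(vals2) < 0))

  cm$lib_sizes <- c(s1 = 0)
  expect_error(logcpm(cm), "zero library size")
})

test_that("expression status boundaries: floor-10 counts are common, 9 never", {
  samples <- tiny_samples(2, 2)
  all10 <- tiny_counts(rep(10L, 4), genes = "g", samples = samples$sample_id)
  expect_identical(as.character(
    classify_expression_status(all10, samples)$status), "common")
  all9 <- tiny_counts(rep(9L, 4), genes = "g", samples = samples$sample_id)
  expect_identical(as.character(
    classify_expression_status(all9, samples)$status), "never")
  mixed <- tiny_counts(c(50L, 60L, 0L, 2L), genes = "g",
                       samples = samples$sample_id)
  expect_identical(as.character(
    classify_expression_status(mixed, samples)$status), "variable")
})

test_that("expression status equals a brute-force re-scan on random fixtures", {
  samples <- tiny_samples(4, 3)
  for (seed in 1:25) {
    set.seed(seed)
    m <- matrix(rpois(40 * 12, 12), 40,
                dimnames = list(sprintf("g%02d", 1:40), samples$sample_id))
    cm <- counts_matrix(m)
    got <- classify_expression_status(cm, samples, floor = 10)
    # brute force: per gene, loop strains and replicates
    want <- apply(m, 1, function(row) {
      per_strain <- vapply(unique(samples$strain_id), function(s) {
        v <- row[samples$sample_id[samples$strain_id == s]]
        c(all = all(v >= 10), any = any(v >= 10))
      }, logical(2))
      if (all(per_strain["all", ])) "common"
      else if (!any(per_strain["any", ])) "never"
      else "variable"
    })
    expect_identical(as.character(got$status), unname(want))
  }
})

test_that("strain means average replicates exactly", {
  samples <- tiny_samples(2, 4)[1:6, ]  # S01 x4, S02 x2
  m <- matrix(c(1, 2, 3, 4, 10, 20,
                0, 0, 0, 0, 5, 5,
                -1, 1, -1, 1, 2, 2), 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), samples$sample_id))
  sm <- strain_means(m, samples)
  expect_equal(sm["g1", ], c(S01 = 2.5, S02 = 15))
  expect_equal(sm["g2", ], c(S01 = 0, S02 = 5))
  expect_equal(sm["g3", ], c(S01 = 0, S02 = 2))
  # single replicate per strain: identity
  two <- samples[c(1, 5), ]
  two$replicate <- 1L
  # each strain still needs >= 2 replicates in validation, so duplicate rows
  dup <- rbind(samples[c(1, 2), ], samples[c(5, 6), ])
  sm2 <- strain_means(m[, dup$sample_id], dup)
  expect_equal(sm2["g1", "S02"], mean(m["g1", samples$sample_id[5:6]]))
})

test_that("variable-gene selection ranks by variance with lexicographic ties", {
  set.seed(1)
  m <- matrix(rnorm(10 * 6), 10,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("s%d", 1:6)))
  m[3, ] <- m[3, ] * 10
  m[7, ] <- m[7, ] * 5
  m[1, ] <- 0                       # constant
  v <- apply(m, 1, var)
  want <- names(sort(v, decreasing = TRUE))[1:3]
  expect_setequal(select_variable_genes(m, 3), want)
  expect_identical(select_variable_genes(m, nrow(m)) |> sort(),
                   rownames(m) |> sort())
  expect_false("g01" %in% select_variable_genes(m, 9))
  # deterministic tie-break on equal variances
  m2 <- matrix(rep(c(1, 2, 1, 2), 3), 3, byrow = TRUE,
               dimnames = list(c("b", "a", "c"), sprintf("s%d", 1:4)))
  expect_identical(select_variable_genes(m2, 2), c("a", "b"))
})

test_that("strain PCA matches a covariance-eigen oracle and its invariances", {
  set.seed(42)
  m <- matrix(rnorm(5 * 4), 5, dimnames = list(sprintf("g%d", 1:5),
                                               sprintf("S%d", 1:4)))
  res <- pca_strains(m)
  x <- scale(t(m), center = TRUE, scale = FALSE)
  eig <- eigen(cov(x))
  expect_equal(res$variance_explained,
               (eig$values / sum(eig$values))[seq_along(res$variance_explained)],
               tolerance = 1e-8)
  # compare score directions only where eigenvalues are distinct and nonzero
  for (j in 1:2) {
    oracle <- as.numeric(x %*% eig$vectors[, j])
    expect_equal(abs(cor(res$scores[, j], oracle)), 1, tolerance = 1e-6)
  }
  expect_equal(unname(colMeans(res$scores)), rep(0, ncol(res$scores)),
               tolerance = 1e-12)
  expect_true(all(diff(res$variance_explained) <= 1e-12))
  # invariant to gene reordering
  perm <- sample(nrow(m))
  expect_equal(pca_strains(m[perm, ])$variance_explained,
               res$variance_explained, tolerance = 1e-12)
  # degenerate: identical strains -> all zero eigenvalues, explained 0
  same <- matrix(rep(1:5, 2), 5, dimnames = list(sprintf("g%d", 1:5),
                                                 c("A", "B")))
  expect_equal(sum(pca_strains(same)$variance_explained), 0)
  # collinear data -> PC1 explains 100%
  line <- outer(rnorm(6), c(1, 2, 3))
  dimnames(line) <- list(sprintf("g%d", 1:6), sprintf("S%d", 1:3))
  expect_equal(pca_strains(line)$variance_explained[1], 1, tolerance = 1e-10)
})

test_that("dispersion summary groups by pangenome class", {
  sm <- matrix(c(5, 5, 5, 5, 1, 9, 0, 8), 4, byrow = TRUE,
               dimnames = list(c("g1", "g2", "g3", "g4"), c("A", "B")))
  cls <- c(g1 = "core", g2 = "core", g3 = "shell", g4 = "shell")
  ds <- dispersion_summary(sm, cls)
  expect_setequal(ds$class, c("core", "shell"))
  expect_true(ds$median_var[ds$class == "shell"] >
                ds$median_var[ds$class == "core"])
})
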