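test_that("module-trait correlation matches the direct formula and flags cuts", {
  set.seed(8)
  strains <- sprintf("S%02d", 1:20)
  eg <- matrix(rnorm(3 * 20), 3, dimnames = list(c("M01", "M02", "M03"),
                                                 strains))
  y <- rnorm(20)
  eg["M01", ] <- (y - mean(y)) / sd(y) / sqrt(19)   # standardized trait
  phen <- data.frame(strain_id = strains, shoot_biomass = y,
                     height = rnorm(20))
  res <- module_trait_correlation(eg, phen)
  r1 <- res$r[res$module == "M01" & res$trait == "shoot_biomass"]
  expect_equal(r1, 1, tolerance = 1e-10)
  expect_lt(res$p[res$module == "M01" & res$trait == "shoot_biomass"], 1e-10)
  for (m in rownames(eg)) {
    want <- cor(eg[m, ], y)
    expect_equal(res$r[res$module == m & res$trait == "shoot_biomass"],
                 want, tolerance = 1e-12)
    n <- 20
    tstat <- want * sqrt(n - 2) / sqrt(1 - want^2)
    expect_equal(res$p[res$module == m & res$trait == "shoot_biomass"],
                 2 * pt(abs(tstat), n - 2, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  expect_error(module_trait_correlation(
    eg, data.frame(strain_id = strains, shoot_biomass = 1)), "constant")
})

test_that("cross-network edges pass the cut and respect strain order strictly", {
  set.seed(12)
  strains <- sprintf("S%02d", 1:20)
  eg <- matrix(rnorm(4 * 20), 4, dimnames = list(sprintf("h%d", 1:4),
                                                 strains))
  eg2 <- eg
  rownames(eg2) <- sprintf("s%d", 1:4)
  res <- cross_network_correlation(eg, eg2)
  self <- res[match(paste0("h", 1:4, "s", 1:4),
                    paste0(res$host_module, res$symbiont_module)), ]
  expect_equal(self$r, rep(1, 4), tolerance = 1e-12)
  expect_true(all(self$passes_cut))

  # symmetric under swapping the two networks
  swapped <- cross_network_correlation(eg2, eg)
  key1 <- paste(res$host_module, res$symbiont_module)
  key2 <- paste(swapped$symbiont_module, swapped$host_module)
  expect_equal(res$r[order(key1)], swapped$r[order(key2)], tolerance = 1e-12)

  # shuffled strain columns are a hard error, not silently realigned
  expect_error(cross_network_correlation(eg, eg2[, rev(strains)]),
               "strain sets/order")
})

test_that("independent eigengenes yield edge counts near the null tail", {
  set.seed(21)
  n_edges <- 0
  n_pairs <- 0
  for (rep in 1:20) {
    h <- matrix(rnorm(5 * 20), 5,
                dimnames = list(sprintf("h%d", 1:5), sprintf("S%02d", 1:20)))
    s <- matrix(rnorm(5 * 20), 5,
                dimnames = list(sprintf("s%d", 1:5), sprintf("S%02d", 1:20)))
    res <- cross_network_correlation(h, s)
    n_edges <- n_edges + sum(res$passes_cut)
    n_pairs <- n_pairs + nrow(res)
  }
  # null tail for |r| > 0.7 at n = 20: 2 * pt(.) with r-to-t transform
  t_cut <- 0.7 * sqrt(18) / sqrt(1 - 0.49)
  p_tail <- 2 * pt(t_cut, 18, lower.tail = FALSE)
  expect_lt(abs(n_edges / n_pairs - p_tail), 3 * sqrt(p_tail / n_pairs) + 5e-3)
})

test_that("phenotype summary reproduces a hand-computed two-strain ANOVA", {
  phen <- data.frame(strain_id = c("A", "B"), shoot_biomass = c(1.5, 4),
                     height = c(1, 2))
  reps <- data.frame(strain_id = c("A", "A", "B", "B"),
                     shoot_biomass = c(1, 2, 3, 5))
  ps <- phenotype_summary(phen, reps)
  # by hand: MS_strain = 6.25 (df 1), MS_error = 1.25 (df 2)
  expect_equal(ps$anova$F, 5, tolerance = 1e-12)
  expect_equal(ps$anova$df, c(1, 2))
  expect_equal(ps$anova$p, pf(5, 1, 2, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(ps$anova$variance_component, (6.25 - 1.25) / 2,
               tolerance = 1e-12)
  expect_equal(ps$cv, sd(c(1.5, 4)) / mean(c(1.5, 4)), tolerance = 1e-12)
  expect_true(isSymmetric(ps$trait_correlations))
  expect_equal(unname(diag(ps$trait_correlations)), rep(1, 2))

  # degenerate: all means equal with zero error variance
  reps0 <- data.frame(strain_id = c("A", "A", "B", "B"),
                      shoot_biomass = c(2, 2, 2, 2))
  phen0 <- data.frame(strain_id = c("A", "B"), shoot_biomass = c(2, 2))
  ps0 <- phenotype_summary(phen0, reps0)
  expect_true(ps0$anova$degenerate)
  expect_equal(ps0$anova$variance_component, 0)
  expect_equal(ps0$variance, 0)
})

test_that("hypergeometric enrichment matches exhaustive enumeration (<= 20 genes)", {
  choose_p <- function(overlap, K, N, n) {
    # upper tail by direct enumeration over achievable overlaps
    ks <- max(0, n - (N - K)):min(K, n)
    sum(vapply(ks[ks >= overlap], function(j)
      choose(K, j) * choose(N - K, n - j), 0)) / choose(N, n)
  }
  set.seed(44)
  for (rep in 1:20) {
    N <- sample(8:20, 1)
    genes <- sprintf("g%02d", seq_len(N))
    n_mod <- sample(2:(N - 2), 1)
    K <- sample(2:(N - 2), 1)
    asg <- setNames(rep("unassigned", N), genes)
    asg[sample(N, n_mod)] <- "M01"
    cats <- data.frame(gene_id = sample(genes, K), category = "cat1")
    res <- category_enrichment(asg, cats, universe = genes)
    ov <- length(intersect(names(asg)[asg == "M01"], cats$gene_id))
    expect_identical(res$overlap, ov)
    expect_equal(res$p, choose_p(ov, K, N, n_mod), tolerance = 1e-10)
  }

  # module identical to a category: smallest achievable p = 1 / C(N, n)
  genes <- sprintf("g%02d", 1:10)
  asg <- setNames(rep("unassigned", 10), genes)
  asg[1:3] <- "M01"
  cats <- data.frame(gene_id = genes[1:3], category = "catX")
  res <- category_enrichment(asg, cats, universe = genes)
  expect_equal(res$p, 1 / choose(10, 3), tolerance = 1e-12)

  # zero overlap with a tiny category: upper tail includes >= 0, so p = 1
  cats2 <- data.frame(gene_id = genes[9:10], category = "catY")
  res2 <- category_enrichment(asg, cats2, universe = genes)
  expect_equal(res2$p, 1, tolerance = 1e-12)

  expect_error(category_enrichment(asg,
                                   data.frame(gene_id = "zz", category = "c")),
               "no category labels")
})

test_that("enrichment fdr is BH-monotone across the table", {
  set.seed(60)
  genes <- sprintf("g%03d", 1:200)
  asg <- setNames(sample(c("M01", "M02", "M03"), 200, TRUE), genes)
  cats <- data.frame(gene_id = rep(genes, 2),
                     category = sample(sprintf("c%d", 1:6), 400, TRUE))
  res <- category_enrichment(asg, cats)
  o <- order(res$p)
  expect_true(all(diff(res$fdr[o]) >= -1e-12))
  expect_equal(res$fdr, p.adjust(res$p, "BH"), tolerance = 1e-12)
})
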