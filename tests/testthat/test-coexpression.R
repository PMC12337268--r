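test_that("network prefilter drops genes below the median-count floor", {
  samples <- tiny_samples(2, 2)
  m <- matrix(c(9, 9, 9, 11,      # median 9 -> dropped
                10, 10, 9, 11,    # median 10 -> kept
                50, 50, 50, 50),  # kept
              3, byrow = TRUE,
              dimnames = list(c("gLow", "gEdge", "gHigh"),
                              samples$sample_id))
  cm <- counts_matrix(m)
  expect_identical(prefilter_for_network(cm, 10), c("gEdge", "gHigh"))
  expect_identical(prefilter_for_network(cm, 1), rownames(m))
})

test_that("TOM matches a triple-loop brute-force oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(4:10, 1)
    a <- matrix(runif(n * n), n)
    a <- (a + t(a)) / 2
    diag(a) <- 0
    dimnames(a) <- list(sprintf("g%d", 1:n), sprintf("g%d", 1:n))
    tom <- compute_tom(a)
    k <- rowSums(a)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) {
        expect_identical(tom[i, j], 1)
      } else {
        l <- 0
        for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
        want <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
        expect_equal(tom[i, j], want, tolerance = 1e-12)
      }
    }
  }
  # perfect 2-gene overlap and empty network edge cases
  a2 <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(compute_tom(a2)["x", "y"], 1)
  a0 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_true(all(compute_tom(a0)[upper.tri(a0)] == 0))
  expect_error(compute_tom(matrix(c(0, 1, 0, 0), 2)), "symmetric")
})

test_that("adjacency at power 1 is |cor| and power choice is deterministic", {
  set.seed(9)
  sm <- matrix(rnorm(3 * 8), 3, dimnames = list(c("a", "b", "c"),
                                                sprintf("S%d", 1:8)))
  cmat <- cor(t(sm))
  a <- pavnet:::network_adjacency(cmat, 1)
  expect_equal(a[upper.tri(a)], abs(cmat)[upper.tri(cmat)], tolerance = 1e-12)

  # independent genes: no power reaches the target; fallback is the argmax,
  # reproducibly
  set.seed(10)
  big <- matrix(rnorm(150 * 12), 150,
                dimnames = list(sprintf("g%03d", 1:150), sprintf("S%d", 1:12)))
  p1 <- pick_soft_power(big)
  p2 <- pick_soft_power(big)
  expect_identical(p1$beta, p2$beta)
  expect_identical(p1$fit_table, p2$fit_table)
  expect_error(pick_soft_power(matrix(1, 5, 6,
                                      dimnames = list(letters[1:5], NULL))),
               "constant")
})

# Two planted blocks with high within- and zero between-correlation.
planted_block_sm <- function(seed = 1, block = 30, noise = 0.45) {
  set.seed(seed)
  f1 <- rnorm(20); f2 <- rnorm(20)
  sm <- rbind(
    t(replicate(block, f1 + rnorm(20, 0, noise))),
    t(replicate(block, f2 + rnorm(20, 0, noise))))
  dimnames(sm) <- list(sprintf("g%02d", seq_len(2 * block)),
                       sprintf("S%02d", 1:20))
  sm
}

test_that("two planted blocks are recovered as exactly two modules", {
  sm <- planted_block_sm()
  cmat <- cor(t(sm))
  tom <- compute_tom(pavnet:::network_adjacency(cmat, 6))
  asg <- cut_modules(tom, min_module_size = 10, prefix = "M")
  expect_identical(sort(unique(asg)), c("M01", "M02"))
  expect_identical(length(unique(asg[1:30])), 1L)
  expect_identical(length(unique(asg[31:60])), 1L)

  # relabeling genes permutes labels but not the partition
  perm <- sample(nrow(tom))
  asg2 <- cut_modules(tom[perm, perm], min_module_size = 10, prefix = "M")
  expect_equal(adjusted_rand_index(asg2, asg[perm]), 1)

  # an impossible size threshold empties the assignment with a warning
  expect_warning(asg3 <- cut_modules(tom, min_module_size = 100),
                 "unassigned")
  expect_true(all(asg3 == "unassigned"))
})

test_that("eigengenes summarize modules and match an eigen oracle", {
  # module of identical genes: |cor| with members 1, variance explained 1
  f <- rnorm(12)
  sm <- t(replicate(4, f))
  dimnames(sm) <- list(sprintf("g%d", 1:4), sprintf("S%d", 1:12))
  asg <- setNames(rep("M01", 4), rownames(sm))
  me <- module_eigengenes(sm, asg)
  expect_equal(abs(cor(me$eigengenes["M01", ], f)), 1, tolerance = 1e-10)
  expect_equal(unname(me$variance_explained["M01"]), 1, tolerance = 1e-12)
  expect_equal(sum(me$eigengenes["M01", ]^2), 1, tolerance = 1e-12)
  # orientation: positively correlated with the module mean profile
  expect_gt(cor(me$eigengenes["M01", ], colMeans(scale(t(sm)) |> t())), 0)

  # random module: variance explained equals the leading eigenvalue ratio of
  # the gene-gene correlation matrix
  set.seed(77)
  sm2 <- matrix(rnorm(6 * 15), 6, dimnames = list(sprintf("g%d", 1:6),
                                                  sprintf("S%d", 1:15)))
  asg2 <- setNames(rep("M01", 6), rownames(sm2))
  me2 <- module_eigengenes(sm2, asg2)
  ev <- eigen(cor(t(sm2)))$values
  expect_equal(unname(me2$variance_explained["M01"]), ev[1] / sum(ev),
               tolerance = 1e-8)
})

test_that("similar modules merge to a fixpoint independent of order", {
  set.seed(30)
  f <- rnorm(20)
  mk_block <- function(f, n, noise) t(replicate(n, f + rnorm(20, 0, noise)))
  sm <- rbind(mk_block(f, 12, 0.1), mk_block(f, 12, 0.1),
              mk_block(f, 12, 0.1), mk_block(rnorm(20), 12, 0.1))
  dimnames(sm) <- list(sprintf("g%02d", 1:48), sprintf("S%02d", 1:20))
  asg <- setNames(rep(c("M01", "M02", "M03", "M04"), each = 12),
                  rownames(sm))
  me <- module_eigengenes(sm, asg)
  merged <- merge_similar_modules(sm, me, merge_cor = 0.75,
                                  min_module_size = 10)
  # three mutually similar modules collapse into one; the independent one stays
  expect_identical(length(unique(merged$assignment)), 2L)
  expect_identical(length(unique(merged$assignment[1:36])), 1L)
  # idempotent once below the threshold
  again <- merge_similar_modules(sm, merged, merge_cor = 0.75,
                                 min_module_size = 10)
  expect_identical(again$assignment, merged$assignment)
})

test_that("the network size guard refuses oversized inputs", {
  sm <- matrix(rnorm(30 * 8), 30, dimnames = list(sprintf("g%d", 1:30),
                                                  sprintf("S%d", 1:8)))
  expect_error(build_coexpression_network(sm, max_genes = 10L), "max_genes")
})
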