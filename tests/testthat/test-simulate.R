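no_clusters <- function() {
  data.frame(cluster_id = character(0), size = integer(0),
             replicon = character(0), frequency = numeric(0),
             effect = numeric(0), stringsAsFactors = FALSE)
}

test_that("identical parameters and seed give identical datasets", {
  d1 <- suppressWarnings(simulate_dataset(small_params(seed = 5)))
  d2 <- suppressWarnings(simulate_dataset(small_params(seed = 5)))
  expect_identical(d1$symbiont_counts$counts, d2$symbiont_counts$counts)
  expect_identical(d1$host_counts$counts, d2$host_counts$counts)
  expect_identical(d1$phenotypes, d2$phenotypes)
  expect_identical(d1$annotation, d2$annotation)
  expect_identical(d1$truth$presence, d2$truth$presence)
  d3 <- suppressWarnings(simulate_dataset(small_params(seed = 6)))
  expect_false(identical(d1$symbiont_counts$counts,
                         d3$symbiont_counts$counts))
})

test_that("an all-core pangenome yields an all-true presence matrix", {
  p <- sim_params(
    replicons = data.frame(replicon_id = "chromosome", n_genes = 50L,
                           core = 1, shell = 0, cloud = 0),
    accessory_n_genes = 0L, planted_clusters = no_clusters(), seed = 2)
  pan <- simulate_pangenome(p)
  expect_true(all(pan$presence))
  expect_identical(dim(pan$presence), c(50L, 20L))
})

test_that("planted clusters share one pattern, hit their frequency, and sit within the gap rule", {
  p <- small_params(seed = 3)
  pan <- simulate_pangenome(p)
  for (j in seq_len(nrow(p$planted_clusters))) {
    id <- p$planted_clusters$cluster_id[j]
    members <- pan$truth$cluster_members[[id]]
    expect_length(members, p$planted_clusters$size[j])
    sub <- pan$presence[members, , drop = FALSE]
    expect_true(all(apply(sub, 2, function(col) length(unique(col)) == 1)))
    expect_identical(sum(sub[1, ]),
                     as.integer(round(p$planted_clusters$frequency[j] * 20)))
    a <- pan$annotation[match(members, pan$annotation$gene_id), ]
    a <- a[order(a$start), ]
    if (nrow(a) > 1) {
      gaps <- a$start[-1] - a$end[-nrow(a)] - 1L
      expect_true(all(gaps < 3000))
    }
  }
  # trait-linked patterns follow the latent quality axis
  u <- pan$truth$quality
  pos <- pan$truth$cluster_patterns[["pcPos"]]
  neg <- pan$truth$cluster_patterns[["pcNeg"]]
  expect_gt(mean(u[pos]) - mean(u[!pos]), 0)
  expect_lt(mean(u[neg]) - mean(u[!neg]), 0)

  # infeasible layout: cluster larger than the replicon's shell capacity
  bad <- small_params()
  bad$planted_clusters$size[1] <- 1000L
  expect_error(simulate_pangenome(bad), "shell capacity|infeasible")
})

test_that("absent genes have zero counts when contamination is zero", {
  ds <- suppressWarnings(simulate_dataset(small_params(seed = 4)))
  pres <- ds$truth$presence[, ds$samples$strain_id]
  expect_true(all(ds$symbiont_counts$counts[!pres] == 0))
  # with contamination, absent genes see a few reads
  p <- small_params(seed = 4)
  p$contamination <- 2
  ds2 <- suppressWarnings(simulate_dataset(p))
  pres2 <- ds2$truth$presence[, ds2$samples$strain_id]
  expect_gt(sum(ds2$symbiont_counts$counts[!pres2]), 0)
})

test_that("zero-loading module genes are independent of their strain factor", {
  p <- sim_params(
    n_strains = 200, n_reps = 2,
    replicons = data.frame(replicon_id = "chromosome", n_genes = 30L,
                           core = 1, shell = 0, cloud = 0),
    accessory_n_genes = 0L, planted_clusters = no_clusters(),
    symbiont_modules = data.frame(size_frac = 0.5, rho = 0, gamma = 0),
    host_modules = data.frame(size_frac = 0.5, rho = 0, gamma = 0),
    n_host_genes = 30L, module_loading = 0, seed = 9)
  pan <- simulate_pangenome(p)
  cnt <- simulate_counts(pan, p)
  sm <- strain_means(logcpm(cnt$symbiont), cnt$samples)
  fac <- cnt$truth$symbiont_modules$factors[1, colnames(sm)]
  members <- names(cnt$truth$symbiont_modules$membership)[
    cnt$truth$symbiont_modules$membership == "rM01"]
  rr <- abs(cor(t(sm[members, , drop = FALSE]), fac))
  expect_lt(median(rr), 0.07)
  expect_lt(max(rr), 0.2)
})

test_that("doubling library sizes doubles expected counts", {
  base <- small_params(seed = 10)
  base$lib_size_range <- c(2e6, 2e6)
  dbl <- small_params(seed = 10)
  dbl$lib_size_range <- c(4e6, 4e6)
  c1 <- simulate_counts(simulate_pangenome(base), base)$symbiont
  c2 <- simulate_counts(simulate_pangenome(dbl), dbl)$symbiont
  expect_equal(sum(c2$counts) / sum(c1$counts), 2, tolerance = 0.02)
})

test_that("phenotype CV tracks the target and effects act in the planted direction", {
  # no planted effects: CV comes from the environmental term alone
  cvs <- vapply(1:50, function(s) {
    p <- small_params(seed = s)
    p$planted_clusters$effect[] <- 0
    p$symbiont_modules$gamma[] <- 0
    p$host_modules$gamma[] <- 0
    pan <- simulate_pangenome(p)
    phe <- suppressWarnings(simulate_phenotype(pan$truth, p))
    sd(phe$phenotypes$shoot_biomass) / mean(phe$phenotypes$shoot_biomass)
  }, 0)
  expect_lt(abs(mean(cvs) - 0.6), 0.12)   # within 20% of the 0.6 target

  # one positive-effect cluster raises biomass of carrier strains
  hits <- 0
  for (s in 1:20) {
    p <- small_params(seed = s)
    p$planted_clusters <- p$planted_clusters[1, ]   # pcPos only
    p$symbiont_modules$gamma[] <- 0
    p$host_modules$gamma[] <- 0
    pan <- simulate_pangenome(p)
    phe <- suppressWarnings(simulate_phenotype(pan$truth, p))
    pat <- pan$truth$cluster_patterns[["pcPos"]]
    pv <- t.test(phe$phenotypes$shoot_biomass[pat],
                 phe$phenotypes$shoot_biomass[!pat],
                 alternative = "greater")$p.value
    if (pv < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 18)

  # no environmental noise, no modules: biomass is exactly linear in presence
  p <- small_params(seed = 11)
  p$heritability <- 1
  p$symbiont_modules$gamma[] <- 0
  p$host_modules$gamma[] <- 0
  pan <- simulate_pangenome(p)
  phe <- suppressWarnings(simulate_phenotype(pan$truth, p))
  X <- vapply(pan$truth$cluster_patterns, as.numeric,
              numeric(p$n_strains))
  fit <- lm(phe$phenotypes$shoot_biomass ~ X)
  expect_lt(max(abs(residuals(fit))), 1e-10)
})

test_that("assemblies contain exact copies at zero substitution and none for absent genes", {
  p <- sim_params(
    replicons = data.frame(replicon_id = "pSymA", n_genes = 12L,
                           core = 0.5, shell = 0.5, cloud = 0),
    accessory_n_genes = 0L, planted_clusters = no_clusters(),
    substitution_rate = 0, rc_frac = 0, n_host_genes = 20L,
    symbiont_modules = data.frame(size_frac = 0.5, rho = 0, gamma = 0),
    host_modules = data.frame(size_frac = 0.5, rho = 0, gamma = 0),
    seed = 12)
  pan <- simulate_pangenome(p)
  asm <- simulate_assemblies(pan, p)
  for (s in c("S01", "S07")) {
    genome <- paste(as.character(asm$genomes[[s]]), collapse = "")
    for (g in rownames(pan$presence)) {
      found <- grepl(as.character(asm$ref_seqs[[g]]), genome, fixed = TRUE)
      expect_identical(found, pan$presence[g, s])
    }
  }
})

test_that("mutated copies recover the expected identity", {
  p <- sim_params(
    n_strains = 4,
    replicons = data.frame(replicon_id = "pSymA", n_genes = 6L,
                           core = 1, shell = 0, cloud = 0),
    accessory_n_genes = 0L, planted_clusters = no_clusters(),
    substitution_rate = 0.01, rc_frac = 0.5, n_host_genes = 20L,
    symbiont_modules = data.frame(size_frac = 0.5, rho = 0, gamma = 0),
    host_modules = data.frame(size_frac = 0.5, rho = 0, gamma = 0),
    seed = 13)
  pan <- simulate_pangenome(p)
  dir <- withr::local_tempdir()
  asm <- simulate_assemblies(pan, p, out_dir = dir)
  res <- find_sequence_presence(asm$ref_seqs, asm$store,
                                strains = c("S01", "S02"))
  # per-site substitution at 1%: identity concentrates near 0.99
  expect_equal(mean(res$hits$identity), 0.99, tolerance = 0.005)
  expect_true(all(res$hits$identity > 0.96))
})

test_that("written datasets are read back bit-identically by the package readers", {
  dir <- withr::local_tempdir()
  ds <- suppressWarnings(simulate_dataset(small_params(seed = 14),
                                          out_dir = dir))
  back <- read_expression_inputs(file.path(dir, "symbiont_counts.tsv"),
                                 file.path(dir, "sample_sheet.csv"))
  expect_identical(back$counts$counts, ds$symbiont_counts$counts)
  expect_identical(back$samples, ds$samples)
  phen <- read_phenotypes(file.path(dir, "phenotypes.csv"))
  expect_equal(phen$shoot_biomass, ds$phenotypes$shoot_biomass,
               tolerance = 1e-12)
  ann <- read_annotation(file.path(dir, "annotation.gff3"), "pangenome_ref")
  ann <- ann[match(ds$annotation$gene_id, ann$gene_id), ]
  expect_identical(ann$start, ds$annotation$start)
  expect_identical(ann$end, ds$annotation$end)
  grp <- read_gene_groups(file.path(dir, "gene_groups.tsv"))
  expect_identical(nrow(grp), nrow(ds$gene_groups))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
})
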