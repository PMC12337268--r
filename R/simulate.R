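#' Simulation parameters
#'
#' Defaults emulate the study conditions the pipeline is built for: 20 strains
#' with 4 RNA-seq replicates, a multipartite symbiont genome (~6,000 genes over
#' a chromosome, pSymA, pSymB and a small accessory plasmid carried by 8
#' strains), replicon-specific core/shell/cloud frequency profiles with core
#' fractions 56.1% (chromosome), 19.9% (pSymA) and 67.9% (pSymB), planted
#' intermediate-frequency syntenic clusters on pSymA with trait effects,
#' planted coexpression modules in both organisms, ~5,000 host genes, and a
#' strain-level shoot-biomass phenotype with a coefficient of variation of 0.6.
#'
#' Strain quality structure: a latent per-strain quality factor drives (i) the
#' presence patterns of trait-linked clusters (sign of the effect tilts the
#' threshold), (ii) the strain factors of trait-coupled modules (via `rho`),
#' and (iii) the phenotype, which remains an additive function of cluster
#' presence and module factors plus environmental noise, auto-scaled to the CV
#' target.
#'
#' @param n_strains,n_reps Strains and RNA-seq replicates per strain.
#' @param replicons Data frame `replicon_id`, `n_genes`, `core`, `shell`,
#'   `cloud` (class fractions summing to 1 per replicon).
#' @param accessory_n_genes,accessory_strains Genes on the accessory plasmid
#'   and number of strains carrying it.
#' @param planted_clusters Data frame `cluster_id`, `size`, `replicon`,
#'   `frequency`, `effect` (trait effect in relative units; 0 = neutral).
#'   Cluster members are adjacent shell genes sharing one presence pattern.
#' @param symbiont_modules,host_modules Data frames `size_frac` (fraction of
#'   the eligible gene set), `rho` (correlation of the module's strain factor
#'   with the latent quality factor), `gamma` (additive phenotype weight).
#'   Symbiont modules partition the true core genes; host modules partition all
#'   host genes.
#' @param module_loading Mean per-gene loading (log2 units per factor SD);
#'   per-gene loadings are jittered by `loading_jitter`.
#' @param loading_jitter Multiplicative uniform jitter range for loadings.
#' @param nb_dispersion Negative-binomial dispersion (1/size).
#' @param lib_size_range,host_lib_size_range Uniform library-size ranges
#'   (reads) for symbiont- and host-mapped counts.
#' @param baseline_meanlog,baseline_sdlog,host_baseline_meanlog,host_baseline_sdlog
#'   Log-normal parameters of baseline expression (CPM).
#' @param contamination Mean CPM observed for a truly absent gene (delta; 0 =
#'   clean absence, > 0 stresses the absence caller).
#' @param substitution_rate Per-site substitution rate applied to gene copies
#'   in simulated assemblies.
#' @param rc_frac Fraction of gene copies inserted reverse-complemented.
#' @param gene_len_meanlog,gene_len_sdlog Log-normal gene length (bp).
#' @param spacer_within,spacer_between Uniform intergenic gap ranges (bp)
#'   within planted clusters and between layout units; the between-unit minimum
#'   exceeds the 3-kb syntenic rule so background genes never chain.
#' @param assembly_spacer Uniform spacer range (bp) between adjacent present
#'   genes in simulated strain assemblies.
#' @param n_host_genes Number of host genes.
#' @param phenotype_cv_target Target CV of strain-mean shoot biomass.
#' @param biomass_mean Grand mean shoot biomass (g).
#' @param heritability Fraction of strain-mean biomass variance explained by
#'   planted genetic structure; the rest is environmental.
#' @param cluster_pattern_noise SD of the noise added to the latent quality
#'   factor before thresholding trait-linked cluster patterns.
#' @param biomass_floor Lower clip for simulated biomass (g).
#' @param n_pheno_reps,within_strain_cv Replicate-level phenotype design.
#' @param n_categories,category_purity Functional-category labels: number of
#'   COG-like categories and the probability a gene takes its module's
#'   dominant category.
#' @param seed Integer seed; all randomness flows from it.
#'
#' @return A `sim_params` object (validated named list).
#' @export
sim_params <- function(n_strains = 20,
                       n_reps = 4,
                       replicons = data.frame(
                         replicon_id = c("chromosome", "pSymA", "pSymB"),
                         n_genes = c(3400L, 1300L, 1200L),
                         core = c(0.561, 0.199, 0.679),
                         shell = c(0.330, 0.650, 0.250),
                         cloud = c(0.109, 0.151, 0.071),
                         stringsAsFactors = FALSE),
                       accessory_n_genes = 100L,
                       accessory_strains = 8L,
                       planted_clusters = data.frame(
                         cluster_id = c("pcPos", "pcNeg", "pcNeuA", "pcNeuB"),
                         size = c(4L, 10L, 3L, 2L),
                         replicon = c("pSymA", "pSymA", "pSymA", "pSymA"),
                         frequency = c(0.5, 0.5, 0.4, 0.6),
                         effect = c(1, -1, 0, 0),
                         stringsAsFactors = FALSE),
                       symbiont_modules = data.frame(
                         size_frac = c(0.30, 0.20, 0.15, 0.12, 0.09,
                                       0.07, 0.04, 0.03),
                         rho = c(0, 0.9, 0, 0, -0.6, 0, 0, 0),
                         gamma = c(0, 0.5, 0, 0, 0, 0, 0, 0)),
                       host_modules = data.frame(
                         size_frac = c(0.40, 0.28, 0.16, 0.10, 0.06),
                         rho = c(0, 0.9, 0, -0.6, 0),
                         gamma = c(0, 0.5, 0, 0, 0)),
                       module_loading = 0.5,
                       loading_jitter = c(0.7, 1.3),
                       nb_dispersion = 0.1,
                       lib_size_range = c(2e6, 8e6),
                       host_lib_size_range = c(8e6, 2e7),
                       baseline_meanlog = log(150),
                       baseline_sdlog = 1.0,
                       host_baseline_meanlog = log(80),
                       host_baseline_sdlog = 1.0,
                       contamination = 0,
                       substitution_rate = 0.005,
                       rc_frac = 0.1,
                       gene_len_meanlog = log(900),
                       gene_len_sdlog = 0.3,
                       spacer_within = c(50, 500),
                       spacer_between = c(4000, 20000),
                       assembly_spacer = c(200, 800),
                       n_host_genes = 5000L,
                       phenotype_cv_target = 0.60,
                       biomass_mean = 0.26,
                       heritability = 0.85,
                       cluster_pattern_noise = 0.3,
                       biomass_floor = 0.01,
                       n_pheno_reps = 10L,
                       within_strain_cv = 0.25,
                       n_categories = 18L,
                       category_purity = 0.4,
                       seed = 1L) {
  p <- mget(names(formals(sim_params)))
  p$n_strains <- as.integer(n_strains)
  p$n_reps <- as.integer(n_reps)
  p$seed <- as.integer(seed)
  class(p) <- "sim_params"
  validate_sim_params(p)
  p
}

validate_sim_params <- function(p) {
  stopifnot(inherits(p, "sim_params"))
  chk <- function(ok, msg) if (!ok) stop("invalid sim_params: ", msg,
                                         call. = FALSE)
  chk(p$n_strains >= 4L, "need >= 4 strains")
  chk(p$n_reps >= 2L, "need >= 2 replicates")
  fr <- p$replicons[, c("core", "shell", "cloud")]
  chk(all(fr >= 0 & fr <= 1), "class fractions must be in [0, 1]")
  chk(all(abs(rowSums(fr) - 1) < 1e-8), "class fractions must sum to 1")
  chk(all(p$planted_clusters$size >= 2L), "planted cluster sizes must be >= 2")
  chk(all(p$planted_clusters$frequency > 0 & p$planted_clusters$frequency < 1),
      "planted cluster frequencies must be in (0, 1)")
  chk(all(p$planted_clusters$replicon %in% p$replicons$replicon_id),
      "planted cluster on unknown replicon")
  shell_quota <- round(p$replicons$shell * p$replicons$n_genes)
  names(shell_quota) <- p$replicons$replicon_id
  demand <- tapply(p$planted_clusters$size, p$planted_clusters$replicon, sum)
  over <- demand > shell_quota[names(demand)]
  chk(!any(over), paste("planted clusters exceed shell capacity of replicon",
                        names(demand)[over][1]))
  for (m in list(p$symbiont_modules, p$host_modules)) {
    chk(all(m$size_frac > 0) && sum(m$size_frac) <= 1 + 1e-8,
        "module size fractions must be positive and sum to <= 1")
    chk(all(abs(m$rho) <= 1), "module rho must be in [-1, 1]")
  }
  chk(p$accessory_n_genes == 0L || p$accessory_strains <= p$n_strains,
      "accessory_strains exceeds n_strains")
  chk(p$contamination >= 0, "contamination must be >= 0")
  chk(p$substitution_rate >= 0 && p$substitution_rate < 1,
      "substitution_rate must be in [0, 1)")
  chk(p$phenotype_cv_target > 0, "phenotype_cv_target must be > 0")
  chk(p$heritability >= 0 && p$heritability <= 1,
      "heritability must be in [0, 1]")
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(paste0("sim_params: %d strains x %d reps, %d symbiont genes ",
                     "(+%d accessory), %d host genes, %d planted clusters, ",
                     "seed %d\n"),
              x$n_strains, x$n_reps, sum(x$replicons$n_genes),
              x$accessory_n_genes, x$n_host_genes,
              nrow(x$planted_clusters), x$seed))
  invisible(x)
}

strain_ids <- function(n) sprintf("S%02d", seq_len(n))

#' Simulate a pangenome with planted structure
#'
#' Draws per-gene presence frequencies from a three-component mixture (core
#' frequency 1; shell Uniform(0.15, 0.95); cloud Uniform(1/n, 0.15)) with
#' deterministic per-replicon class counts so the replicon profiles are hit in
#' expectation, places planted clusters as runs of adjacent genes with
#' intra-cluster gaps below the 3-kb rule and >= 4-kb gaps everywhere else,
#' and adds an accessory plasmid carried by a strict subset of strains.
#' A gene drawn absent from every strain is forced into one random strain so
#' every emitted gene group is observed at least once.
#'
#' @param params A [sim_params()] object.
#' @return List with `annotation` (reference coordinates), `gene_groups`
#'   (group_id, strain_id, gene_id), `presence` (logical gene x strain
#'   matrix), and `truth` (latent quality factor, per-gene class and
#'   frequency, planted cluster membership/patterns/effects).
#' @export
simulate_pangenome <- function(params = sim_params()) {
  validate_sim_params(params)
  set.seed(params$seed)
  n <- params$n_strains
  strains <- strain_ids(n)
  u <- stats::rnorm(n)
  names(u) <- strains

  genes <- list()
  for (i in seq_len(nrow(params$replicons))) {
    rep_id <- params$replicons$replicon_id[i]
    ng <- params$replicons$n_genes[i]
    n_core <- round(params$replicons$core[i] * ng)
    n_shell <- round(params$replicons$shell[i] * ng)
    n_cloud <- ng - n_core - n_shell
    cls <- sample(rep(c("core", "shell", "cloud"), c(n_core, n_shell, n_cloud)))
    freq <- numeric(ng)
    freq[cls == "core"] <- 1
    freq[cls == "shell"] <- stats::runif(sum(cls == "shell"), 0.15, 0.95)
    freq[cls == "cloud"] <- stats::runif(sum(cls == "cloud"), 1 / n, 0.15)
    genes[[rep_id]] <- data.frame(
      gene_id = sprintf("%s_%04d", rep_id, seq_len(ng)),
      replicon_id = rep_id, class = cls, freq = freq,
      cluster = NA_character_, stringsAsFactors = FALSE)
  }
  if (params$accessory_n_genes > 0L) {
    genes[["pAcc"]] <- data.frame(
      gene_id = sprintf("pAcc_%04d", seq_len(params$accessory_n_genes)),
      replicon_id = "pAcc", class = "shell",
      freq = params$accessory_strains / n,
      cluster = NA_character_, stringsAsFactors = FALSE)
  }

  # Carve planted cluster members out of each replicon's shell quota.
  pc <- params$planted_clusters
  cluster_members <- list()
  for (j in seq_len(nrow(pc))) {
    g <- genes[[pc$replicon[j]]]
    free_shell <- which(g$class == "shell" & is.na(g$cluster))
    if (pc$size[j] > length(free_shell)) {
      stop("infeasible layout: cluster ", pc$cluster_id[j],
           " larger than available shell genes on ", pc$replicon[j],
           call. = FALSE)
    }
    take <- sample(free_shell, pc$size[j])
    g$cluster[take] <- pc$cluster_id[j]
    g$freq[take] <- pc$frequency[j]
    genes[[pc$replicon[j]]] <- g
    cluster_members[[pc$cluster_id[j]]] <- g$gene_id[take]
  }
  gene_tab <- do.call(rbind, genes)
  rownames(gene_tab) <- NULL

  # Presence: shared patterns for planted clusters, Bernoulli(freq) otherwise.
  presence <- matrix(FALSE, nrow(gene_tab), n,
                     dimnames = list(gene_tab$gene_id, strains))
  presence[gene_tab$class == "core", ] <- TRUE
  acc_strains <- if (params$accessory_n_genes > 0L) {
    sample(strains, params$accessory_strains)
  } else character(0)
  cluster_patterns <- list()
  for (j in seq_len(nrow(pc))) {
    k <- max(1L, min(n - 1L, round(pc$frequency[j] * n)))
    if (pc$effect[j] != 0) {
      z <- sign(pc$effect[j]) * u + stats::rnorm(n, 0, params$cluster_pattern_noise)
      pat <- rank(-z, ties.method = "first") <= k
    } else {
      pat <- seq_len(n) %in% sample(n, k)
    }
    names(pat) <- strains
    cluster_patterns[[pc$cluster_id[j]]] <- pat
    presence[cluster_members[[pc$cluster_id[j]]], ] <-
      matrix(pat, pc$size[j], n, byrow = TRUE)
  }
  singles <- which(is.na(gene_tab$cluster) & gene_tab$class != "core" &
                     gene_tab$replicon_id != "pAcc")
  if (length(singles)) {
    pm <- matrix(stats::runif(length(singles) * n), length(singles), n) <
      gene_tab$freq[singles]
    none <- rowSums(pm) == 0L
    if (any(none)) pm[cbind(which(none), sample(n, sum(none), replace = TRUE))] <- TRUE
    presence[singles, ] <- pm
  }
  if (params$accessory_n_genes > 0L) {
    presence[gene_tab$replicon_id == "pAcc", ] <-
      matrix(strains %in% acc_strains, params$accessory_n_genes, n,
             byrow = TRUE)
  }

  annotation <- layout_annotation(gene_tab, params)
  idx <- rep(seq_len(nrow(presence)), n)
  keep <- as.vector(presence)
  gene_groups <- data.frame(
    group_id = gene_tab$gene_id[idx][keep],
    strain_id = rep(strains, each = nrow(presence))[keep],
    gene_id = gene_tab$gene_id[idx][keep],
    stringsAsFactors = FALSE)

  truth <- list(
    quality = u,
    strains = strains,
    gene_table = gene_tab,
    presence = presence,
    clusters = data.frame(pc, stringsAsFactors = FALSE),
    cluster_members = cluster_members,
    cluster_patterns = cluster_patterns,
    accessory_strains = acc_strains
  )
  list(annotation = annotation, gene_groups = gene_groups,
       presence = presence, truth = truth)
}

# Reference coordinates: planted clusters are contiguous runs with small
# internal gaps; every other unit boundary gap exceeds the syntenic rule.
layout_annotation <- function(gene_tab, params) {
  out <- list()
  for (rep_id in unique(gene_tab$replicon_id)) {
    g <- gene_tab[gene_tab$replicon_id == rep_id, ]
    units <- split(seq_len(nrow(g)), ifelse(is.na(g$cluster),
                                            paste0("s", seq_len(nrow(g))),
                                            g$cluster))
    units <- units[sample(length(units))]
    lens <- pmax(100L, round(stats::rlnorm(nrow(g), params$gene_len_meanlog,
                                           params$gene_len_sdlog)))
    pos <- 0L
    start <- end <- integer(nrow(g))
    for (un in units) {
      un <- un[order(un)]
      for (i in seq_along(un)) {
        gap <- if (i == 1L) {
          round(stats::runif(1, params$spacer_between[1],
                             params$spacer_between[2]))
        } else {
          round(stats::runif(1, params$spacer_within[1],
                             params$spacer_within[2]))
        }
        start[un[i]] <- pos + gap + 1L
        end[un[i]] <- start[un[i]] + lens[un[i]] - 1L
        pos <- end[un[i]]
      }
    }
    out[[rep_id]] <- data.frame(
      strain_id = "pangenome_ref", gene_id = g$gene_id, replicon_id = rep_id,
      start = as.integer(start), end = as.integer(end),
      strand = sample(c("+", "-"), nrow(g), replace = TRUE),
      stringsAsFactors = FALSE)
  }
  ann <- do.call(rbind, out)
  rownames(ann) <- NULL
  validate_annotation(ann)
}

#' Simulate host and symbiont nodule counts
#'
#' Counts are negative binomial with mean `lib * 1e-6 * cpm * 2^(loading *
#' factor)` for present genes and `contamination * lib * 1e-6` for absent
#' genes. Symbiont modules partition the true core genes; host modules
#' partition all host genes; trait-coupled module factors correlate with the
#' latent quality factor through `rho`.
#'
#' @param pan Result of [simulate_pangenome()] (or its `truth` element).
#' @param params A [sim_params()] object.
#' @return List with `symbiont` and `host` [counts_matrix()] objects,
#'   `samples` (sample sheet), and `truth` (the pangenome truth augmented with
#'   module memberships, strain factors, loadings and category labels).
#' @export
simulate_counts <- function(pan, params = sim_params()) {
  truth <- if (!is.null(pan$truth)) pan$truth else pan
  set.seed(params$seed + 1L)
  n <- params$n_strains
  strains <- truth$strains
  samples <- data.frame(
    sample_id = paste0(rep(strains, each = params$n_reps), "_r",
                       rep(seq_len(params$n_reps), n)),
    strain_id = rep(strains, each = params$n_reps),
    replicate = rep(seq_len(params$n_reps), n),
    stringsAsFactors = FALSE)

  core_genes <- rownames(truth$presence)[rowSums(truth$presence) == n]
  n_sym <- nrow(params$symbiont_modules)
  fac_all <- module_factors(c(params$symbiont_modules$rho,
                              params$host_modules$rho), truth$quality)
  symb <- plant_modules(core_genes, params$symbiont_modules, "rM",
                        fac_all[seq_len(n_sym), , drop = FALSE], params)
  host_genes <- sprintf("Mt_%05d", seq_len(params$n_host_genes))
  host <- plant_modules(host_genes, params$host_modules, "pM",
                        fac_all[-seq_len(n_sym), , drop = FALSE], params)

  symb_counts <- nb_counts(rownames(truth$presence), samples, truth$presence,
                           symb, params$lib_size_range,
                           params$baseline_meanlog, params$baseline_sdlog,
                           params)
  host_presence <- matrix(TRUE, length(host_genes), n,
                          dimnames = list(host_genes, strains))
  host_counts <- nb_counts(host_genes, samples, host_presence, host,
                           params$host_lib_size_range,
                           params$host_baseline_meanlog,
                           params$host_baseline_sdlog, params)

  categories <- module_categories(symb$membership, rownames(truth$presence),
                                  params)
  truth$symbiont_modules <- symb
  truth$host_modules <- host
  truth$categories <- categories
  list(symbiont = symb_counts, host = host_counts, samples = samples,
       truth = truth)
}

# Module strain factors `rho * u + sqrt(1 - rho^2) * w`, with the residual
# directions w made exactly orthonormal to the quality axis and to each other
# (joint Gram-Schmidt over host and symbiont), so uncoupled planted modules
# are decorrelated in sample and the only cross-module structure is the one
# planted through u.
module_factors <- function(rho, u) {
  n <- length(u)
  n_mod <- length(rho)
  stopifnot(n_mod + 1L <= n)
  u_std <- as.vector(scale(u))
  q <- qr.Q(qr(cbind(u_std, matrix(stats::rnorm(n * n_mod), n, n_mod))))
  w <- t(q[, -1L, drop = FALSE]) * sqrt(n - 1)   # unit sample variance
  f <- rho * matrix(u_std, n_mod, n, byrow = TRUE) + sqrt(1 - rho^2) * w
  colnames(f) <- names(u)
  f
}

# Partition `gene_ids` into modules carrying the given strain factors.
plant_modules <- function(gene_ids, spec, prefix, factors, params) {
  n_mod <- nrow(spec)
  sizes <- floor(spec$size_frac * length(gene_ids))
  sizes[1] <- sizes[1] + (length(gene_ids) - sum(sizes))  # remainder to largest
  labels <- rep(c(sprintf("%s%02d", prefix, seq_len(n_mod)), "background"),
                c(sizes, length(gene_ids) - sum(sizes)))
  membership <- stats::setNames(sample(labels), gene_ids)
  rownames(factors) <- sprintf("%s%02d", prefix, seq_len(n_mod))
  # Signs balanced within modules (induced and repressed members) so module
  # activity does not shift total library size and leak into the CPM of
  # unrelated genes.
  loadings <- stats::setNames(
    params$module_loading * stats::runif(length(gene_ids),
                                         params$loading_jitter[1],
                                         params$loading_jitter[2]) *
      sample(c(-1, 1), length(gene_ids), replace = TRUE),
    gene_ids)
  loadings[membership == "background"] <- 0
  list(membership = membership, factors = factors, loadings = loadings,
       spec = cbind(module = rownames(factors), spec))
}

nb_counts <- function(gene_ids, samples, presence, modules, lib_range,
                      meanlog, sdlog, params) {
  ng <- length(gene_ids)
  ns <- nrow(samples)
  libs <- round(stats::runif(ns, lib_range[1], lib_range[2]))
  base_cpm <- stats::rlnorm(ng, meanlog, sdlog)
  mod_of <- modules$membership[gene_ids]      # NA for genes outside the set
  fac <- matrix(0, ng, length(unique(samples$strain_id)),
                dimnames = list(gene_ids, colnames(modules$factors)))
  in_mod <- !is.na(mod_of) & mod_of != "background"
  fac[in_mod, ] <- modules$factors[mod_of[in_mod], , drop = FALSE] *
    modules$loadings[gene_ids[in_mod]]
  cpm_gs <- base_cpm * 2^fac                      # gene x strain expected CPM
  pres <- presence[gene_ids, samples$strain_id, drop = FALSE]
  cpm_samp <- cpm_gs[, samples$strain_id, drop = FALSE]
  cpm_samp[!pres] <- params$contamination
  mu <- sweep(cpm_samp, 2, libs * 1e-6, "*")
  counts <- matrix(stats::rnbinom(ng * ns, mu = mu,
                                  size = 1 / params$nb_dispersion),
                   ng, ns, dimnames = list(gene_ids, samples$sample_id))
  counts_matrix(counts)
}

module_categories <- function(membership, gene_ids, params) {
  cats <- sprintf("COG%02d", seq_len(params$n_categories))
  mods <- setdiff(unique(membership), "background")
  dominant <- stats::setNames(sample(cats, length(mods), replace = TRUE), mods)
  lab <- sample(cats, length(gene_ids), replace = TRUE)
  names(lab) <- gene_ids
  mem <- membership[gene_ids]
  covered <- !is.na(mem) & mem != "background"
  take <- covered & stats::runif(length(gene_ids)) < params$category_purity
  lab[take] <- dominant[mem[take]]
  data.frame(gene_id = gene_ids, category = unname(lab),
             stringsAsFactors = FALSE)
}

#' Simulate the strain-level phenotype
#'
#' Strain-mean shoot biomass is the additive model `mu0 + sum(effect_c *
#' presence_cs) + sum(gamma_m * factor_ms) + eps`, with the genetic part
#' standardized to `heritability * (CV * mu0)^2` variance and the
#' environmental variance filling the remainder, so the realized CV matches
#' the target in expectation. Correlated secondary traits and a
#' replicate-level table (for the strain ANOVA) are emitted alongside.
#'
#' @param cnt Result of [simulate_counts()] (or a truth list carrying cluster
#'   patterns; module factors are optional).
#' @param params A [sim_params()] object.
#' @return List with `phenotypes` (strain means, traits in columns),
#'   `pheno_reps` (replicate-level shoot biomass), and `truth` augmented with
#'   the phenotype decomposition.
#' @export
simulate_phenotype <- function(cnt, params = sim_params()) {
  truth <- if (!is.null(cnt$truth)) cnt$truth else cnt
  set.seed(params$seed + 2L)
  strains <- truth$strains
  n <- length(strains)
  sigma_t <- params$phenotype_cv_target * params$biomass_mean

  g <- stats::setNames(numeric(n), strains)
  pc <- truth$clusters
  for (j in seq_len(nrow(pc))) {
    g <- g + pc$effect[j] * as.numeric(truth$cluster_patterns[[pc$cluster_id[j]]])
  }
  for (mods in list(truth$symbiont_modules, truth$host_modules)) {
    if (is.null(mods)) next
    for (m in seq_len(nrow(mods$spec))) {
      g <- g + mods$spec$gamma[m] * mods$factors[m, ]
    }
  }
  if (stats::sd(g) > 0) {
    g <- (g - mean(g)) / stats::sd(g) * sqrt(params$heritability) * sigma_t
    eps_sd <- sqrt(1 - params$heritability) * sigma_t
  } else {
    eps_sd <- sigma_t
  }
  eps <- stats::rnorm(n, 0, eps_sd)
  biomass <- params$biomass_mean + g + eps
  low <- biomass < params$biomass_floor
  if (any(low)) {
    warning(sum(low), " strain biomass value(s) clipped at the floor",
            call. = FALSE)
    biomass[low] <- params$biomass_floor
  }

  q <- (biomass - mean(biomass)) / stats::sd(biomass)
  phenotypes <- data.frame(
    strain_id = strains,
    shoot_biomass = biomass,
    root_biomass = pmax(0.005, 0.4 * biomass + stats::rnorm(n, 0, 0.02)),
    chlorophyll = 30 + 5 * q + stats::rnorm(n, 0, 2),
    height = 12 + 2.5 * q + stats::rnorm(n, 0, 1.2),
    leaf_number = pmax(2, round(9 + 2 * q + stats::rnorm(n, 0, 1.5))),
    nodule_number = pmax(1, round(40 - 8 * q + stats::rnorm(n, 0, 6))),
    stringsAsFactors = FALSE)

  reps <- params$n_pheno_reps
  pheno_reps <- data.frame(
    strain_id = rep(strains, each = reps),
    replicate = rep(seq_len(reps), n),
    shoot_biomass = pmax(params$biomass_floor,
                         rep(biomass, each = reps) +
                           stats::rnorm(n * reps, 0,
                                        params$within_strain_cv *
                                          params$biomass_mean)),
    stringsAsFactors = FALSE)

  truth$phenotype <- list(mu0 = params$biomass_mean, genetic = g, eps = eps,
                          strain_means = stats::setNames(biomass, strains))
  list(phenotypes = phenotypes, pheno_reps = pheno_reps, truth = truth)
}

#' Simulate per-strain genome assemblies
#'
#' Each gene gets an i.i.d. A/C/G/T reference sequence of its annotated
#' length; a strain's replicon concatenates random spacers with the sequences
#' of the genes truly present in that strain, each copy mutated at
#' `substitution_rate` per site and reverse-complemented with probability
#' `rc_frac`. Absent genes leave no copy.
#'
#' @param pan Result of [simulate_pangenome()] (needs `annotation` and
#'   `truth`).
#' @param params A [sim_params()] object.
#' @param out_dir If non-NULL, write one FASTA per strain there and return a
#'   [genome_store()] over them.
#' @return List with `ref_seqs` (named `DNAStringSet` of gene reference
#'   sequences), `genomes` (per-strain `DNAStringSet`s), and when `out_dir`
#'   is given, `store` (a `genome_store`) and `paths`.
#' @export
simulate_assemblies <- function(pan, params = sim_params(), out_dir = NULL) {
  set.seed(params$seed + 3L)
  ann <- pan$annotation
  truth <- pan$truth
  presence <- truth$presence
  bases <- c("A", "C", "G", "T")
  lens <- stats::setNames(ann$end - ann$start + 1L, ann$gene_id)
  ref_chr <- lapply(lens, function(L) sample(bases, L, replace = TRUE))
  ref_seqs <- Biostrings::DNAStringSet(
    vapply(ref_chr, paste, character(1), collapse = ""))
  names(ref_seqs) <- ann$gene_id

  genomes <- list()
  for (s in truth$strains) {
    reps <- character(0)
    for (rep_id in unique(ann$replicon_id)) {
      a <- ann[ann$replicon_id == rep_id, ]
      a <- a[order(a$start), ]
      here <- a$gene_id[presence[a$gene_id, s]]
      if (!length(here)) next
      pieces <- character(2L * length(here))
      for (i in seq_along(here)) {
        gch <- ref_chr[[here[i]]]
        nm <- stats::rbinom(1, length(gch), params$substitution_rate)
        if (nm > 0) {
          at <- sample(length(gch), nm)
          gch[at] <- vapply(gch[at],
                            function(b) sample(setdiff(bases, b), 1), "")
        }
        seq <- paste(gch, collapse = "")
        if (stats::runif(1) < params$rc_frac) {
          seq <- as.character(
            Biostrings::reverseComplement(Biostrings::DNAString(seq)))
        }
        sp <- round(stats::runif(1, params$assembly_spacer[1],
                                 params$assembly_spacer[2]))
        pieces[2L * i - 1L] <- paste(sample(bases, sp, replace = TRUE),
                                     collapse = "")
        pieces[2L * i] <- seq
      }
      reps[rep_id] <- paste(pieces, collapse = "")
    }
    genomes[[s]] <- Biostrings::DNAStringSet(reps)
  }

  out <- list(ref_seqs = ref_seqs, genomes = genomes)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    paths <- stats::setNames(
      file.path(out_dir, paste0(truth$strains, ".fasta")), truth$strains)
    for (s in truth$strains) {
      Biostrings::writeXStringSet(genomes[[s]], paths[[s]])
    }
    out$paths <- paths
    out$store <- genome_store(paths)
  }
  out
}

#' Simulate a complete dataset
#'
#' Orchestrates [simulate_pangenome()], [simulate_counts()] and
#' [simulate_phenotype()] (and optionally [simulate_assemblies()]), asserts
#' that expression truth, sequence truth and the recorded ground truth are
#' mutually consistent, and optionally writes every file the readers in the
#' package consume plus a ground-truth JSON.
#'
#' @param params A [sim_params()] object.
#' @param with_assemblies Also simulate per-strain genome FASTAs.
#' @param out_dir If non-NULL, write counts TSVs, sample sheet, phenotype CSV,
#'   GFF3 annotation, gene-group TSV (and FASTAs) there.
#' @return List with `symbiont_counts`, `host_counts`, `samples`,
#'   `phenotypes`, `pheno_reps`, `annotation`, `gene_groups`, `truth`,
#'   `params`, and (optionally) `assemblies`.
#' @export
simulate_dataset <- function(params = sim_params(), with_assemblies = FALSE,
                             out_dir = NULL) {
  pan <- simulate_pangenome(params)
  cnt <- simulate_counts(pan, params)
  phe <- simulate_phenotype(cnt, params)
  ds <- list(symbiont_counts = cnt$symbiont, host_counts = cnt$host,
             samples = cnt$samples, phenotypes = phe$phenotypes,
             pheno_reps = phe$pheno_reps, annotation = pan$annotation,
             gene_groups = pan$gene_groups, truth = phe$truth,
             params = params)
  if (with_assemblies) {
    ds$assemblies <- simulate_assemblies(pan, params,
                                         out_dir = if (!is.null(out_dir))
                                           file.path(out_dir, "assemblies"))
  }
  assert_truth_consistency(ds)
  if (!is.null(out_dir)) write_dataset(ds, out_dir)
  ds
}

# Internal consistency: a truly absent gene shows zero counts (when
# contamination is zero) and no sequence copy; presence matrix matches the
# gene-group table.
assert_truth_consistency <- function(ds) {
  truth <- ds$truth
  pres <- truth$presence
  grp <- table(factor(ds$gene_groups$group_id, levels = rownames(pres)),
               factor(ds$gene_groups$strain_id, levels = colnames(pres)))
  stopifnot(all((grp > 0) == pres))
  if (ds$params$contamination == 0) {
    expanded <- pres[, ds$samples$strain_id, drop = FALSE]
    stopifnot(all(ds$symbiont_counts$counts[!expanded] == 0))
  }
  if (!is.null(ds$assemblies)) {
    for (s in colnames(pres)) {
      present_len <- sum(Biostrings::width(ds$assemblies$ref_seqs[
        rownames(pres)[pres[, s]]]))
      stopifnot(sum(Biostrings::width(ds$assemblies$genomes[[s]])) >=
                  present_len)
    }
  }
  invisible(TRUE)
}

write_dataset <- function(ds, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  wtsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  sym <- data.frame(gene_id = rownames(ds$symbiont_counts$counts),
                    ds$symbiont_counts$counts, check.names = FALSE)
  hst <- data.frame(gene_id = rownames(ds$host_counts$counts),
                    ds$host_counts$counts, check.names = FALSE)
  wtsv(sym, "symbiont_counts.tsv")
  wtsv(hst, "host_counts.tsv")
  utils::write.csv(ds$samples, file.path(out_dir, "sample_sheet.csv"),
                   row.names = FALSE)
  utils::write.csv(ds$phenotypes, file.path(out_dir, "phenotypes.csv"),
                   row.names = FALSE)
  utils::write.csv(ds$pheno_reps, file.path(out_dir, "phenotype_replicates.csv"),
                   row.names = FALSE)
  write_annotation(ds$annotation, file.path(out_dir, "annotation.gff3"))
  wtsv(ds$gene_groups, "gene_groups.tsv")
  truth_json <- list(
    quality = as.list(ds$truth$quality),
    presence = list(genes = rownames(ds$truth$presence),
                    strains = colnames(ds$truth$presence),
                    calls = unname(apply(ds$truth$presence, 1, as.integer,
                                         simplify = FALSE))),
    clusters = ds$truth$clusters,
    cluster_members = ds$truth$cluster_members,
    symbiont_modules = as.list(ds$truth$symbiont_modules$membership),
    host_modules = as.list(ds$truth$host_modules$membership),
    seed = ds$params$seed)
  jsonlite::write_json(truth_json, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
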