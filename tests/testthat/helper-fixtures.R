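# Shared fixture builders. Everything is generated in code; tests that need
# files write them under withr::local_tempdir()/tempfile().

# A tiny counts matrix with explicit values.
tiny_counts <- function(values, n_genes = NULL, n_samples = NULL,
                        genes = NULL, samples = NULL) {
  m <- matrix(values, nrow = n_genes %||% length(genes),
              ncol = n_samples %||% length(samples))
  rownames(m) <- genes %||% sprintf("g%02d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%02d", seq_len(ncol(m)))
  counts_matrix(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Sample sheet for n_strains x n_reps, sample ids "<strain>_r<rep>".
tiny_samples <- function(n_strains = 2, n_reps = 2) {
  strains <- sprintf("S%02d", seq_len(n_strains))
  data.frame(
    sample_id = paste0(rep(strains, each = n_reps), "_r",
                       rep(seq_len(n_reps), n_strains)),
    strain_id = rep(strains, each = n_reps),
    replicate = rep(seq_len(n_reps), n_strains),
    stringsAsFactors = FALSE)
}

# Annotation row helper.
ann_row <- function(gene_id, replicon_id, start, end, strand = "+",
                    strain_id = "ref") {
  data.frame(strain_id = strain_id, gene_id = gene_id,
             replicon_id = replicon_id, start = as.integer(start),
             end = as.integer(end), strand = strand,
             stringsAsFactors = FALSE)
}

# Reduced-scale simulation parameters: same design (20 strains x 4 reps,
# same class profiles, same planted clusters and module structure), ~10x
# fewer genes, for fast unit tests.
small_params <- function(seed = 1L, ...) {
  sim_params(
    replicons = data.frame(
      replicon_id = c("chromosome", "pSymA", "pSymB"),
      n_genes = c(340L, 130L, 120L),
      core = c(0.561, 0.199, 0.679),
      shell = c(0.330, 0.650, 0.250),
      cloud = c(0.109, 0.151, 0.071),
      stringsAsFactors = FALSE),
    accessory_n_genes = 10L,
    n_host_genes = 400L,
    symbiont_modules = data.frame(
      size_frac = c(0.4, 0.3, 0.2),
      rho = c(0, 0.9, -0.6),
      gamma = c(0, 0.5, 0)),
    host_modules = data.frame(
      size_frac = c(0.5, 0.3, 0.15),
      rho = c(0, 0.9, -0.6),
      gamma = c(0, 0.5, 0)),
    seed = seed,
    ...)
}

# Random counts fixture with a seeded RNG, for brute-force comparisons.
random_counts <- function(n_genes, samples, seed, lambda = 60) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * nrow(samples), lambda), n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              samples$sample_id))
  # sprinkle zeros/low counts so presence calls vary
  drop <- matrix(runif(length(m)) < 0.25, nrow(m))
  m[drop] <- rpois(sum(drop), 1)
  counts_matrix(m)
}
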