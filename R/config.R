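#' Analysis configuration
#'
#' Bundles every threshold used downstream, with defaults equal to the values
#' the pipeline is built around: a count floor of 10 converted to a per-strain
#' CPM cutoff, absence in 3 of 4 replicates, an on/off window of 3 to
#' `n_strains - 3` strains, gene-trait cuts |r| > 0.5 and FDR < 0.15, sequence
#' confirmation at 98% identity and coverage, a 3-kb syntenic gap, pangenome
#' bins core > 99% / shell 15-95% / cloud < 15%, a median-count-10 network
#' prefilter, the 5,000 most variable host genes, module-trait cuts |r| > 0.6
#' and P < 0.05, and a cross-network cut |r| > 0.7.
#'
#' @param cpm_floor Count floor (counts-equivalent) converted to a per-strain
#'   CPM cutoff using the median library size of that strain's replicates.
#' @param absent_rep_fraction Fraction of a strain's replicates that must fall
#'   below the cutoff to label the gene absent (ceil(fraction * n_reps)).
#' @param min_present_strains,max_present_strains On/off window on the number
#'   of presence strains. `max_present_strains = NA` means `n_strains - 3`,
#'   resolved when the filter runs.
#' @param r_cut_gene,fdr_cut_gene Gene-trait significance cuts.
#' @param min_identity,min_coverage Sequence-confirmation thresholds.
#' @param seed_k K-mer size for the seed-and-extend confirmation aligner.
#' @param cluster_gap_bp Maximum inter-feature gap (bp, inclusive) chaining two
#'   candidate genes into one syntenic cluster.
#' @param core_frac,shell_lo,shell_hi Pangenome class boundaries. Fractions in
#'   `(shell_hi, core_frac]` are assigned shell (gap rule, logged).
#' @param median_count_floor Network prefilter: drop genes whose median raw
#'   count across all samples is below this.
#' @param n_variable_host_genes Host genes kept by variance ranking.
#' @param r_cut_module_trait,p_cut_module_trait Module-trait cuts.
#' @param r_cut_cross Cross-network module-module cut.
#' @param soft_power_grid Candidate soft-threshold powers.
#' @param scale_free_r2 Scale-free fit target R^2 for power selection.
#' @param min_module_size Smallest reported module; smaller clusters are
#'   labelled unassigned.
#' @param merge_cor Module eigengene correlation above which modules merge.
#' @param cut_height_quantile Dendrogram cut at this quantile of merge heights.
#' @param signed_network Use signed correlations (`(1 + cor)/2`) instead of
#'   `|cor|` for adjacency.
#' @param trait Trait used for gene/cluster/module association.
#' @param presence_correlation `"binary"` correlates 0/1 presence with the
#'   trait (point-biserial); `"logcpm"` uses strain-mean logCPM instead.
#' @param ttest_var_equal Pooled-variance t for cluster-trait tests (`FALSE`
#'   gives Welch).
#' @param round_fractional Round fractional counts half-to-even at read time
#'   (with a warning) instead of raising an error.
#' @param seed Integer seed recorded in the run manifest.
#'
#' @return An object of class `pav_config` (a validated named list).
#' @export
analysis_config <- function(cpm_floor = 10,
                            absent_rep_fraction = 0.75,
                            min_present_strains = 3,
                            max_present_strains = NA_integer_,
                            r_cut_gene = 0.5,
                            fdr_cut_gene = 0.15,
                            min_identity = 0.98,
                            min_coverage = 0.98,
                            seed_k = 31L,
                            cluster_gap_bp = 3000,
                            core_frac = 0.99,
                            shell_lo = 0.15,
                            shell_hi = 0.95,
                            median_count_floor = 10,
                            n_variable_host_genes = 5000,
                            r_cut_module_trait = 0.6,
                            p_cut_module_trait = 0.05,
                            r_cut_cross = 0.7,
                            soft_power_grid = 1:12,
                            scale_free_r2 = 0.8,
                            min_module_size = 10,
                            merge_cor = 0.75,
                            cut_height_quantile = 0.99,
                            signed_network = FALSE,
                            trait = "shoot_biomass",
                            presence_correlation = c("binary", "logcpm"),
                            ttest_var_equal = TRUE,
                            round_fractional = FALSE,
                            seed = 1L) {
  presence_correlation <- match.arg(presence_correlation)
  cfg <- list(
    cpm_floor = cpm_floor,
    absent_rep_fraction = absent_rep_fraction,
    min_present_strains = as.integer(min_present_strains),
    max_present_strains = as.integer(max_present_strains),
    r_cut_gene = r_cut_gene,
    fdr_cut_gene = fdr_cut_gene,
    min_identity = min_identity,
    min_coverage = min_coverage,
    seed_k = as.integer(seed_k),
    cluster_gap_bp = cluster_gap_bp,
    core_frac = core_frac,
    shell_lo = shell_lo,
    shell_hi = shell_hi,
    median_count_floor = median_count_floor,
    n_variable_host_genes = as.integer(n_variable_host_genes),
    r_cut_module_trait = r_cut_module_trait,
    p_cut_module_trait = p_cut_module_trait,
    r_cut_cross = r_cut_cross,
    soft_power_grid = as.integer(soft_power_grid),
    scale_free_r2 = scale_free_r2,
    min_module_size = as.integer(min_module_size),
    merge_cor = merge_cor,
    cut_height_quantile = cut_height_quantile,
    signed_network = isTRUE(signed_network),
    trait = trait,
    presence_correlation = presence_correlation,
    ttest_var_equal = isTRUE(ttest_var_equal),
    round_fractional = isTRUE(round_fractional),
    seed = as.integer(seed)
  )
  class(cfg) <- "pav_config"
  validate_config(cfg)
  cfg
}

#' Validate an analysis configuration
#'
#' @param cfg A `pav_config` object.
#' @return `cfg`, invisibly, or an error naming the offending field.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "pav_config"))
  chk <- function(ok, msg) if (!ok) stop("invalid config: ", msg, call. = FALSE)
  in01 <- function(x) is.numeric(x) && length(x) == 1L && x >= 0 && x <= 1
  chk(is.numeric(cfg$cpm_floor) && cfg$cpm_floor >= 0, "cpm_floor must be >= 0")
  chk(in01(cfg$absent_rep_fraction) && cfg$absent_rep_fraction > 0,
      "absent_rep_fraction must be in (0, 1]")
  chk(cfg$min_present_strains >= 0, "min_present_strains must be >= 0")
  if (!is.na(cfg$max_present_strains)) {
    chk(cfg$min_present_strains <= cfg$max_present_strains,
        "min_present_strains exceeds max_present_strains")
  }
  chk(in01(cfg$r_cut_gene) && in01(cfg$fdr_cut_gene),
      "gene-trait cuts must be in [0, 1]")
  chk(in01(cfg$min_identity) && in01(cfg$min_coverage),
      "identity/coverage thresholds must be in [0, 1]")
  chk(cfg$seed_k >= 4L, "seed_k must be >= 4")
  chk(cfg$cluster_gap_bp >= 0, "cluster_gap_bp must be >= 0")
  chk(in01(cfg$core_frac) && in01(cfg$shell_lo) && in01(cfg$shell_hi) &&
        cfg$shell_lo <= cfg$shell_hi && cfg$shell_hi <= cfg$core_frac,
      "pangenome bins must satisfy shell_lo <= shell_hi <= core_frac, all in [0, 1]")
  chk(cfg$median_count_floor >= 0, "median_count_floor must be >= 0")
  chk(cfg$n_variable_host_genes >= 1L, "n_variable_host_genes must be >= 1")
  chk(in01(cfg$r_cut_module_trait) && in01(cfg$p_cut_module_trait) &&
        in01(cfg$r_cut_cross), "module cuts must be in [0, 1]")
  chk(all(cfg$soft_power_grid >= 1L), "soft_power_grid powers must be >= 1")
  chk(in01(cfg$scale_free_r2), "scale_free_r2 must be in [0, 1]")
  chk(cfg$min_module_size >= 2L, "min_module_size must be >= 2")
  chk(in01(cfg$merge_cor), "merge_cor must be in [0, 1]")
  chk(in01(cfg$cut_height_quantile), "cut_height_quantile must be in [0, 1]")
  invisible(cfg)
}

#' @export
print.pav_config <- function(x, ...) {
  cat("pavnet analysis configuration\n")
  nm <- names(x)
  for (i in seq_along(x)) {
    cat(sprintf("  %-24s %s\n", nm[i], paste(format(x[[i]]), collapse = " ")))
  }
  invisible(x)
}

#' Read an analysis configuration from a YAML-like key:value text file
#'
#' A single structured text file (`key: value` per line, `#` comments; vectors
#' as comma-separated values) overriding [analysis_config()] defaults.
#'
#' @param path Path to the configuration file.
#' @return A `pav_config` object.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, ":", fixed = TRUE)[[1]]
    if (length(kv) < 2L) stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = ":"))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    if (!anyNA(num)) {
      args[[key]] <- num
    } else if (all(parts %in% c("TRUE", "FALSE", "true", "false"))) {
      args[[key]] <- as.logical(toupper(parts))
    } else {
      args[[key]] <- parts
    }
  }
  unknown <- setdiff(names(args), names(formals(analysis_config)))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(analysis_config, args)
}

# Small stable FNV-1a hash of the config for the run manifest (text-only, no
# external digest dependency).
config_hash <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(v) paste(format(v), collapse = ","),
                                character(1)), sep = "=", collapse = ";")
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
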