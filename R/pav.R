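#' Call gene presence/absence from expression
#'
#' Per strain, the count floor is converted to a CPM cutoff using the median
#' library size of that strain's replicates (`cpm_floor / median_lib_millions`,
#' in the spirit of edgeR's filterByExpr). A gene is labeled absent in a
#' strain when its CPM falls below that cutoff in at least
#' `ceil(absent_rep_fraction * n_reps)` of the strain's replicates (3 of 4 at
#' the defaults), and present otherwise.
#'
#' @param cm A [counts_matrix()].
#' @param samples Sample sheet data frame.
#' @param config A [analysis_config()].
#' @return Logical gene x strain presence matrix with attributes `cutoffs`
#'   (per-strain CPM cutoff) and `source = "expression"`.
#' @export
call_presence_from_expression <- function(cm, samples,
                                          config = analysis_config()) {
  samples <- validate_sample_sheet(samples)
  stopifnot(all(samples$sample_id %in% colnames(cm$counts)))
  cpm_mat <- cpm(cm)
  strains <- unique(samples$strain_id)
  cutoffs <- stats::setNames(numeric(length(strains)), strains)
  presence <- matrix(TRUE, nrow(cm$counts), length(strains),
                     dimnames = list(rownames(cm$counts), strains))
  for (s in strains) {
    idx <- samples$sample_id[samples$strain_id == s]
    med_lib <- stats::median(cm$lib_sizes[idx])
    if (med_lib == 0) stop("strain with all-zero libraries: ", s,
                           call. = FALSE)
    cutoffs[s] <- config$cpm_floor / (med_lib / 1e6)
    n_below_needed <- ceiling(config$absent_rep_fraction * length(idx))
    below <- cpm_mat[, idx, drop = FALSE] < cutoffs[s]
    presence[, s] <- rowSums(below) < n_below_needed
  }
  attr(presence, "cutoffs") <- cutoffs
  attr(presence, "source") <- "expression"
  presence
}

#' Filter genes by on/off presence pattern
#'
#' Keeps genes present in at least `min_present_strains` and at most
#' `max_present_strains` strains (defaults 3 and `n_strains - 3`, the
#' 3-to-17-of-20 window).
#'
#' @param presence Logical gene x strain matrix.
#' @param config A [analysis_config()].
#' @return Character vector of retained gene ids.
#' @export
filter_onoff <- function(presence, config = analysis_config()) {
  n_strains <- ncol(presence)
  lo <- config$min_present_strains
  hi <- if (is.na(config$max_present_strains)) n_strains - 3L else
    config$max_present_strains
  if (lo > hi) stop("min_present_strains exceeds max_present_strains",
                    call. = FALSE)
  k <- rowSums(presence)
  rownames(presence)[k >= lo & k <= hi]
}

#' Correlate gene presence with a trait
#'
#' Point-biserial (Pearson) correlation of each gene's 0/1 presence vector
#' with the strain-mean trait; p from the t transform `r * sqrt(n-2) /
#' sqrt(1-r^2)` with `n - 2` df (two-sided); Benjamini-Hochberg FDR over the
#' tested (non-constant) genes. Alternatively (`presence_correlation =
#' "logcpm"` in the config) the strain-mean logCPM replaces the binary vector.
#'
#' @param presence Logical gene x strain matrix (already on/off filtered).
#' @param phenotypes Phenotype data frame (`strain_id` + traits).
#' @param config A [analysis_config()].
#' @param expr Optional gene x strain matrix used when the config selects
#'   `"logcpm"` correlation.
#' @return Data frame with `unit_id`, `n_present`, `r`, `stat`, `p`, `fdr`,
#'   `significant`, `degenerate`; degenerate (constant) genes carry NA
#'   statistics and are excluded from the FDR set.
#' @export
correlate_presence_with_trait <- function(presence, phenotypes,
                                          config = analysis_config(),
                                          expr = NULL) {
  trait_vals <- trait_by_strain(phenotypes, colnames(presence), config$trait)
  x <- if (config$presence_correlation == "logcpm") {
    stopifnot(!is.null(expr))
    expr[rownames(presence), colnames(presence), drop = FALSE]
  } else {
    presence * 1
  }
  res <- cor_with_trait(x, trait_vals)
  res <- data.frame(unit_id = rownames(presence),
                    n_present = rowSums(presence), res,
                    stringsAsFactors = FALSE)
  res$fdr <- NA_real_
  tested <- !res$degenerate
  res$fdr[tested] <- stats::p.adjust(res$p[tested], method = "BH")
  res$significant <- !res$degenerate & abs(res$r) > config$r_cut_gene &
    res$fdr < config$fdr_cut_gene
  rownames(res) <- NULL
  res
}

# Pearson r against a trait for each row of x, with t statistic and p.
cor_with_trait <- function(x, trait_vals) {
  n <- length(trait_vals)
  degenerate <- apply(x, 1, function(v) stats::var(v) == 0) |
    rep(stats::var(trait_vals) == 0, nrow(x))
  r <- rep(NA_real_, nrow(x))
  r[!degenerate] <- as.vector(stats::cor(t(x[!degenerate, , drop = FALSE]),
                                         trait_vals))
  r <- pmin(1, pmax(-1, r))
  stat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(stat), df = n - 2, lower.tail = FALSE)
  data.frame(r = r, stat = stat, p = p, n = n, degenerate = degenerate)
}

trait_by_strain <- function(phenotypes, strains, trait) {
  if (!trait %in% names(phenotypes)) {
    stop("trait not in phenotype table: ", trait, call. = FALSE)
  }
  missing <- setdiff(strains, phenotypes$strain_id)
  if (length(missing)) stop("no phenotype for strain ", missing[1],
                            call. = FALSE)
  stats::setNames(phenotypes[[trait]][match(strains, phenotypes$strain_id)],
                  strains)
}

#' Keep genes whose expression and sequence presence calls fully agree
#'
#' The 100%-agreement rule: a gene is confirmed only when its
#' expression-based and sequence-based presence calls match in every strain;
#' the rest are reported with per-gene discordance counts.
#'
#' @param expr_presence,seq_presence Logical gene x strain matrices over the
#'   same genes and strains.
#' @return List with `confirmed` (gene ids in full agreement) and
#'   `discordance` (data frame gene_id, n_discordant for the dropped genes).
#' @export
agreement_filter <- function(expr_presence, seq_presence) {
  if (!identical(dim(expr_presence), dim(seq_presence)) ||
      !identical(rownames(expr_presence), rownames(seq_presence)) ||
      !identical(colnames(expr_presence), colnames(seq_presence))) {
    stop("presence matrices must cover the same genes and strains",
         call. = FALSE)
  }
  mism <- rowSums(expr_presence != seq_presence)
  list(confirmed = rownames(expr_presence)[mism == 0L],
       discordance = data.frame(
         gene_id = rownames(expr_presence)[mism > 0L],
         n_discordant = unname(mism[mism > 0L]),
         stringsAsFactors = FALSE))
}
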