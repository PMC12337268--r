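#' Correlate module eigengenes with traits
#'
#' Pearson r per (module, trait) with p from the t transform (df = n - 2);
#' a module is flagged significant for the primary trait when `|r|` exceeds
#' the cut and p is below the cut (raw p, as is conventional for
#' module-trait heatmaps; `adjust = TRUE` adds BH across modules per trait).
#'
#' @param me Result of [module_eigengenes()] (or a module x strain matrix).
#' @param phenotypes Phenotype data frame.
#' @param config A [analysis_config()] (`r_cut_module_trait`,
#'   `p_cut_module_trait`).
#' @param traits Trait columns to test (default: all numeric).
#' @param adjust Add BH-adjusted fdr across modules within each trait.
#' @return Data frame module, trait, r, stat, p, (fdr,) significant.
#' @export
module_trait_correlation <- function(me, phenotypes,
                                     config = analysis_config(),
                                     traits = NULL, adjust = FALSE) {
  eg <- if (is.list(me) && !is.null(me$eigengenes)) me$eigengenes else me
  strains <- colnames(eg)
  if (is.null(traits)) {
    traits <- names(phenotypes)[vapply(phenotypes, is.numeric, TRUE)]
  }
  rows <- list()
  for (tr in traits) {
    y <- trait_by_strain(phenotypes, strains, tr)
    if (stats::var(y) == 0) {
      stop("trait constant across strains: ", tr, call. = FALSE)
    }
    res <- cor_with_trait(eg, y)
    rows[[tr]] <- data.frame(module = rownames(eg), trait = tr,
                             r = res$r, stat = res$stat, p = res$p,
                             stringsAsFactors = FALSE)
    if (adjust) rows[[tr]]$fdr <- stats::p.adjust(res$p, method = "BH")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$significant <- abs(out$r) > config$r_cut_module_trait &
    out$p < config$p_cut_module_trait
  out
}

#' Correlate modules across the host and symbiont networks
#'
#' All pairwise Pearson correlations between host and symbiont module
#' eigengenes over the same, identically ordered strains; edges where `|r|`
#' exceeds the cut (0.7 at the defaults). Strain order mismatches are a hard
#' error, never silently realigned.
#'
#' @param me_host,me_symbiont [module_eigengenes()] results (or module x
#'   strain matrices).
#' @param config A [analysis_config()] (`r_cut_cross`).
#' @param trait_cor Optional [module_trait_correlation()] tables (host and
#'   symbiont) used to annotate each edge with both modules' trait
#'   correlations.
#' @return Data frame host_module, symbiont_module, r, p, passes_cut (and
#'   host_trait_r / symbiont_trait_r when annotations are supplied).
#' @export
cross_network_correlation <- function(me_host, me_symbiont,
                                      config = analysis_config(),
                                      trait_cor = NULL) {
  h <- if (is.list(me_host) && !is.null(me_host$eigengenes))
    me_host$eigengenes else me_host
  s <- if (is.list(me_symbiont) && !is.null(me_symbiont$eigengenes))
    me_symbiont$eigengenes else me_symbiont
  if (!identical(colnames(h), colnames(s))) {
    stop("strain sets/order differ between the two eigengene matrices",
         call. = FALSE)
  }
  n <- ncol(h)
  r <- stats::cor(t(h), t(s))
  stat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(stat), df = n - 2, lower.tail = FALSE)
  out <- data.frame(
    host_module = rep(rownames(h), times = ncol(r)),
    symbiont_module = rep(colnames(r), each = nrow(r)),
    r = as.vector(r), p = as.vector(p),
    passes_cut = as.vector(abs(r) > config$r_cut_cross),
    stringsAsFactors = FALSE)
  if (!is.null(trait_cor)) {
    pick <- function(tab, mod) {
      hit <- tab$r[tab$module == mod & tab$trait == config$trait]
      if (length(hit)) hit[1] else NA_real_
    }
    out$host_trait_r <- vapply(out$host_module, pick, 0,
                               tab = trait_cor$host)
    out$symbiont_trait_r <- vapply(out$symbiont_module, pick, 0,
                                   tab = trait_cor$symbiont)
  }
  out
}

#' Phenotype summary: variance, CV, strain ANOVA, trait correlations
#'
#' One-way ANOVA of the replicate-level trait on strain; the among-strain
#' variance component by the method of moments, `(MS_strain - MS_error) /
#' n_reps` floored at zero; the CV of strain means; and the full trait-trait
#' Pearson correlation matrix.
#'
#' @param phenotypes Strain-mean phenotype data frame.
#' @param pheno_reps Replicate-level data frame with `strain_id` and the
#'   trait column (needed for the ANOVA; may be NULL).
#' @param trait Primary trait.
#' @return List with `trait`, `variance` (of strain means), `cv`,
#'   `anova` (F, df, p, variance_component) or NULL, and `trait_correlations`.
#' @export
phenotype_summary <- function(phenotypes, pheno_reps = NULL,
                              trait = "shoot_biomass") {
  y <- phenotypes[[trait]]
  if (is.null(y)) stop("trait not in phenotype table: ", trait, call. = FALSE)
  if (nrow(phenotypes) < 2L) stop("need >= 2 strains", call. = FALSE)
  out <- list(trait = trait, variance = stats::var(y),
              cv = stats::sd(y) / mean(y))
  if (!is.null(pheno_reps)) {
    fit <- stats::lm(stats::reformulate("strain_id", trait), data = pheno_reps)
    # a perfect fit is the degenerate case flagged below; silence the F-test
    # reliability warning it triggers
    av <- suppressWarnings(stats::anova(fit))
    ms_strain <- av$`Mean Sq`[1]
    ms_error <- av$`Mean Sq`[2]
    n_reps <- mean(table(pheno_reps$strain_id))
    degenerate <- !is.finite(av$`F value`[1])
    out$anova <- list(
      F = if (degenerate) NA_real_ else av$`F value`[1],
      df = av$Df[1:2],
      p = if (degenerate) NA_real_ else av$`Pr(>F)`[1],
      variance_component = max(0, (ms_strain - ms_error) / n_reps),
      degenerate = degenerate)
  }
  num <- phenotypes[vapply(phenotypes, is.numeric, TRUE)]
  out$trait_correlations <- stats::cor(as.matrix(num))
  out
}

#' Hypergeometric category enrichment per module
#'
#' Upper-tail hypergeometric test of the overlap between each module and
#' each category given the module size, category size and universe size;
#' BH fdr across all tested (module, category) pairs.
#'
#' @param assignment Named gene -> module vector.
#' @param categories Data frame `gene_id`, `category` (flat labels; a gene
#'   may appear under several categories).
#' @param universe Gene universe (default: all genes in `assignment`).
#' @return Data frame module, category, overlap, module_size, category_size,
#'   universe_size, p, fdr.
#' @export
category_enrichment <- function(assignment, categories, universe = NULL) {
  if (is.null(universe)) universe <- names(assignment)
  categories <- categories[categories$gene_id %in% universe, , drop = FALSE]
  if (nrow(categories) == 0L) {
    stop("no category labels intersect the universe", call. = FALSE)
  }
  n_univ <- length(universe)
  cat_genes <- split(categories$gene_id, categories$category)
  mods <- setdiff(sort(unique(assignment)), "unassigned")
  rows <- list()
  for (m in mods) {
    mg <- intersect(names(assignment)[assignment == m], universe)
    for (ct in names(cat_genes)) {
      cg <- unique(cat_genes[[ct]])
      ov <- length(intersect(mg, cg))
      p <- stats::phyper(ov - 1L, length(cg), n_univ - length(cg),
                         length(mg), lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        module = m, category = ct, overlap = ov, module_size = length(mg),
        category_size = length(cg), universe_size = n_univ, p = p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Assemble a plain-text analysis report
#'
#' One Markdown summary of the significant genes, clusters, modules and
#' cross-network edges in a result bundle (see [run_pipeline()]).
#'
#' @param bundle A [run_pipeline()] result.
#' @param path Optional output file.
#' @return The report lines, invisibly (written to `path` when given).
#' @export
render_report <- function(bundle, path = NULL) {
  ln <- c("# pavnet run report", "",
          sprintf("- strains: %d; symbiont genes: %d; host genes: %d",
                  ncol(bundle$presence$expression),
                  nrow(bundle$symbiont_counts$counts),
                  nrow(bundle$host_counts$counts)),
          sprintf("- shoot biomass: CV = %.3f, variance = %.4f",
                  bundle$phenotype_summary$cv,
                  bundle$phenotype_summary$variance))
  st <- table(bundle$expression_status$status)
  ln <- c(ln, sprintf("- expression status: %s",
                      paste(names(st), st, sep = "=", collapse = ", ")),
          sprintf("- on/off genes: %d; trait-correlated: %d",
                  length(bundle$onoff_genes),
                  sum(bundle$gene_trait$significant, na.rm = TRUE)),
          sprintf("- syntenic clusters: %d (sizes %s)",
                  length(bundle$clusters$clusters),
                  paste(vapply(bundle$clusters$clusters,
                               function(cl) length(cl$members), 0L),
                        collapse = ",")))
  for (org in c("symbiont", "host")) {
    net <- bundle$networks[[org]]
    if (is.null(net)) next
    sig <- bundle$module_trait[[org]]
    sig <- sig[sig$significant & sig$trait == bundle$config$trait, ]
    ln <- c(ln, sprintf("- %s network: beta=%d, %d modules; trait-linked: %s",
                        org, net$beta, length(net$module_sizes),
                        if (nrow(sig)) paste0(sig$module, " (r=",
                                              round(sig$r, 2), ")",
                                              collapse = ", ") else "none"))
  }
  edges <- bundle$cross_edges[bundle$cross_edges$passes_cut, , drop = FALSE]
  ln <- c(ln, sprintf("- cross-network edges (|r| > %.2f): %d",
                      bundle$config$r_cut_cross, nrow(edges)))
  if (nrow(edges)) {
    ln <- c(ln, paste0("  - ", edges$host_module, " ~ ",
                       edges$symbiont_module, ": r = ", round(edges$r, 2)))
  }
  if (!is.null(path)) writeLines(ln, path)
  invisible(ln)
}
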