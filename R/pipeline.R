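#' Run the full analysis pipeline
#'
#' Executes the stages in order — input validation, expression preparation
#' (logCPM, expression-status classes, strain means, host variable-gene
#' selection, PCA), PAV discovery (presence calls, on/off filter, trait
#' correlation, optional sequence confirmation + 100%-agreement rule),
#' syntenic clustering and pangenome partitioning, coexpression networks for
#' both organisms, and the association report (module-trait, cross-network,
#' phenotype summary, enrichment). Deterministic given its inputs; any stage
#' error aborts tagged with the stage name.
#'
#' @param dataset A dataset list as returned by [simulate_dataset()] (or
#'   assembled from the readers: `symbiont_counts`, `host_counts`, `samples`,
#'   `phenotypes`, `pheno_reps`, `annotation`, `gene_groups`, optionally
#'   `assemblies` with `store` and `ref_seqs`, optionally `categories`).
#' @param config A [analysis_config()].
#' @param out_dir If non-NULL, write every intermediate table plus the run
#'   manifest there.
#' @param network_max_genes Size guard forwarded to
#'   [build_coexpression_network()].
#' @return A result bundle (list) with elements per stage and `stages`, the
#'   executed stage names.
#' @export
run_pipeline <- function(dataset, config = analysis_config(), out_dir = NULL,
                         network_max_genes = 10000L) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage %s: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  bundle <- list(config = config, stages = character(0))

  stage("data_io", {
    stopifnot(inherits(dataset$symbiont_counts, "counts_matrix"),
              inherits(dataset$host_counts, "counts_matrix"))
    dataset$samples <- validate_sample_sheet(dataset$samples)
    validate_config(config)
    bundle$symbiont_counts <- dataset$symbiont_counts
    bundle$host_counts <- dataset$host_counts
    bundle$samples <- dataset$samples
    bundle$phenotypes <- dataset$phenotypes
  })
  bundle$stages <- c(bundle$stages, "data_io")

  stage("expression_prep", {
    bundle$logcpm <- list(symbiont = logcpm(dataset$symbiont_counts),
                          host = logcpm(dataset$host_counts))
    bundle$expression_status <- classify_expression_status(
      dataset$symbiont_counts, dataset$samples, floor = config$cpm_floor)
    bundle$strain_means <- list(
      symbiont = strain_means(bundle$logcpm$symbiont, dataset$samples),
      host = strain_means(bundle$logcpm$host, dataset$samples))
    n_var <- min(config$n_variable_host_genes,
                 nrow(bundle$strain_means$host))
    bundle$host_variable_genes <- select_variable_genes(
      bundle$strain_means$host, n_var)
    bundle$pca <- list(
      symbiont = pca_strains(bundle$strain_means$symbiont),
      host = pca_strains(bundle$strain_means$host[
        bundle$host_variable_genes, , drop = FALSE]))
  })
  bundle$stages <- c(bundle$stages, "expression_prep")

  stage("pav_discovery", {
    expr_presence <- call_presence_from_expression(
      dataset$symbiont_counts, dataset$samples, config)
    bundle$presence <- list(expression = expr_presence)
    bundle$onoff_genes <- filter_onoff(expr_presence, config)
    bundle$gene_trait <- correlate_presence_with_trait(
      expr_presence[bundle$onoff_genes, , drop = FALSE],
      dataset$phenotypes, config,
      expr = bundle$strain_means$symbiont)
    sig <- bundle$gene_trait$unit_id[bundle$gene_trait$significant]
    bundle$candidate_genes <- sig
    if (!is.null(dataset$assemblies)) {
      seq_res <- find_sequence_presence(
        dataset$assemblies$ref_seqs[sig], dataset$assemblies$store, config)
      bundle$sequence_hits <- seq_res$hits
      bundle$presence$sequence <- seq_res$presence
      agree <- agreement_filter(
        expr_presence[sig, colnames(seq_res$presence), drop = FALSE],
        seq_res$presence)
      bundle$agreement <- agree
      bundle$candidate_genes <- agree$confirmed
    }
  })
  bundle$stages <- c(bundle$stages, "pav_discovery")

  stage("synteny_pangenome", {
    bundle$clusters <- detect_clusters(dataset$annotation,
                                       bundle$candidate_genes,
                                       gap = config$cluster_gap_bp)
    if (length(bundle$clusters$clusters)) {
      bundle$cluster_presence <- cluster_presence(
        bundle$clusters$clusters, bundle$presence$expression)
      bundle$cluster_trait <- cluster_trait_ttest(
        bundle$cluster_presence, dataset$phenotypes, config$trait,
        var_equal = config$ttest_var_equal)
    }
    if (!is.null(dataset$gene_groups)) {
      rep_of <- stats::setNames(dataset$annotation$replicon_id,
                                dataset$annotation$gene_id)
      bundle$pangenome <- classify_pangenome(dataset$gene_groups, config,
                                             replicons = rep_of)
    }
  })
  bundle$stages <- c(bundle$stages, "synteny_pangenome")

  stage("coexpression", {
    net_genes <- prefilter_for_network(dataset$symbiont_counts,
                                       config$median_count_floor)
    bundle$network_genes <- list(
      symbiont = net_genes,
      host = bundle$host_variable_genes)
    bundle$networks <- list(
      symbiont = build_coexpression_network(
        bundle$strain_means$symbiont[net_genes, , drop = FALSE], config,
        prefix = "rM", max_genes = network_max_genes),
      host = build_coexpression_network(
        bundle$strain_means$host[bundle$host_variable_genes, , drop = FALSE],
        config, prefix = "pM", max_genes = network_max_genes))
  })
  bundle$stages <- c(bundle$stages, "coexpression")

  stage("association_report", {
    bundle$module_trait <- list(
      symbiont = module_trait_correlation(bundle$networks$symbiont$eigengenes,
                                          dataset$phenotypes, config),
      host = module_trait_correlation(bundle$networks$host$eigengenes,
                                      dataset$phenotypes, config))
    bundle$cross_edges <- cross_network_correlation(
      bundle$networks$host$eigengenes, bundle$networks$symbiont$eigengenes,
      config, trait_cor = list(host = bundle$module_trait$host,
                               symbiont = bundle$module_trait$symbiont))
    bundle$phenotype_summary <- phenotype_summary(
      dataset$phenotypes, dataset$pheno_reps, config$trait)
    categories <- dataset$categories
    if (is.null(categories) && !is.null(dataset$truth)) {
      categories <- dataset$truth$categories
    }
    if (!is.null(categories)) {
      bundle$enrichment <- category_enrichment(
        bundle$networks$symbiont$assignment, categories)
    }
  })
  bundle$stages <- c(bundle$stages, "association_report")

  if (!is.null(out_dir)) {
    tables <- list(
      gene_trait = bundle$gene_trait,
      expression_presence = bundle$presence$expression,
      symbiont_modules = data.frame(
        gene_id = names(bundle$networks$symbiont$assignment),
        module = unname(bundle$networks$symbiont$assignment)),
      host_modules = data.frame(
        gene_id = names(bundle$networks$host$assignment),
        module = unname(bundle$networks$host$assignment)),
      module_trait_symbiont = bundle$module_trait$symbiont,
      module_trait_host = bundle$module_trait$host,
      cross_edges = bundle$cross_edges)
    if (!is.null(bundle$cluster_trait)) {
      tables$cluster_trait <- bundle$cluster_trait
      tables$cluster_presence <- bundle$cluster_presence
    }
    if (!is.null(bundle$pangenome)) tables$pangenome <- bundle$pangenome$classes
    if (!is.null(bundle$enrichment)) tables$enrichment <- bundle$enrichment
    if (!is.null(bundle$sequence_hits)) tables$sequence_hits <- bundle$sequence_hits
    write_results(tables, out_dir, config)
    render_report(bundle, file.path(out_dir, "report.md"))
    manifest_path <- file.path(out_dir, "manifest.json")
    manifest <- jsonlite::read_json(manifest_path)
    manifest$stages <- bundle$stages
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  bundle
}

#' Adjusted Rand index by pair counting
#'
#' `ARI = (sum_ij C(n_ij,2) - E) / (max - E)` with the usual expectation and
#' maximum from the contingency-table margins; 1 for identical partitions,
#' ~0 for independent ones.
#'
#' @param a,b Two label vectors over the same items.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / (maximum - expected)
}

#' Score a pipeline run against recorded ground truth
#'
#' Presence-call accuracy (fraction of gene x strain entries matching the
#' planted truth), planted-cluster recovery (per-cluster best Jaccard of
#' member sets against detected clusters, with precision/recall at Jaccard
#' >= 0.5), module adjusted Rand index per organism over the network genes,
#' and gene-trait association precision/recall against the planted
#' trait-linked gene set.
#'
#' @param bundle A [run_pipeline()] result.
#' @param truth The dataset's `truth` element.
#' @return An `evaluation_report` list; all metrics lie in [0, 1] (NA when a
#'   component was absent from the run).
#' @export
evaluate_against_truth <- function(bundle, truth) {
  called <- bundle$presence$expression
  genes <- intersect(rownames(called), rownames(truth$presence))
  strains <- intersect(colnames(called), colnames(truth$presence))
  if (!length(genes) || !length(strains)) {
    stop("truth and bundle share no genes/strains", call. = FALSE)
  }
  acc <- mean(called[genes, strains] == truth$presence[genes, strains])

  planted <- truth$cluster_members[
    truth$clusters$cluster_id[truth$clusters$effect != 0]]
  detected <- lapply(bundle$clusters$clusters, function(cl) cl$members)
  jac <- function(x, y) length(intersect(x, y)) / length(union(x, y))
  cluster_jaccard <- vapply(planted, function(p) {
    if (!length(detected)) return(0)
    max(vapply(detected, jac, 0, x = p))
  }, 0)
  recall <- if (length(planted)) mean(cluster_jaccard >= 0.5) else NA_real_
  precision <- if (length(detected)) {
    mean(vapply(detected, function(d)
      max(c(0, vapply(truth$cluster_members, jac, 0, x = d))) >= 0.5, TRUE))
  } else NA_real_

  ari <- c(symbiont = NA_real_, host = NA_real_)
  truth_mod <- list(symbiont = truth$symbiont_modules$membership,
                    host = truth$host_modules$membership)
  for (org in c("symbiont", "host")) {
    net <- bundle$networks[[org]]
    if (is.null(net) || is.null(truth_mod[[org]])) next
    g <- intersect(names(net$assignment), names(truth_mod[[org]]))
    ari[org] <- adjusted_rand_index(net$assignment[g], truth_mod[[org]][g])
  }

  true_genes <- unlist(planted, use.names = FALSE)
  called_genes <- bundle$gene_trait$unit_id[bundle$gene_trait$significant]
  assoc_recall <- if (length(true_genes))
    mean(true_genes %in% called_genes) else NA_real_
  assoc_precision <- if (length(called_genes))
    mean(called_genes %in% true_genes) else NA_real_

  out <- list(presence_accuracy = acc,
              cluster_jaccard = cluster_jaccard,
              cluster_recall = recall,
              cluster_precision = precision,
              module_ari = ari,
              trait_assoc_recall = assoc_recall,
              trait_assoc_precision = assoc_precision)
  class(out) <- "evaluation_report"
  out
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation against planted truth\n")
  cat(sprintf("  presence-call accuracy : %.4f\n", x$presence_accuracy))
  if (length(x$cluster_jaccard)) {
    cat(sprintf("  cluster Jaccard        : %s\n",
                paste(names(x$cluster_jaccard),
                      round(x$cluster_jaccard, 2), sep = "=",
                      collapse = " ")))
  }
  cat(sprintf("  cluster precision/recall: %.2f / %.2f\n",
              x$cluster_precision, x$cluster_recall))
  cat(sprintf("  module ARI             : symbiont=%.3f host=%.3f\n",
              x$module_ari["symbiont"], x$module_ari["host"]))
  cat(sprintf("  trait assoc prec/recall: %.2f / %.2f\n",
              x$trait_assoc_precision, x$trait_assoc_recall))
  invisible(x)
}
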