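#' Prefilter genes for network construction
#'
#' Drops genes whose median raw count across all samples falls below the
#' floor (default 10), the usual guard before coexpression analysis.
#'
#' @param cm A [counts_matrix()].
#' @param floor Median count floor.
#' @return Character vector of retained gene ids.
#' @export
prefilter_for_network <- function(cm, floor = 10) {
  med <- apply(cm$counts, 1, stats::median)
  rownames(cm$counts)[med >= floor]
}

network_adjacency <- function(cmat, beta, signed = FALSE) {
  s <- if (signed) (1 + cmat) / 2 else abs(cmat)
  a <- s^beta
  diag(a) <- 0
  a
}

#' Choose the soft-threshold power by scale-free fit
#'
#' For each candidate power, computes the connectivity distribution of the
#' resulting adjacency and the R^2 of the log-log regression of bin frequency
#' on mean bin connectivity (10 bins). Picks the smallest power reaching the
#' target R^2, falling back to the power maximizing R^2 when none does.
#'
#' @param sm Gene x strain matrix of strain means.
#' @param config A [analysis_config()] (`soft_power_grid`, `scale_free_r2`,
#'   `signed_network`).
#' @param nbreaks Histogram bins for the fit.
#' @return List with `beta` (chosen power) and `fit_table` (power, r2,
#'   mean_k, median_k, max_k).
#' @export
pick_soft_power <- function(sm, config = analysis_config(), nbreaks = 10) {
  stopifnot(ncol(sm) >= 4)
  v <- apply(sm, 1, stats::var)
  if (all(v == 0)) stop("constant expression matrix", call. = FALSE)
  cmat <- stats::cor(t(sm[v > 0, , drop = FALSE]))
  rows <- lapply(config$soft_power_grid, function(beta) {
    a <- network_adjacency(cmat, beta, config$signed_network)
    k <- rowSums(a)
    data.frame(power = beta, r2 = scale_free_r2(k, nbreaks),
               mean_k = mean(k), median_k = stats::median(k), max_k = max(k))
  })
  fit <- do.call(rbind, rows)
  ok <- which(fit$r2 >= config$scale_free_r2)
  beta <- if (length(ok)) fit$power[ok[1]] else fit$power[which.max(fit$r2)]
  list(beta = beta, fit_table = fit)
}

# Signed scale-free fit: R^2 of log10(frequency) ~ log10(mean connectivity)
# over connectivity bins, negated when the slope is positive (the standard
# convention: a scale-free topology requires a decreasing frequency).
scale_free_r2 <- function(k, nbreaks = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 3L) return(0)
  bins <- cut(k, nbreaks)
  freq <- tapply(k, bins, length)
  kmean <- tapply(k, bins, mean)
  keep <- !is.na(freq) & freq > 0
  if (sum(keep) < 3L) return(0)
  fit <- stats::lm(log10(freq[keep]) ~ log10(kmean[keep]))
  r2 <- summary(fit)$r.squared
  if (stats::coef(fit)[2] > 0) -r2 else r2
}

#' Topological overlap matrix
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj` over `u != i, j`, unit diagonal: similarity of
#' two genes by direct adjacency plus shared neighborhood.
#'
#' @param a Symmetric adjacency matrix in [0, 1] (diagonal ignored).
#' @return TOM matrix (same dimnames, unit diagonal).
#' @export
compute_tom <- function(a) {
  stopifnot(is.matrix(a), nrow(a) == ncol(a))
  if (max(abs(a - t(a))) > 1e-12) stop("adjacency must be symmetric",
                                       call. = FALSE)
  diag(a) <- 0
  k <- rowSums(a)
  l <- a %*% a                                 # includes u = i and u = j terms
  # with diag(a) = 0, a_ii a_ij and a_ij a_jj are zero, so l is already the
  # u != i, j sum
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Cut the TOM dendrogram into modules
#'
#' Average-linkage hierarchical clustering of `1 - TOM`, cut at the given
#' quantile of merge heights; clusters below the minimum size become
#' `unassigned`. Module labels are ordered by size (module 1 largest), with a
#' configurable prefix.
#'
#' @param tom TOM matrix.
#' @param min_module_size Smallest reported module.
#' @param cut_height_quantile Quantile of merge heights at which to cut.
#' @param prefix Module label prefix (e.g. `"rM"` for rhizobium, `"pM"` for
#'   plant).
#' @return Named character vector gene -> module label (or `"unassigned"`).
#' @export
cut_modules <- function(tom, min_module_size = 10,
                        cut_height_quantile = 0.99, prefix = "M") {
  d <- stats::as.dist(1 - tom)
  hc <- stats::hclust(d, method = "average")
  h <- stats::quantile(hc$height, cut_height_quantile)
  raw <- stats::cutree(hc, h = h)
  relabel_by_size(raw, min_module_size, prefix, names = rownames(tom))
}

relabel_by_size <- function(raw, min_module_size, prefix, names = NULL) {
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_module_size]
  assignment <- rep("unassigned", length(raw))
  if (length(keep)) {
    ord <- keep[order(-sizes[keep], as.integer(keep))]
    new <- stats::setNames(sprintf("%s%02d", prefix, seq_along(ord)), ord)
    hit <- as.character(raw) %in% ord
    assignment[hit] <- new[as.character(raw)[hit]]
  } else {
    warning("all genes unassigned at this cut", call. = FALSE)
  }
  names(assignment) <- if (is.null(names)) names(raw) else names
  assignment
}

#' Module eigengenes
#'
#' Per module: z-score each member gene across strains and take the first
#' left singular vector over strains (unit norm), sign-oriented so the mean
#' correlation with member genes is nonnegative. Variance explained is the
#' leading squared singular value over the total.
#'
#' @param sm Gene x strain matrix of strain means.
#' @param assignment Named gene -> module vector ([cut_modules()]).
#' @return List with `eigengenes` (module x strain matrix),
#'   `variance_explained` (named per module), and `assignment`.
#' @export
module_eigengenes <- function(sm, assignment) {
  mods <- setdiff(sort(unique(assignment)), "unassigned")
  if (!length(mods)) stop("no modules to summarize", call. = FALSE)
  me <- matrix(NA_real_, length(mods), ncol(sm),
               dimnames = list(mods, colnames(sm)))
  ve <- stats::setNames(numeric(length(mods)), mods)
  for (m in mods) {
    genes <- names(assignment)[assignment == m]
    x <- sm[genes, , drop = FALSE]
    x <- t(scale(t(x)))                       # z-score genes across strains
    x[is.na(x)] <- 0                          # constant genes contribute zero
    sv <- svd(x, nu = 0, nv = 1)
    e <- sv$v[, 1]
    if (mean(stats::cor(e, t(x))[stats::sd(e) > 0], na.rm = TRUE) < 0) e <- -e
    me[m, ] <- e
    tot <- sum(sv$d^2)
    ve[m] <- if (tot > 0) sv$d[1]^2 / tot else 0
  }
  list(eigengenes = me, variance_explained = ve, assignment = assignment)
}

#' Merge modules with similar eigengenes
#'
#' Iteratively merges the module pair with the highest eigengene correlation
#' above the threshold (signed correlation, so anti-correlated modules are
#' not merged), recomputes eigengenes, and repeats to fixpoint. Labels are
#' re-ordered by size afterwards.
#'
#' @param sm Gene x strain matrix of strain means.
#' @param me Result of [module_eigengenes()].
#' @param merge_cor Correlation above which modules merge (default 0.75).
#' @param min_module_size Passed through to relabeling.
#' @param prefix Module label prefix.
#' @return Updated [module_eigengenes()] result.
#' @export
merge_similar_modules <- function(sm, me, merge_cor = 0.75,
                                  min_module_size = 10, prefix = "M") {
  assignment <- me$assignment
  repeat {
    mods <- rownames(me$eigengenes)
    if (length(mods) < 2L) break
    cc <- stats::cor(t(me$eigengenes))
    diag(cc) <- -Inf
    if (max(cc) <= merge_cor) break
    pair <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    from <- mods[max(pair)]
    into <- mods[min(pair)]
    assignment[assignment == from] <- into
    me <- module_eigengenes(sm, assignment)
  }
  sizes <- table(assignment[assignment != "unassigned"])
  raw <- match(assignment, names(sort(sizes, decreasing = TRUE)))
  raw[is.na(raw)] <- 0L
  assignment <- relabel_by_size(raw, min_module_size, prefix,
                                names = names(assignment))
  module_eigengenes(sm, assignment)
}

#' Build a weighted coexpression network end to end
#'
#' Soft-power selection, adjacency, TOM, dendrogram cut, eigengenes, and the
#' eigengene-similarity merge, from a strain-mean expression matrix.
#'
#' @param sm Gene x strain matrix of strain means.
#' @param config A [analysis_config()].
#' @param prefix Module label prefix.
#' @param keep_tom Keep the TOM matrix in the result (memory-heavy for large
#'   gene sets).
#' @param max_genes Guard against accidental genome-scale TOMs; raise it
#'   deliberately for big runs.
#' @return A `coexpression_network`: list with `beta`, `fit_table`,
#'   `assignment`, `eigengenes`, `variance_explained`, `module_sizes`, and
#'   optionally `tom`.
#' @export
build_coexpression_network <- function(sm, config = analysis_config(),
                                       prefix = "M", keep_tom = FALSE,
                                       max_genes = 10000L) {
  if (nrow(sm) > max_genes) {
    stop("gene set exceeds max_genes guard (", nrow(sm), " > ", max_genes,
         "); raise max_genes explicitly for a run this size", call. = FALSE)
  }
  pw <- pick_soft_power(sm, config)
  cmat <- stats::cor(t(sm))
  cmat[is.na(cmat)] <- 0                       # constant genes: no edges
  a <- network_adjacency(cmat, pw$beta, config$signed_network)
  tom <- compute_tom(a)
  assignment <- cut_modules(tom, config$min_module_size,
                            config$cut_height_quantile, prefix)
  if (all(assignment == "unassigned")) {
    warning("no module met the size threshold", call. = FALSE)
    return(structure(list(beta = pw$beta, fit_table = pw$fit_table,
                          assignment = assignment, eigengenes = NULL,
                          variance_explained = NULL,
                          module_sizes = integer(0)),
                     class = "coexpression_network"))
  }
  me <- module_eigengenes(sm, assignment)
  me <- merge_similar_modules(sm, me, config$merge_cor,
                              config$min_module_size, prefix)
  net <- list(beta = pw$beta, fit_table = pw$fit_table,
              assignment = me$assignment, eigengenes = me$eigengenes,
              variance_explained = me$variance_explained,
              module_sizes = sort(table(me$assignment[
                me$assignment != "unassigned"]), decreasing = TRUE))
  if (keep_tom) net$tom <- tom
  class(net) <- "coexpression_network"
  net
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("coexpression_network: %d genes, beta = %d, %d modules (%d unassigned)\n",
              length(x$assignment), x$beta, length(x$module_sizes),
              sum(x$assignment == "unassigned")))
  if (length(x$module_sizes)) {
    cat("  sizes:", paste(names(x$module_sizes), x$module_sizes, sep = "=",
                          collapse = " "), "\n")
  }
  invisible(x)
}
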