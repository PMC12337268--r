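#' Log2 counts per million
#'
#' `log2((count + prior) / (lib_size + 2 * prior) * 1e6)`, the moderated
#' logCPM used throughout: strictly increasing in the count and strictly
#' decreasing in the library size, finite for zero counts.
#'
#' @param cm A [counts_matrix()].
#' @param prior Prior count (default 0.5).
#' @return Numeric gene x sample matrix on the log2 scale with attribute
#'   `prior`.
#' @export
logcpm <- function(cm, prior = 0.5) {
  stopifnot(inherits(cm, "counts_matrix"), prior >= 0)
  if (any(cm$lib_sizes == 0)) {
    stop("zero library size for sample ",
         names(cm$lib_sizes)[cm$lib_sizes == 0][1], call. = FALSE)
  }
  out <- log2(sweep(cm$counts + prior, 2, cm$lib_sizes + 2 * prior, "/") * 1e6)
  attr(out, "prior") <- prior
  out
}

#' Raw counts per million
#'
#' @param cm A [counts_matrix()].
#' @return Numeric gene x sample CPM matrix.
#' @export
cpm <- function(cm) {
  stopifnot(inherits(cm, "counts_matrix"))
  sweep(cm$counts, 2, cm$lib_sizes / 1e6, "/")
}

#' Classify per-gene expression status across strains
#'
#' A gene is `common` when its count reaches the floor in every replicate of
#' every strain, `never` when it stays below the floor in every replicate of
#' every strain, and `variable` otherwise (the on/off candidates).
#'
#' @param cm A [counts_matrix()].
#' @param samples Sample sheet data frame.
#' @param floor Count floor (default 10).
#' @return List with `status` (named factor gene -> common/never/variable) and
#'   `expressed` (logical gene x strain matrix: floor reached in every
#'   replicate of that strain).
#' @export
classify_expression_status <- function(cm, samples, floor = 10) {
  stopifnot(inherits(cm, "counts_matrix"))
  samples <- validate_sample_sheet(samples)
  strains <- unique(samples$strain_id)
  above <- cm$counts >= floor
  per_strain <- function(f) {
    out <- vapply(strains, function(s) {
      idx <- samples$sample_id[samples$strain_id == s]
      f(above[, idx, drop = FALSE], length(idx))
    }, logical(nrow(cm$counts)))
    matrix(out, nrow = nrow(cm$counts),
           dimnames = list(rownames(cm$counts), strains))
  }
  all_above <- per_strain(function(x, k) rowSums(x) == k)
  any_above <- per_strain(function(x, k) rowSums(x) > 0L)
  status <- rep("variable", nrow(cm$counts))
  status[rowSums(all_above) == length(strains)] <- "common"
  status[rowSums(any_above) == 0L] <- "never"
  status <- factor(status, levels = c("common", "never", "variable"))
  names(status) <- rownames(cm$counts)
  list(status = status, expressed = all_above)
}

#' Per-strain means of a sample-level matrix
#'
#' Arithmetic mean over each strain's replicates, per gene: logCPM is averaged
#' on the log scale (strain means of per-sample logCPM).
#'
#' @param mat Gene x sample numeric matrix (columns named by sample id).
#' @param samples Sample sheet data frame.
#' @return Gene x strain matrix, strains in first-appearance order.
#' @export
strain_means <- function(mat, samples) {
  samples <- validate_sample_sheet(samples)
  stopifnot(all(samples$sample_id %in% colnames(mat)))
  strains <- unique(samples$strain_id)
  out <- vapply(strains, function(s) {
    idx <- samples$sample_id[samples$strain_id == s]
    rowMeans(mat[, idx, drop = FALSE])
  }, numeric(nrow(mat)))
  matrix(out, nrow = nrow(mat), dimnames = list(rownames(mat), strains))
}

#' Select the most variable genes
#'
#' Top `n` genes by variance across columns; ties broken by gene id
#' (lexicographic) for determinism.
#'
#' @param mat Gene x strain (or gene x sample) numeric matrix.
#' @param n Number of genes to keep.
#' @return Character vector of selected gene ids.
#' @export
select_variable_genes <- function(mat, n = 5000) {
  stopifnot(n <= nrow(mat), !is.null(rownames(mat)))
  v <- apply(mat, 1, stats::var)
  ord <- order(-v, rownames(mat))
  rownames(mat)[ord[seq_len(n)]]
}

#' PCA over strains
#'
#' Strains are the observations; the decomposition is of the covariance of
#' the (gene-centered) strain profiles. Variance explained is eigenvalue over
#' trace; a degenerate all-zero covariance reports 0 explained.
#'
#' @param mat Gene x strain numeric matrix.
#' @param center,scale. Passed to the underlying decomposition (genes are
#'   centered by default and not scaled).
#' @param n_components Number of components to keep (default all).
#' @return List with `scores` (strain x component), `variance_explained`,
#'   and `loadings` (gene x component).
#' @export
pca_strains <- function(mat, center = TRUE, scale. = FALSE,
                        n_components = NULL) {
  stopifnot(ncol(mat) >= 2)
  if (isTRUE(scale.)) {
    keep <- apply(mat, 1, stats::var) > 0
    mat <- mat[keep, , drop = FALSE]
  }
  x <- t(mat)                                 # strains x genes
  p <- stats::prcomp(x, center = center, scale. = scale.)
  ev <- p$sdev^2
  total <- sum(ev)
  ve <- if (total > 0) ev / total else rep(0, length(ev))
  k <- min(if (is.null(n_components)) length(ev) else n_components,
           length(ev))
  if (!is.null(n_components) && n_components > length(ev)) {
    stop("requested more components than available", call. = FALSE)
  }
  list(scores = p$x[, seq_len(k), drop = FALSE],
       variance_explained = ve[seq_len(k)],
       loadings = p$rotation[, seq_len(k), drop = FALSE])
}

#' Dispersion summary by pangenome class
#'
#' Mean and variance of strain-mean expression per gene, summarized by
#' core/shell/cloud class: a descriptive table of expression level and
#' among-strain dispersion per compartment.
#'
#' @param sm Gene x strain matrix of strain means (logCPM scale).
#' @param classes Named character vector gene -> class.
#' @return Data frame with per-class gene counts and median expression mean
#'   and among-strain variance.
#' @export
dispersion_summary <- function(sm, classes) {
  common <- intersect(rownames(sm), names(classes))
  sm <- sm[common, , drop = FALSE]
  cls <- classes[common]
  mu <- rowMeans(sm)
  v <- apply(sm, 1, stats::var)
  out <- do.call(rbind, lapply(split(seq_along(cls), cls), function(idx) {
    data.frame(n_genes = length(idx), median_mean = stats::median(mu[idx]),
               median_var = stats::median(v[idx]))
  }))
  data.frame(class = rownames(out), out, row.names = NULL)
}
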