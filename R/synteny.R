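#' Detect syntenic clusters among candidate genes
#'
#' Sorts candidates per replicon by start and chains adjacent candidates
#' while the inter-feature gap (`next start - current end - 1`) stays at or
#' below `gap` bp. Chains of two or more genes become clusters; the rest are
#' singletons. Order-invariant: the input candidate order never matters.
#'
#' @param ann Annotation data frame (one reference strain; see
#'   [read_annotation()]).
#' @param candidates Character vector of candidate gene ids.
#' @param gap Maximum inter-feature gap in bp (inclusive; default 3000, the
#'   3-kb rule).
#' @return List with `clusters` (list of `syntenic_cluster`: cluster_id,
#'   replicon_id, members ordered by start, span) and `singletons`.
#' @export
detect_clusters <- function(ann, candidates, gap = 3000) {
  missing <- setdiff(candidates, ann$gene_id)
  if (length(missing)) {
    stop("candidate without coordinates: ", missing[1], call. = FALSE)
  }
  a <- ann[ann$gene_id %in% candidates, , drop = FALSE]
  clusters <- list()
  singletons <- character(0)
  for (rep_id in unique(a$replicon_id)) {
    ar <- a[a$replicon_id == rep_id, , drop = FALSE]
    ar <- ar[order(ar$start, ar$end, ar$gene_id), , drop = FALSE]
    if (nrow(ar) == 0L) next
    chain_id <- cumsum(c(1L, as.integer(
      ar$start[-1L] - ar$end[-nrow(ar)] - 1L > gap)))
    for (ch in split(seq_len(nrow(ar)), chain_id)) {
      if (length(ch) >= 2L) {
        clusters[[length(clusters) + 1L]] <- list(
          replicon_id = rep_id,
          members = ar$gene_id[ch],
          span = max(ar$end[ch]) - min(ar$start[ch]) + 1L)
      } else {
        singletons <- c(singletons, ar$gene_id[ch])
      }
    }
  }
  if (length(clusters)) {
    ord <- order(vapply(clusters, function(cl) cl$replicon_id, ""),
                 vapply(clusters, function(cl) cl$members[1], ""))
    clusters <- clusters[ord]
    for (i in seq_along(clusters)) {
      clusters[[i]]$cluster_id <- sprintf("C%d", i)
      class(clusters[[i]]) <- "syntenic_cluster"
    }
  }
  list(clusters = clusters, singletons = sort(singletons))
}

#' @export
print.syntenic_cluster <- function(x, ...) {
  cat(sprintf("%s (%s): %d genes, span %d bp [%s]\n", x$cluster_id,
              x$replicon_id, length(x$members), x$span,
              paste(x$members, collapse = ", ")))
  invisible(x)
}

#' Collapse gene presence to cluster presence
#'
#' A cluster is present in a strain when all member genes are present
#' (`rule = "all"`, the default) or when at least the given fraction of
#' members is present (`rule` a number in (0, 1]).
#'
#' @param clusters Cluster list from [detect_clusters()].
#' @param presence Logical gene x strain matrix covering all members.
#' @param rule `"all"` or a fraction.
#' @return Logical cluster x strain matrix.
#' @export
cluster_presence <- function(clusters, presence, rule = "all") {
  stopifnot(length(clusters) > 0)
  frac <- if (identical(rule, "all")) 1 else {
    stopifnot(is.numeric(rule), rule > 0, rule <= 1)
    rule
  }
  out <- t(vapply(clusters, function(cl) {
    miss <- setdiff(cl$members, rownames(presence))
    if (length(miss)) stop("no presence call for member ", miss[1],
                           call. = FALSE)
    sub <- presence[cl$members, , drop = FALSE]
    colMeans(sub) >= frac
  }, logical(ncol(presence))))
  rownames(out) <- vapply(clusters, function(cl) cl$cluster_id, "")
  out
}

#' Test cluster presence against a trait by independent t test
#'
#' Two-sided Student's t on strain-mean trait values between the
#' cluster-present and cluster-absent strain groups; pooled variance by
#' default, Welch when `var_equal = FALSE`. A group of fewer than two strains
#' yields a degenerate record with NA statistics.
#'
#' @param cl_presence Logical cluster x strain matrix.
#' @param phenotypes Phenotype data frame.
#' @param trait Trait column to test.
#' @param var_equal Pooled-variance t (default) vs Welch.
#' @return Data frame unit_id, n_present, n_absent, mean_present,
#'   mean_absent, stat, df, p, fdr, degenerate.
#' @export
cluster_trait_ttest <- function(cl_presence, phenotypes,
                                trait = "shoot_biomass", var_equal = TRUE) {
  y <- trait_by_strain(phenotypes, colnames(cl_presence), trait)
  rows <- lapply(rownames(cl_presence), function(id) {
    x <- cl_presence[id, ]
    y1 <- y[x]
    y0 <- y[!x]
    if (length(y1) < 2L || length(y0) < 2L) {
      return(data.frame(unit_id = id, n_present = length(y1),
                        n_absent = length(y0), mean_present = mean(y1),
                        mean_absent = mean(y0), stat = NA_real_,
                        df = NA_real_, p = NA_real_, degenerate = TRUE,
                        stringsAsFactors = FALSE))
    }
    n1 <- length(y1); n0 <- length(y0)
    if (var_equal) {
      sp2 <- ((n1 - 1) * stats::var(y1) + (n0 - 1) * stats::var(y0)) /
        (n1 + n0 - 2)
      se <- sqrt(sp2 * (1 / n1 + 1 / n0))
      df <- n1 + n0 - 2
    } else {
      v1 <- stats::var(y1) / n1; v0 <- stats::var(y0) / n0
      se <- sqrt(v1 + v0)
      df <- (v1 + v0)^2 / (v1^2 / (n1 - 1) + v0^2 / (n0 - 1))
    }
    stat <- if (se == 0) 0 else (mean(y1) - mean(y0)) / se
    p <- if (se == 0) 1 else 2 * stats::pt(abs(stat), df, lower.tail = FALSE)
    data.frame(unit_id = id, n_present = n1, n_absent = n0,
               mean_present = mean(y1), mean_absent = mean(y0),
               stat = stat, df = df, p = p, degenerate = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- NA_real_
  out$fdr[!out$degenerate] <- stats::p.adjust(out$p[!out$degenerate],
                                              method = "BH")
  out
}

#' Partition a pangenome into core/shell/cloud frequency classes
#'
#' Presence fraction `f = strains_with_group / n_strains`; core when
#' `f > core_frac` (0.99), cloud when `f < shell_lo` (0.15), shell for
#' `shell_lo <= f <= shell_hi` (0.15-0.95). The printed bins leave
#' `(shell_hi, core_frac]` undefined; those groups are assigned shell and
#' counted in the output (`n_gap_shell`).
#'
#' @param x Either a gene-group membership data frame (`group_id`,
#'   `strain_id`) or a logical group x strain presence matrix.
#' @param config A [analysis_config()].
#' @param n_strains Total strains in the pangenome (defaults to the number of
#'   distinct strains observed in `x`).
#' @param replicons Optional named vector group_id -> replicon_id enabling
#'   the per-replicon class-fraction summary.
#' @return List with `classes` (data frame group_id, n_strains_with,
#'   fraction, class), `summary` (per-replicon class fractions, when
#'   `replicons` given), and `n_gap_shell`.
#' @export
classify_pangenome <- function(x, config = analysis_config(),
                               n_strains = NULL, replicons = NULL) {
  if (is.matrix(x)) {
    counts <- rowSums(x)
    if (is.null(n_strains)) n_strains <- ncol(x)
    ids <- rownames(x)
  } else {
    stopifnot(all(c("group_id", "strain_id") %in% names(x)))
    tab <- tapply(x$strain_id, x$group_id, function(s) length(unique(s)))
    counts <- as.vector(tab)
    ids <- names(tab)
    if (is.null(n_strains)) n_strains <- length(unique(x$strain_id))
  }
  if (any(counts == 0L)) stop("group present in no strain", call. = FALSE)
  f <- counts / n_strains
  cls <- ifelse(f > config$core_frac, "core",
                ifelse(f < config$shell_lo, "cloud", "shell"))
  n_gap <- sum(f > config$shell_hi & f <= config$core_frac)
  classes <- data.frame(group_id = ids, n_strains_with = counts,
                        fraction = f, class = cls, stringsAsFactors = FALSE)
  out <- list(classes = classes, n_gap_shell = n_gap)
  if (!is.null(replicons)) {
    rep_of <- replicons[classes$group_id]
    tab <- table(rep_of, factor(classes$class,
                                levels = c("core", "shell", "cloud")))
    out$summary <- data.frame(replicon_id = rownames(tab),
                              core = as.vector(prop.table(tab, 1)[, "core"]),
                              shell = as.vector(prop.table(tab, 1)[, "shell"]),
                              cloud = as.vector(prop.table(tab, 1)[, "cloud"]),
                              n_groups = as.vector(rowSums(tab)),
                              stringsAsFactors = FALSE)
  }
  out
}
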