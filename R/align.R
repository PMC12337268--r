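# Sequence-based presence confirmation: exact k-mer seeding, diagonal
# chaining, then a local alignment of the query against the spanned target
# window. Ambiguous IUPAC letters score as mismatches.

pav_substitution_matrix <- function(match = 1, mismatch = -2) {
  letters <- Biostrings::DNA_ALPHABET
  m <- matrix(mismatch, length(letters), length(letters),
              dimnames = list(letters, letters))
  for (b in c("A", "C", "G", "T")) m[b, b] <- match
  m
}

# Precompute the sampled k-mer dictionary of a query once; matching it
# against many targets is then cheap (PDict construction dominates
# otherwise).
query_seed_dict <- function(query, k, stride) {
  qlen <- Biostrings::nchar(query)
  starts <- unique(c(seq(1L, qlen - k + 1L, by = stride), qlen - k + 1L))
  kmers <- Biostrings::DNAStringSet(query, start = starts, width = k)
  list(pdict = Biostrings::PDict(kmers), starts = starts)
}

# Exact k-mer seeds of a prebuilt dictionary in `target`; returns
# query/target start positions of matching k-mers.
kmer_seeds <- function(dict, target) {
  hits <- Biostrings::matchPDict(dict$pdict, target)
  qpos <- rep(dict$starts, S4Vectors::elementNROWS(hits))
  tpos <- unlist(lapply(hits, IRanges::start), use.names = FALSE)
  if (is.null(tpos)) tpos <- integer(0)
  data.frame(qpos = qpos, tpos = tpos)
}

# Best-scoring local alignment of query against one target sequence, seeded.
# Returns NULL when no seed chain exists.
align_seeded <- function(query, dict, target, band = 64L,
                         submat, gap_open = 5, gap_ext = 2) {
  seeds <- kmer_seeds(dict, target)
  if (nrow(seeds) == 0L) return(NULL)
  diag <- seeds$tpos - seeds$qpos
  band_id <- round(diag / band)
  best_band <- as.integer(names(which.max(table(band_id))))
  sel <- abs(diag - best_band * band) <= 2L * band
  qlen <- Biostrings::nchar(query)
  tlen <- Biostrings::nchar(target)
  tstart <- max(1L, min(seeds$tpos[sel] - seeds$qpos[sel]) + 1L - band)
  tend <- min(tlen, max(seeds$tpos[sel] + (qlen - seeds$qpos[sel])) + band)
  window <- Biostrings::subseq(target, tstart, tend)
  pa <- Biostrings::pairwiseAlignment(query, window, type = "local",
                                      substitutionMatrix = submat,
                                      gapOpening = gap_open,
                                      gapExtension = gap_ext)
  nmat <- Biostrings::nmatch(pa)
  nmis <- Biostrings::nmismatch(pa)
  ins <- sum(IRanges::width(unlist(Biostrings::insertion(pa))))
  del <- sum(IRanges::width(unlist(Biostrings::deletion(pa))))
  cols <- nmat + nmis + ins + del
  qr <- pa@pattern@range
  list(score = Biostrings::score(pa),
       identity = if (cols > 0) nmat / cols else 0,
       coverage = (IRanges::width(qr)) / qlen,
       t_start = tstart + IRanges::start(pa@subject@range) - 1L,
       t_end = tstart + IRanges::end(pa@subject@range) - 1L)
}

#' Confirm gene presence by sequence search
#'
#' For each gene and strain, seeds exact k-mers of the query (both strands)
#' in every replicon of the strain's assembly, chains collinear seeds on the
#' dominant diagonal, locally aligns the query against the spanned window,
#' and reports the best hit's identity (matching columns over alignment
#' columns) and coverage (aligned query bases over query length). A gene is
#' called present when identity and coverage both reach the configured
#' thresholds (98% at the defaults).
#'
#' @param gene_seqs Named `DNAStringSet` (or named character vector) of query
#'   gene sequences.
#' @param store A [genome_store()] over the strain assemblies.
#' @param config A [analysis_config()] (`seed_k`, `min_identity`,
#'   `min_coverage`).
#' @param strains Strains to search (default: all in the store).
#' @return List with `hits` (data frame gene_id, strain_id, replicon_id,
#'   start, end, strand, identity, coverage, score) and `presence` (logical
#'   gene x strain matrix with attribute `source = "sequence"`).
#' @export
find_sequence_presence <- function(gene_seqs, store,
                                   config = analysis_config(),
                                   strains = names(store$paths)) {
  if (!methods::is(gene_seqs, "DNAStringSet")) {
    gene_seqs <- Biostrings::DNAStringSet(gene_seqs)
  }
  stopifnot(!is.null(names(gene_seqs)), all(nzchar(names(gene_seqs))))
  k <- config$seed_k
  short <- Biostrings::width(gene_seqs) < k
  if (any(short)) {
    stop("query shorter than seed k-mer size: ", names(gene_seqs)[short][1],
         call. = FALSE)
  }
  # non-overlapping seeds: at 5% divergence a 900-bp query still yields ~6
  # clean 31-mers in expectation, ample to locate the window
  stride <- k
  submat <- pav_substitution_matrix()
  hits <- vector("list", length(gene_seqs) * length(strains))
  presence <- matrix(FALSE, length(gene_seqs), length(strains),
                     dimnames = list(names(gene_seqs), strains))
  # one seed dictionary per query and strand, shared across all strains
  dicts <- lapply(seq_along(gene_seqs), function(i) {
    q_fwd <- gene_seqs[[i]]
    q_rev <- Biostrings::reverseComplement(q_fwd)
    list(`+` = list(q = q_fwd, d = query_seed_dict(q_fwd, k, stride)),
         `-` = list(q = q_rev, d = query_seed_dict(q_rev, k, stride)))
  })
  names(dicts) <- names(gene_seqs)
  hi <- 0L
  for (s in strains) {
    genome <- get_genome(store, s)
    for (g in names(gene_seqs)) {
      best <- NULL
      for (rep_id in names(genome)) {
        for (strand in c("+", "-")) {
          qd <- dicts[[g]][[strand]]
          al <- align_seeded(qd$q, qd$d, genome[[rep_id]], submat = submat)
          if (!is.null(al) && (is.null(best) || al$score > best$score)) {
            best <- c(al, list(replicon_id = rep_id, strand = strand))
          }
          if (!is.null(best) && best$identity == 1 && best$coverage == 1) {
            break  # a perfect hit cannot be improved upon
          }
        }
        if (!is.null(best) && best$identity == 1 && best$coverage == 1) break
      }
      hi <- hi + 1L
      if (is.null(best)) {
        hits[[hi]] <- data.frame(gene_id = g, strain_id = s,
                                 replicon_id = NA_character_,
                                 start = NA_integer_, end = NA_integer_,
                                 strand = NA_character_, identity = 0,
                                 coverage = 0, score = NA_real_,
                                 stringsAsFactors = FALSE)
      } else {
        hits[[hi]] <- data.frame(gene_id = g, strain_id = s,
                                 replicon_id = best$replicon_id,
                                 start = best$t_start, end = best$t_end,
                                 strand = best$strand,
                                 identity = best$identity,
                                 coverage = best$coverage,
                                 score = best$score, stringsAsFactors = FALSE)
        presence[g, s] <- best$identity >= config$min_identity &&
          best$coverage >= config$min_coverage
      }
    }
  }
  attr(presence, "source") <- "sequence"
  list(hits = do.call(rbind, hits), presence = presence)
}
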