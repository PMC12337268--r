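#' Construct a validated counts matrix
#'
#' @param counts Nonnegative integer matrix, genes in rows (rownames = gene
#'   ids), samples in columns (colnames = sample ids).
#' @param round_fractional Round fractional values half-to-even with a warning
#'   instead of erroring. Quantifier output is sometimes fractional; the
#'   presence-calling rules are stated on counts, so rounding is explicit.
#' @return A `counts_matrix`: list with `counts` and `lib_sizes` (column sums).
#' @export
counts_matrix <- function(counts, round_fractional = FALSE) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  stopifnot(is.matrix(counts))
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry gene rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate gene id: ",
         rownames(counts)[duplicated(rownames(counts))][1], call. = FALSE)
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate sample id: ",
         colnames(counts)[duplicated(colnames(counts))][1], call. = FALSE)
  }
  if (!is.numeric(counts) || anyNA(counts)) {
    stop("counts must be numeric and non-missing", call. = FALSE)
  }
  frac <- counts != round(counts)
  if (any(frac)) {
    if (round_fractional) {
      warning(sum(frac), " fractional counts rounded half-to-even",
              call. = FALSE)
      counts <- round(counts)  # round() is half-to-even in R
    } else {
      bad <- which(frac, arr.ind = TRUE)[1, ]
      stop(sprintf("non-integer count %g at gene %s, sample %s",
                   counts[bad[1], bad[2]], rownames(counts)[bad[1]],
                   colnames(counts)[bad[2]]), call. = FALSE)
    }
  }
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  storage.mode(counts) <- "double"  # integer overflow-safe column sums
  obj <- list(counts = counts, lib_sizes = colSums(counts))
  class(obj) <- "counts_matrix"
  obj
}

#' @export
print.counts_matrix <- function(x, ...) {
  cat(sprintf("counts_matrix: %d genes x %d samples, library sizes %s..%s\n",
              nrow(x$counts), ncol(x$counts),
              format(min(x$lib_sizes), big.mark = ","),
              format(max(x$lib_sizes), big.mark = ",")))
  invisible(x)
}

#' @export
dim.counts_matrix <- function(x) dim(x$counts)

#' Read a counts TSV and its sample sheet
#'
#' The counts file is TSV with a header row of sample ids and gene ids in the
#' first column. The sample sheet is CSV/TSV with columns `sample_id`,
#' `strain_id`, `replicate`. Samples are reordered to the sheet's order.
#'
#' @param counts_path,sample_sheet_path File paths.
#' @param round_fractional See [counts_matrix()].
#' @return List with elements `counts` (a `counts_matrix`) and `samples` (the
#'   validated sample sheet data frame).
#' @export
read_expression_inputs <- function(counts_path, sample_sheet_path,
                                   round_fractional = FALSE) {
  raw <- utils::read.delim(counts_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("counts file needs gene ids plus >= 1 sample",
                           call. = FALSE)
  genes <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- genes
  cm <- counts_matrix(m, round_fractional = round_fractional)
  samples <- read_sample_sheet(sample_sheet_path)
  missing_in_sheet <- setdiff(colnames(cm$counts), samples$sample_id)
  if (length(missing_in_sheet)) {
    stop("sample in counts but not in sample sheet: ", missing_in_sheet[1],
         call. = FALSE)
  }
  missing_in_counts <- setdiff(samples$sample_id, colnames(cm$counts))
  if (length(missing_in_counts)) {
    stop("sample in sample sheet but not in counts: ", missing_in_counts[1],
         call. = FALSE)
  }
  cm$counts <- cm$counts[, samples$sample_id, drop = FALSE]
  cm$lib_sizes <- cm$lib_sizes[samples$sample_id]
  list(counts = cm, samples = samples)
}

#' Read and validate a sample sheet
#'
#' @param path CSV or TSV file with columns `sample_id`, `strain_id`,
#'   `replicate`.
#' @return Data frame with those three columns.
#' @export
read_sample_sheet <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  validate_sample_sheet(df)
}

#' @rdname read_sample_sheet
#' @param df A data frame to validate in place.
#' @export
validate_sample_sheet <- function(df) {
  need <- c("sample_id", "strain_id", "replicate")
  if (!all(need %in% names(df))) {
    stop("sample sheet must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df$sample_id <- as.character(df$sample_id)
  df$strain_id <- as.character(df$strain_id)
  df$replicate <- as.integer(df$replicate)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in sample sheet: ",
         df$sample_id[duplicated(df$sample_id)][1], call. = FALSE)
  }
  if (any(df$replicate < 1L)) stop("replicate must be >= 1", call. = FALSE)
  reps <- table(df$strain_id)
  if (any(reps < 2L)) {
    stop("strain with < 2 replicates: ", names(reps)[reps < 2][1],
         call. = FALSE)
  }
  df[, need]
}

#' Read a strain-level phenotype table
#'
#' One row per strain; numeric trait columns (shoot biomass in grams, other
#' traits unitless).
#'
#' @param path CSV with a `strain_id` column plus numeric trait columns.
#' @return Data frame with `strain_id` first.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"strain_id" %in% names(df)) stop("phenotype table needs strain_id",
                                        call. = FALSE)
  df$strain_id <- as.character(df$strain_id)
  if (anyDuplicated(df$strain_id)) {
    stop("duplicate strain_id in phenotype table: ",
         df$strain_id[duplicated(df$strain_id)][1], call. = FALSE)
  }
  traits <- setdiff(names(df), "strain_id")
  for (tr in traits) {
    if (!is.numeric(df[[tr]])) stop("non-numeric trait: ", tr, call. = FALSE)
  }
  df
}

#' Read gene annotation from GFF3
#'
#' Keeps `gene` features; seqid is the replicon id and the `ID` attribute the
#' gene id. Coordinates stay 1-based inclusive exactly as in the file.
#'
#' @param gff3_path Path to a GFF3 file.
#' @param strain_id Strain the annotation belongs to.
#' @return Data frame with columns `strain_id`, `gene_id`, `replicon_id`,
#'   `start`, `end`, `strand`.
#' @export
read_annotation <- function(gff3_path, strain_id = "reference") {
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  gr <- gr[as.character(gr$type) == "gene"]
  if (length(gr) == 0L) stop("no gene features in ", gff3_path, call. = FALSE)
  ids <- as.character(gr$ID)
  if (anyNA(ids) || any(!nzchar(ids))) {
    stop("gene feature without ID attribute in ", gff3_path, call. = FALSE)
  }
  ann <- data.frame(
    strain_id = strain_id,
    gene_id = ids,
    replicon_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  ann$strand[!ann$strand %in% c("+", "-")] <- "+"
  validate_annotation(ann)
}

#' @rdname read_annotation
#' @param ann Annotation data frame to validate.
#' @export
validate_annotation <- function(ann) {
  need <- c("strain_id", "gene_id", "replicon_id", "start", "end", "strand")
  stopifnot(all(need %in% names(ann)))
  if (any(ann$start > ann$end)) {
    bad <- ann$gene_id[ann$start > ann$end][1]
    stop("start > end for gene ", bad, call. = FALSE)
  }
  key <- paste(ann$strain_id, ann$gene_id)
  if (anyDuplicated(key)) {
    stop("duplicate gene id within strain: ", key[duplicated(key)][1],
         call. = FALSE)
  }
  ann[, need]
}

#' Write gene annotation as GFF3
#'
#' @param ann Annotation data frame (see [read_annotation()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = ann$replicon_id,
    ranges = IRanges::IRanges(start = ann$start, end = ann$end),
    strand = ann$strand
  )
  gr$type <- "gene"
  gr$ID <- ann$gene_id
  gr$source <- "pavnet"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Open a per-strain genome store
#'
#' Holds FASTA paths and loads each strain's replicon sequences only when
#' requested (cached afterwards), so all genomes never need to be in memory at
#' once. Sequences are upper-cased on load; record ids are replicon ids.
#'
#' @param fasta_paths Named character vector, `strain_id -> FASTA path`.
#' @return A `genome_store` object.
#' @export
genome_store <- function(fasta_paths) {
  stopifnot(is.character(fasta_paths), !is.null(names(fasta_paths)),
            all(nzchar(names(fasta_paths))))
  missing <- fasta_paths[!file.exists(fasta_paths)]
  if (length(missing)) stop("FASTA not found: ", missing[1], call. = FALSE)
  obj <- list(paths = fasta_paths, cache = new.env(parent = emptyenv()))
  class(obj) <- "genome_store"
  obj
}

#' @rdname genome_store
#' @param store A `genome_store`.
#' @param strain_id Strain to fetch.
#' @return A `DNAStringSet` of that strain's replicons.
#' @export
get_genome <- function(store, strain_id) {
  stopifnot(inherits(store, "genome_store"))
  if (!strain_id %in% names(store$paths)) {
    stop("no genome for strain ", strain_id, call. = FALSE)
  }
  if (!exists(strain_id, envir = store$cache)) {
    seqs <- Biostrings::readDNAStringSet(store$paths[[strain_id]])
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    if (any(Biostrings::width(seqs) == 0L)) {
      stop("empty FASTA record in ", store$paths[[strain_id]], call. = FALSE)
    }
    if (anyDuplicated(names(seqs))) {
      stop("duplicate replicon id ", names(seqs)[duplicated(names(seqs))][1],
           " in ", store$paths[[strain_id]], call. = FALSE)
    }
    # DNAStringSet enforces the IUPAC alphabet at parse time; normalize case.
    seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
    assign(strain_id, seqs, envir = store$cache)
  }
  get(strain_id, envir = store$cache)
}

#' @rdname genome_store
#' @export
genome_lengths <- function(store, strain_id) {
  seqs <- get_genome(store, strain_id)
  stats::setNames(Biostrings::width(seqs), names(seqs))
}

#' Read a pangenome gene-group membership table
#'
#' @param path TSV with columns `group_id`, `strain_id`, `gene_id`.
#' @return Data frame with those columns.
#' @export
read_gene_groups <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("group_id", "strain_id", "gene_id")
  if (!all(need %in% names(df))) {
    stop("gene-group table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df[, need]
}

#' Write a presence matrix as TSV (genes x strains, 0/1)
#'
#' @param presence Logical matrix, rownames gene/cluster ids, colnames strains.
#' @param path Output path.
#' @export
write_presence_matrix <- function(presence, path) {
  stopifnot(is.matrix(presence), is.logical(presence))
  out <- data.frame(id = rownames(presence),
                    matrix(as.integer(presence), nrow = nrow(presence),
                           dimnames = list(NULL, colnames(presence))),
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_presence_matrix
#' @export
read_presence_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE]) == 1L
  rownames(m) <- df[[1]]
  m
}

#' Write result tables and a JSON run manifest
#'
#' Every data frame in `tables` is written as `<name>.tsv` with its column
#' order preserved; logical matrices go through [write_presence_matrix()].
#' The manifest records file names, the seed, and a hash of the configuration.
#'
#' @param tables Named list of data frames / logical matrices.
#' @param out_dir Output directory (created if needed).
#' @param config A `pav_config`.
#' @return Invisible character vector of written paths (the manifest last).
#' @export
write_results <- function(tables, out_dir, config = analysis_config()) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory ", out_dir, call. = FALSE)
  }
  stopifnot(is.list(tables), !is.null(names(tables)))
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    x <- tables[[nm]]
    if (is.matrix(x) && is.logical(x)) {
      write_presence_matrix(x, p)
    } else {
      utils::write.table(as.data.frame(x), p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    paths <- c(paths, p)
  }
  manifest <- list(
    files = basename(paths),
    seed = config$seed,
    config_hash = config_hash(config),
    config = unclass(config),
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  )
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, mp))
}
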