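## Annotation container and file-format plumbing.  Coordinates are 1-based
## inclusive everywhere (GTF and GRanges share this convention, so no shift
## ever happens).

#' Build an annotation set from an exon table
#'
#' The central annotation container: a table of exons (one row per exon,
#' 1-based inclusive coordinates) plus a per-transcript summary.  All
#' transcripts must have their exons on a single chromosome and strand, and
#' exons within a transcript must not overlap.
#'
#' @param exons data.frame with columns `chrom`, `start`, `end`, `strand`
#'   (`"+"` or `"-"`), `gene_id`, `transcript_id`.
#' @return An object of class `annotation_set`: a list with elements
#'   `exons` (the validated, sorted exon table) and `transcripts`
#'   (one row per transcript: `transcript_id`, `gene_id`, `chrom`, `strand`,
#'   `start`, `end`, `n_exons`, `spliced_length`).
#' @export
annotation_set <- function(exons) {
  required <- c("chrom", "start", "end", "strand", "gene_id", "transcript_id")
  if (!all(required %in% names(exons)))
    stop("exon table must have columns: ", paste(required, collapse = ", "))
  exons <- as.data.frame(exons)[required]
  if (nrow(exons) == 0L) {
    tr <- data.frame(transcript_id = character(), gene_id = character(),
                     chrom = character(), strand = character(),
                     start = integer(), end = integer(),
                     n_exons = integer(), spliced_length = integer(),
                     stringsAsFactors = FALSE)
    return(structure(list(exons = exons, transcripts = tr),
                     class = "annotation_set"))
  }
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (any(exons$start > exons$end) || any(exons$start < 1L))
    stop("invalid exon coordinates (start > end or start < 1)")
  if (!all(exons$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  exons <- exons[order(exons$transcript_id, exons$start, exons$end), ,
                 drop = FALSE]
  rownames(exons) <- NULL

  by_tx <- split(seq_len(nrow(exons)), exons$transcript_id)
  for (tx in names(by_tx)) {
    i <- by_tx[[tx]]
    if (length(unique(exons$chrom[i])) > 1L ||
        length(unique(exons$strand[i])) > 1L)
      stop("transcript '", tx, "' has exons on mixed chromosomes or strands")
    if (length(unique(exons$gene_id[i])) > 1L)
      stop("transcript '", tx, "' assigned to multiple gene_ids")
    if (length(i) > 1L && any(exons$start[i][-1] <= exons$end[i][-length(i)]))
      stop("transcript '", tx, "' has overlapping exons")
  }
  first <- vapply(by_tx, `[`, integer(1), 1L)
  tr <- data.frame(
    transcript_id = names(by_tx),
    gene_id = exons$gene_id[first],
    chrom = exons$chrom[first],
    strand = exons$strand[first],
    start = vapply(by_tx, function(i) min(exons$start[i]), integer(1)),
    end = vapply(by_tx, function(i) max(exons$end[i]), integer(1)),
    n_exons = lengths(by_tx),
    spliced_length = vapply(by_tx, function(i)
      sum(exons$end[i] - exons$start[i] + 1L), integer(1)),
    stringsAsFactors = FALSE)
  rownames(tr) <- NULL
  structure(list(exons = exons, transcripts = tr), class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set:", nrow(x$transcripts), "transcripts,",
      nrow(x$exons), "exons on",
      length(unique(x$exons$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Subset an annotation set by transcript id
#' @param x annotation_set
#' @param transcript_ids character vector of transcript ids to keep
#' @return annotation_set restricted to the requested transcripts
#' @export
subset_annotation <- function(x, transcript_ids) {
  stopifnot(inherits(x, "annotation_set"))
  annotation_set(x$exons[x$exons$transcript_id %in% transcript_ids, ,
                         drop = FALSE])
}

## GRanges views -------------------------------------------------------------

exon_ranges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$exons$chrom,
    ranges = IRanges::IRanges(x$exons$start, x$exons$end),
    strand = x$exons$strand,
    transcript_id = x$exons$transcript_id,
    gene_id = x$exons$gene_id)
}

transcript_ranges <- function(x) {
  tr <- x$transcripts
  GenomicRanges::GRanges(
    seqnames = tr$chrom,
    ranges = IRanges::IRanges(tr$start, tr$end),
    strand = tr$strand,
    transcript_id = tr$transcript_id,
    gene_id = tr$gene_id)
}

gene_ranges <- function(x) {
  tr <- x$transcripts
  by_gene <- split(seq_len(nrow(tr)), tr$gene_id)
  GenomicRanges::GRanges(
    seqnames = vapply(by_gene, function(i) tr$chrom[i][1], character(1)),
    ranges = IRanges::IRanges(
      vapply(by_gene, function(i) min(tr$start[i]), integer(1)),
      vapply(by_gene, function(i) max(tr$end[i]), integer(1))),
    strand = vapply(by_gene, function(i) tr$strand[i][1], character(1)),
    gene_id = names(by_gene))
}

## introns: gaps between consecutive exons of each multi-exon transcript
intron_ranges <- function(x) {
  ex <- x$exons  # already sorted by transcript then start
  n <- nrow(ex)
  if (n < 2L)
    return(GenomicRanges::GRanges())
  same_tx <- ex$transcript_id[-n] == ex$transcript_id[-1]
  i <- which(same_tx)
  if (length(i) == 0L)
    return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(
    seqnames = ex$chrom[i],
    ranges = IRanges::IRanges(ex$end[i] + 1L, ex$start[i + 1L] - 1L),
    strand = ex$strand[i],
    transcript_id = ex$transcript_id[i])
}

## GTF ------------------------------------------------------------------------

#' Read a GTF file into an annotation set
#'
#' Only `exon` feature rows are interpreted; other feature rows are ignored
#' (their count is reported via a message).  Transcripts are reconstructed by
#' grouping exon rows on their `transcript_id` attribute.
#'
#' @param path path to a GTF file.
#' @return [annotation_set()]
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  if (length(body) == 0L)
    return(annotation_set(data.frame(chrom = character(), start = integer(),
                                     end = integer(), strand = character(),
                                     gene_id = character(),
                                     transcript_id = character())))
  nfields <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- body[nfields != 9L]
  if (length(bad) > 0L)
    stop("malformed GTF line ", bad[1], " in ", path,
         " (expected 9 tab-separated fields, got ",
         nfields[match(bad[1], body)], ")")
  gr <- rtracklayer::import(path, format = "gtf")
  n_other <- sum(gr$type != "exon")
  if (n_other > 0L)
    message("read_gtf: ignoring ", n_other, " non-exon feature row(s)")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L)
    return(annotation_set(data.frame(chrom = character(), start = integer(),
                                     end = integer(), strand = character(),
                                     gene_id = character(),
                                     transcript_id = character())))
  gid <- gr$gene_id
  tid <- gr$transcript_id
  if (is.null(gid) || is.null(tid) || anyNA(gid) || anyNA(tid))
    stop("exon rows must carry gene_id and transcript_id attributes")
  annotation_set(data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = gid,
    transcript_id = tid,
    stringsAsFactors = FALSE))
}

#' Write an annotation set as GTF
#'
#' Emits one `exon` row per exon; round-trips losslessly through
#' [read_gtf()] for chromosome, strand, coordinates and ids.
#'
#' @param x annotation_set
#' @param path output path
#' @return `path`, invisibly.
#' @export
write_gtf <- function(x, path) {
  stopifnot(inherits(x, "annotation_set"))
  ex <- x$exons
  if (nrow(ex) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                   ex$gene_id, ex$transcript_id)
  lines <- paste(ex$chrom, "lncflower", "exon", ex$start, ex$end,
                 ".", ex$strand, ".", attrs, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

## FASTA ----------------------------------------------------------------------

#' Read transcript sequences from FASTA
#' @param path FASTA file path
#' @return named character vector of upper-case sequences
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(ss)), names(ss))
}

#' Write transcript sequences to FASTA
#' @param sequences named character vector
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

## Sample sheet ---------------------------------------------------------------

#' Construct the study sample sheet
#'
#' The default reproduces the study design: three conditions (SD1, SD2, NB)
#' with three biological replicates each.
#'
#' @param conditions character vector of condition names, one per sample.
#' @param replicates integer vector of replicate numbers, parallel to
#'   `conditions`.
#' @param sample_id optional explicit sample ids; default `condition_replicate`.
#' @return data.frame with columns `sample_id`, `condition`, `replicate`.
#' @export
sample_sheet <- function(conditions = rep(c("SD1", "SD2", "NB"), each = 3),
                         replicates = rep(1:3, times = 3),
                         sample_id = paste0(conditions, "_", replicates)) {
  stopifnot(length(conditions) == length(replicates),
            length(sample_id) == length(conditions))
  if (anyDuplicated(sample_id))
    stop("sample ids must be unique")
  tab <- table(conditions)
  if (any(tab < 2L))
    stop("each condition needs >= 2 replicates for differential expression; ",
         "offending: ", paste(names(tab)[tab < 2L], collapse = ", "))
  data.frame(sample_id = sample_id, condition = conditions,
             replicate = as.integer(replicates), stringsAsFactors = FALSE)
}

#' @rdname sample_sheet
#' @param path TSV path with columns sample_id, condition, replicate
#' @export
read_sample_sheet <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  sample_sheet(conditions = df$condition, replicates = df$replicate,
               sample_id = df$sample_id)
}

## Counts ---------------------------------------------------------------------

#' Read a gene-level count matrix
#'
#' TSV with feature ids in the first column and one column per sample.  When
#' a sample sheet is supplied, columns are checked against and reordered to
#' its `sample_id` order, so on-disk column permutations never change
#' downstream results.
#'
#' @param path TSV path.
#' @param samples optional sample sheet (see [sample_sheet()]).
#' @return integer matrix, features x samples.
#' @export
read_counts <- function(path, samples = NULL) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("count table needs a feature column plus samples")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate feature id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m) || any(!is.finite(m)) || any(m != round(m)) || any(m < 0))
    stop("count matrix cells must be non-negative integers")
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  if (!is.null(samples)) {
    missing <- setdiff(samples$sample_id, colnames(m))
    if (length(missing) > 0L)
      stop("count table lacks sample column(s): ",
           paste(missing, collapse = ", "))
    m <- m[, samples$sample_id, drop = FALSE]
  }
  m
}

#' Write a count matrix as TSV
#' @param counts integer matrix with rownames
#' @param path output path
#' @return `path`, invisibly
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(feature_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## Gene sets ------------------------------------------------------------------

#' Read a gene-set annotation table
#' @param path TSV with columns term_id, term_name, gene_id
#' @return data.frame(term_id, term_name, gene_id)
#' @export
read_gene_sets <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("term_id", "term_name", "gene_id") %in% names(df)))
  df[, c("term_id", "term_name", "gene_id")]
}

#' @rdname read_gene_sets
#' @param gene_sets data.frame(term_id, term_name, gene_id)
#' @export
write_gene_sets <- function(gene_sets, path) {
  write.table(gene_sets, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## Edge list ------------------------------------------------------------------

#' Export a regulatory network as a Cytoscape-importable edge table
#'
#' Columns are `source` (lncRNA id), `interaction` (`cis` or `trans`),
#' `target` (mRNA id) and `weight` (Pearson correlation for trans edges,
#' negative genomic distance for cis edges).
#'
#' @param network a [build_network()] result.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "regulatory_network"))
  e <- network$edges
  weight <- ifelse(e$mode == "trans", e$pcc, -e$distance_bp)
  df <- data.frame(source = e$lncrna_id, interaction = e$mode,
                   target = e$mrna_id, weight = weight,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
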