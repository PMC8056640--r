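## lncRNA candidate filtering and positional classification against a
## reference annotation.

#' Filter assembled transcripts to lncRNA candidates
#'
#' A transcript is retained iff it is not part of the reference (mRNA)
#' annotation, its spliced length is strictly greater than `min_length_bp`,
#' it has at least `min_exons` exons, and its coding-potential consensus is
#' `noncoding`.
#'
#' @param annotation [annotation_set()] of assembled transcripts.
#' @param verdicts output of [score_coding_potential()]; must cover every
#'   non-reference transcript in `annotation`.
#' @param reference_ids transcript ids belonging to the reference annotation
#'   (excluded up front — they form the mRNA universe).
#' @param min_length_bp spliced-length cutoff (strict `>`), default 200.
#' @param min_exons minimum exon count (`>=`), default 2.
#' @return data.frame of retained transcripts (columns of
#'   `annotation$transcripts` plus `orf_length_nt`).
#' @export
filter_lncrna_candidates <- function(annotation, verdicts,
                                     reference_ids = character(),
                                     min_length_bp = 200L, min_exons = 2L) {
  stopifnot(inherits(annotation, "annotation_set"))
  tr <- annotation$transcripts
  tr <- tr[!tr$transcript_id %in% reference_ids, , drop = FALSE]
  missing <- setdiff(tr$transcript_id, verdicts$transcript_id)
  if (length(missing) > 0L)
    stop("no coding-potential verdict for transcript(s): ",
         paste(head(missing, 5), collapse = ", "))
  v <- verdicts[match(tr$transcript_id, verdicts$transcript_id), ,
                drop = FALSE]
  keep <- tr$spliced_length > min_length_bp &
    tr$n_exons >= min_exons &
    v$consensus == "noncoding"
  out <- tr[keep, , drop = FALSE]
  out$orf_length_nt <- v$orf_length_nt[keep]
  rownames(out) <- NULL
  out
}

#' Positionally classify lncRNAs against a reference annotation
#'
#' Deterministic decision cascade, first match wins:
#' \enumerate{
#'   \item \strong{sense} — any exon of the lncRNA overlaps (>= 1 bp) an
#'     exon of a same-strand reference transcript;
#'   \item \strong{intronic} — the lncRNA span is fully contained within a
#'     single intron of a same-strand reference transcript;
#'   \item \strong{antisense} — the lncRNA span overlaps (>= 1 bp) the span
#'     of an opposite-strand reference transcript;
#'   \item \strong{lincRNA} — otherwise (intergenic).
#' }
#' The precedence (sense > intronic > antisense > lincRNA) makes the four
#' classes a partition; in particular a transcript contained in an intron on
#' the opposite strand is antisense, since the class is strand-defined.
#'
#' @param lncrnas [annotation_set()] of the lncRNAs to classify (e.g. built
#'   with [subset_annotation()] from the assembled models).
#' @param ref [annotation_set()] of reference protein-coding gene models.
#' @return data.frame with columns `transcript_id`, `class` (one of
#'   `lincRNA`, `intronic`, `sense`, `antisense`).
#' @export
classify_position <- function(lncrnas, ref) {
  stopifnot(inherits(lncrnas, "annotation_set"),
            inherits(ref, "annotation_set"))
  ids <- lncrnas$transcripts$transcript_id
  if (length(ids) == 0L)
    return(data.frame(transcript_id = character(), class = character(),
                      stringsAsFactors = FALSE))
  q_ex <- exon_ranges(lncrnas)
  q_span <- transcript_ranges(lncrnas)
  r_ex <- exon_ranges(ref)
  r_span <- transcript_ranges(ref)
  r_intron <- intron_ranges(ref)

  ## rule 1: same-strand exonic overlap (strand respected by findOverlaps)
  h1 <- GenomicRanges::findOverlaps(q_ex, r_ex, minoverlap = 1L)
  sense_ids <- unique(S4Vectors::mcols(q_ex)$transcript_id[
    S4Vectors::queryHits(h1)])

  ## rule 2: span within a single same-strand intron
  if (length(r_intron) > 0L) {
    h2 <- GenomicRanges::findOverlaps(q_span, r_intron, type = "within")
    intronic_ids <- unique(S4Vectors::mcols(q_span)$transcript_id[
      S4Vectors::queryHits(h2)])
  } else intronic_ids <- character()

  ## rule 3: span overlap with an opposite-strand reference span
  h3 <- GenomicRanges::findOverlaps(q_span, r_span, minoverlap = 1L,
                                    ignore.strand = TRUE)
  opp <- as.character(GenomicRanges::strand(q_span))[
    S4Vectors::queryHits(h3)] !=
    as.character(GenomicRanges::strand(r_span))[S4Vectors::subjectHits(h3)]
  antisense_ids <- unique(S4Vectors::mcols(q_span)$transcript_id[
    S4Vectors::queryHits(h3)[opp]])

  cls <- rep("lincRNA", length(ids))
  cls[ids %in% antisense_ids] <- "antisense"
  cls[ids %in% intronic_ids] <- "intronic"
  cls[ids %in% sense_ids] <- "sense"
  data.frame(transcript_id = ids, class = cls, stringsAsFactors = FALSE)
}

#' Per-class counts and chromosomal density of classified lncRNAs
#'
#' @param classification output of [classify_position()].
#' @param lncrnas the classified [annotation_set()] (supplies chromosome of
#'   each transcript).
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @return list with `class_counts` (named integer vector over the four
#'   classes), `chrom_density` (data.frame `chrom`, `n`, `length_mb`,
#'   `density_per_mb`), and `overall_density_per_mb` (total lncRNAs divided
#'   by total Mb).
#' @export
class_census <- function(classification, lncrnas, chrom_lengths) {
  stopifnot(inherits(lncrnas, "annotation_set"))
  classes <- c("lincRNA", "intronic", "sense", "antisense")
  class_counts <- setNames(integer(length(classes)), classes)
  tab <- table(classification$class)
  class_counts[names(tab)] <- as.integer(tab)

  tr <- lncrnas$transcripts
  chrom <- tr$chrom[match(classification$transcript_id, tr$transcript_id)]
  missing <- setdiff(unique(chrom), names(chrom_lengths))
  if (length(missing) > 0L)
    stop("missing chromosome length(s): ", paste(missing, collapse = ", "))
  n_by_chrom <- table(factor(chrom, levels = names(chrom_lengths)))
  dens <- data.frame(
    chrom = names(chrom_lengths),
    n = as.integer(n_by_chrom),
    length_mb = unname(chrom_lengths) / 1e6,
    stringsAsFactors = FALSE)
  dens$density_per_mb <- dens$n / dens$length_mb
  list(class_counts = class_counts,
       chrom_density = dens,
       overall_density_per_mb =
         nrow(classification) / (sum(chrom_lengths) / 1e6))
}
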