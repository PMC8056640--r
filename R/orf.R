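## Open-reading-frame scanning and the in-house coding-potential rule.

#' Length of the longest open reading frame
#'
#' Scans the given (sense) strand in all three frames for the longest
#' ATG-initiated, stop-terminated ORF and returns its length in nucleotides,
#' stop codon included.  `N` bases never match the start or a stop codon, so
#' ambiguous sequence can only shorten calls, never create them.
#'
#' @param sequence nucleotide string over A, C, G, T, N (case-insensitive).
#' @return integer ORF length in nt (a multiple of 3), 0 if no complete ORF.
#' @export
find_longest_orf <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (is.na(sequence) || !nzchar(sequence)) return(0L)
  s <- toupper(sequence)
  if (grepl("[^ACGTN]", s))
    stop("sequence contains characters outside {A,C,G,T,N}")
  n <- nchar(s)
  best <- 0L
  for (f in 0:2) {
    if (n - f < 3L) next
    at <- seq.int(1L + f, n - 2L, by = 3L)
    codons <- substring(s, at, at + 2L)
    is_start <- codons == "ATG"
    is_stop <- codons %in% c("TAA", "TAG", "TGA")
    open <- NA_integer_  # earliest ATG since the last stop
    for (i in seq_along(codons)) {
      if (is.na(open) && is_start[i]) open <- i
      if (is_stop[i]) {
        if (!is.na(open)) best <- max(best, (i - open + 1L) * 3L)
        open <- NA_integer_
      }
    }
  }
  best
}

#' Score transcripts for protein-coding potential
#'
#' In-house rule: a transcript is called coding when its longest ORF is at
#' least `orf_threshold_nt` (default 300 nt, i.e. 100 codons — lncRNAs
#' typically carry only ~100 bp ORFs while mRNAs carry much longer ones).
#' External tool verdicts (e.g. CPC/CNCI/CPAT/Pfam-style calls supplied as a
#' table) are combined by intersection: the consensus is `noncoding` only if
#' the in-house call and every provided external call agree on `noncoding`.
#'
#' @param sequences named character vector of transcript sequences (names are
#'   transcript ids).
#' @param external optional data.frame with columns `transcript_id`, `tool`,
#'   `call` (values `coding`/`noncoding`).  Rows for unknown transcripts are
#'   dropped with a warning.
#' @param orf_threshold_nt ORF length (nt) at or above which the in-house
#'   call is `coding`.
#' @return data.frame with columns `transcript_id`, `orf_length_nt`,
#'   `in_house_call`, `consensus`.
#' @export
score_coding_potential <- function(sequences, external = NULL,
                                   orf_threshold_nt = 300L) {
  stopifnot(!is.null(names(sequences)), orf_threshold_nt > 0)
  orf <- vapply(sequences, find_longest_orf, integer(1))
  in_house <- ifelse(orf >= orf_threshold_nt, "coding", "noncoding")
  consensus <- in_house
  if (!is.null(external) && nrow(external) > 0L) {
    stopifnot(all(c("transcript_id", "tool", "call") %in% names(external)))
    if (!all(external$call %in% c("coding", "noncoding")))
      stop("external calls must be 'coding' or 'noncoding'")
    unknown <- setdiff(external$transcript_id, names(sequences))
    if (length(unknown) > 0L) {
      warning("external verdicts for unknown transcript(s) ignored: ",
              paste(unique(unknown), collapse = ", "))
      external <- external[!external$transcript_id %in% unknown, ,
                           drop = FALSE]
    }
    any_coding <- tapply(external$call == "coding", external$transcript_id,
                         any)
    hit <- names(any_coding)[any_coding]
    consensus[names(sequences) %in% hit] <- "coding"
  }
  data.frame(transcript_id = names(sequences),
             orf_length_nt = unname(orf),
             in_house_call = unname(in_house),
             consensus = unname(consensus),
             stringsAsFactors = FALSE)
}
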