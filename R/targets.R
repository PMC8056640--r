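## Cis (genomic window) and trans (expression correlation) target prediction.

#' Cis targets: protein-coding genes within a genomic window of a lncRNA
#'
#' A pair (lncRNA, gene) is emitted when the gap between their genomic spans
#' on the same chromosome is at most `window_bp` (inclusive boundary;
#' overlapping spans give distance 0).  The window is strand-agnostic and
#' anchored on full spans; host genes of sense/intronic lncRNAs are not
#' excluded (they pair at distance 0).
#'
#' @param lncrnas [annotation_set()] of lncRNA models; pairs are reported at
#'   the gene level (`gene_id`).
#' @param ref [annotation_set()] of protein-coding gene models.
#' @param window_bp window size in bp, default 100000 (100 kb upstream and
#'   downstream).
#' @return data.frame with columns `lncrna_id`, `mrna_id`, `mode` (`"cis"`),
#'   `distance_bp`.
#' @export
cis_targets <- function(lncrnas, ref, window_bp = 100000L) {
  stopifnot(inherits(lncrnas, "annotation_set"),
            inherits(ref, "annotation_set"), window_bp >= 0)
  lg <- gene_ranges(lncrnas)
  rg <- gene_ranges(ref)
  if (length(lg) == 0L || length(rg) == 0L)
    return(data.frame(lncrna_id = character(), mrna_id = character(),
                      mode = character(), distance_bp = integer(),
                      stringsAsFactors = FALSE))
  h <- GenomicRanges::findOverlaps(lg, rg, maxgap = window_bp,
                                   ignore.strand = TRUE)
  d <- GenomicRanges::distance(lg[S4Vectors::queryHits(h)],
                               rg[S4Vectors::subjectHits(h)],
                               ignore.strand = TRUE)
  out <- data.frame(
    lncrna_id = S4Vectors::mcols(lg)$gene_id[S4Vectors::queryHits(h)],
    mrna_id = S4Vectors::mcols(rg)$gene_id[S4Vectors::subjectHits(h)],
    mode = rep("cis", length(h)),
    distance_bp = as.integer(d),
    stringsAsFactors = FALSE)
  out <- out[order(out$lncrna_id, out$mrna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pearson correlation with a t-distribution p-value
#'
#' Sample Pearson r between two expression profiles; the two-sided p-value
#' comes from `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of
#' freedom, with `p = 0` at `r = +/-1`.
#'
#' @param x,y numeric vectors of equal length `n >= 3`, non-constant.
#' @return list with elements `pcc` and `p_value`.
#' @export
pearson_test <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3L) stop("need n >= 3 samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant profile")
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tt), df = n - 2)
  }
  list(pcc = r, p_value = p)
}

#' Trans targets: strongly co-expressed lncRNA-mRNA pairs
#'
#' All lncRNA x mRNA profile pairs are tested for Pearson correlation
#' (by default on `log10(FPKM + 0.01)`, the scale used for the expression
#' heatmaps); a pair is emitted when **both** strict cutoffs hold:
#' `|PCC| > pcc_cutoff` and `p < p_cutoff`.  Constant profiles are skipped
#' with a message.
#'
#' @param lncrna_expr,mrna_expr expression matrices (features x samples)
#'   sharing identical sample columns.
#' @param pcc_cutoff strict absolute-correlation cutoff, default 0.9.
#' @param p_cutoff strict p-value cutoff, default 0.01.
#' @param log_transform correlate on `log10(x + pseudo)` (default) or raw
#'   values.
#' @param pseudo pseudo-value for the log transform, default 0.01.
#' @return data.frame with columns `lncrna_id`, `mrna_id`, `mode`
#'   (`"trans"`), `pcc`, `p_value`.
#' @export
trans_targets <- function(lncrna_expr, mrna_expr, pcc_cutoff = 0.9,
                          p_cutoff = 0.01, log_transform = TRUE,
                          pseudo = 0.01) {
  if (!identical(colnames(lncrna_expr), colnames(mrna_expr)))
    stop("expression matrices must share identical sample columns")
  n <- ncol(lncrna_expr)
  if (n < 3L) stop("need >= 3 shared samples")
  empty <- data.frame(lncrna_id = character(), mrna_id = character(),
                      mode = character(), pcc = numeric(),
                      p_value = numeric(), stringsAsFactors = FALSE)
  if (nrow(lncrna_expr) == 0L || nrow(mrna_expr) == 0L) return(empty)
  if (log_transform) {
    lncrna_expr <- log10(lncrna_expr + pseudo)
    mrna_expr <- log10(mrna_expr + pseudo)
  }
  keep_l <- apply(lncrna_expr, 1L, stats::sd) > 0
  keep_m <- apply(mrna_expr, 1L, stats::sd) > 0
  n_const <- sum(!keep_l) + sum(!keep_m)
  if (n_const > 0L)
    message("trans_targets: skipping ", n_const,
            " constant profile(s) (correlation undefined)")
  lncrna_expr <- lncrna_expr[keep_l, , drop = FALSE]
  mrna_expr <- mrna_expr[keep_m, , drop = FALSE]
  if (nrow(lncrna_expr) == 0L || nrow(mrna_expr) == 0L) return(empty)

  r <- stats::cor(t(lncrna_expr), t(mrna_expr))
  r <- pmin(pmax(r, -1), 1)
  tt <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-tt, df = n - 2)
  p[abs(r) >= 1] <- 0
  hit <- which(abs(r) > pcc_cutoff & p < p_cutoff, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(empty)
  out <- data.frame(
    lncrna_id = rownames(lncrna_expr)[hit[, 1]],
    mrna_id = rownames(mrna_expr)[hit[, 2]],
    mode = "trans",
    pcc = r[hit],
    p_value = p[hit],
    stringsAsFactors = FALSE)
  out <- out[order(out$lncrna_id, out$mrna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
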