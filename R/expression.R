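## FPKM normalization, expressed-set Venn partitions and replicate QC.

#' Compute FPKM from raw counts
#'
#' `fpkm[g, s] = counts[g, s] * 1e9 / (length[g] * total[s])` where
#' `total[s]` is the column sum of the count matrix (the "million mapped
#' fragments" denominator is taken from the matrix itself; externally
#' determined totals can be passed via `totals`).
#'
#' @param counts integer matrix, features x samples, with rownames.
#' @param lengths named numeric vector of feature lengths in bp (spliced
#'   transcript length), covering every row of `counts`.
#' @param totals optional per-sample mapped-fragment totals; defaults to
#'   `colSums(counts)`.
#' @return numeric matrix of FPKM values, same dimnames as `counts`.
#' @export
compute_fpkm <- function(counts, lengths, totals = colSums(counts)) {
  stopifnot(!is.null(rownames(counts)))
  missing <- setdiff(rownames(counts), names(lengths))
  if (length(missing) > 0L)
    stop("missing length(s) for feature(s): ",
         paste(head(missing, 5), collapse = ", "))
  len <- lengths[rownames(counts)]
  if (any(len <= 0))
    stop("zero or negative feature length(s): ",
         paste(head(rownames(counts)[len <= 0], 5), collapse = ", "))
  if (any(totals <= 0))
    stop("all-zero sample column(s): ",
         paste(colnames(counts)[totals <= 0], collapse = ", "))
  counts * 1e9 / outer(unname(len), unname(totals))
}

#' Per-condition expressed sets and their Venn partition
#'
#' A feature counts as expressed in a condition when its mean FPKM over that
#' condition's replicates strictly exceeds the threshold (default 0.1 for
#' lncRNAs, 1 for mRNAs).  Returns the per-condition sets and the 7-region
#' Venn partition over the three conditions.
#'
#' @param fpkm FPKM matrix (features x samples).
#' @param samples sample sheet ([sample_sheet()]).
#' @param feature_kind `"lncRNA"` or `"mRNA"`; selects the default threshold.
#' @param threshold override the expression threshold.
#' @return list with `sets` (named list of expressed feature ids per
#'   condition), `membership` (data.frame `feature_id`, `region` for every
#'   feature expressed in >= 1 condition), and `venn` (named integer vector
#'   of region sizes; region names join condition names with `&`).
#' @export
expressed_sets <- function(fpkm, samples,
                           feature_kind = c("lncRNA", "mRNA"),
                           threshold = NULL) {
  feature_kind <- match.arg(feature_kind)
  if (is.null(threshold))
    threshold <- if (feature_kind == "lncRNA") 0.1 else 1
  conds <- unique(samples$condition)
  if (length(conds) != 3L)
    stop("expressed_sets expects exactly 3 conditions, got ", length(conds))
  sets <- lapply(conds, function(cc) {
    cols <- samples$sample_id[samples$condition == cc]
    mu <- rowMeans(fpkm[, cols, drop = FALSE])
    rownames(fpkm)[mu > threshold]
  })
  names(sets) <- conds
  all_ids <- unique(unlist(sets))
  member <- vapply(conds,
                   function(cc) all_ids %in% sets[[cc]],
                   logical(length(all_ids)))
  if (length(all_ids) == 1L) member <- matrix(member, nrow = 1L,
                                              dimnames = list(NULL, conds))
  region <- apply(member, 1L, function(m) paste(conds[m], collapse = "&"))
  region_levels <- unlist(lapply(1:3, function(k)
    apply(utils::combn(conds, k), 2L, paste, collapse = "&")))
  venn <- table(factor(region, levels = region_levels))
  list(sets = sets,
       membership = data.frame(feature_id = all_ids, region = region,
                               stringsAsFactors = FALSE),
       venn = setNames(as.integer(venn), region_levels))
}

#' Sample-by-sample Spearman correlation matrix
#'
#' Replicate QC: rank correlation of expression profiles between all sample
#' pairs (ties get average ranks).  Constant columns have undefined
#' correlation and yield `NA` entries; the diagonal is 1.
#'
#' @param fpkm expression matrix (features x samples).
#' @return symmetric samples x samples matrix.
#' @export
sample_correlation <- function(fpkm) {
  if (nrow(fpkm) < 2L)
    stop("need >= 2 features for sample correlation")
  rho <- suppressWarnings(stats::cor(fpkm, method = "spearman"))
  diag(rho) <- 1
  rho
}
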