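## Differential expression: median-of-ratios normalization, a simplified
## negative-binomial Wald test, and Benjamini-Hochberg correction.
##
## The test is a documented simplification of the DESeq2-style NB framework:
## per-feature method-of-moments dispersion (no shrinkage), delta-method
## standard error on the log2 fold change, standard-normal reference for the
## Wald statistic.  Externally produced DE tables in the same schema can be
## used interchangeably downstream.

#' Median-of-ratios size factors
#'
#' Per sample, the median over features (restricted to features with
#' positive counts in every sample) of the ratio count / geometric mean
#' across samples; factors are rescaled to geometric mean 1.
#'
#' @param counts integer matrix, features x samples.
#' @return named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  loggm <- rowMeans(log(counts))  # -Inf whenever a zero is present
  use <- is.finite(loggm)
  if (!any(use))
    stop("no feature has positive counts in all samples; ",
         "consider a pseudo-reference fallback")
  ratios <- counts[use, , drop = FALSE] / exp(loggm[use])
  sf <- apply(ratios, 2L, median)
  sf / exp(mean(log(sf)))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Classic step-up: with p-values sorted ascending,
#' `q(i) = min_{j >= i} p(j) * m / j`, capped at 1, returned in the input
#' order.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return numeric vector of BH-adjusted values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p_values)
  o <- order(p_values)
  q <- p_values[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  q[order(o)]
}

#' Negative-binomial Wald test for one condition comparison
#'
#' For comparison `"A_vs_B"` the log2 fold change is oriented second-named
#' over first (`B/A`), so "up in SD1_vs_SD2" means higher under prolonged
#' short days.  Per feature: counts are normalized by [size_factors()],
#' condition means are estimated, `log2fc = log2((muB + 0.5)/(muA + 0.5))`
#' (pseudo-count 0.5 stabilizes zeros), the NB dispersion `alpha` (variance
#' `mu + alpha * mu^2`) is estimated by method of moments within each
#' condition, pooled with degree-of-freedom weights and floored at the
#' genome-wide median dispersion (then at 1e-8),
#' the delta-method standard error of the log2 fold change is formed from
#' the NB variance, and a two-sided p-value is taken from the standard
#' normal.  Features with zero counts in every sample are excluded from
#' testing and from the BH family.
#'
#' @param counts integer matrix, features x samples (rownames = feature id,
#'   colnames matching `samples$sample_id`).
#' @param samples sample sheet.
#' @param comparison string `"A_vs_B"` naming two conditions present in
#'   `samples` (e.g. `"SD1_vs_SD2"`).
#' @param pseudo_count added to normalized condition means before the log
#'   ratio; default 0.5.
#' @return data.frame with columns `feature_id`, `comparison`, `base_mean`,
#'   `log2fc`, `p_value`, `fdr`, `direction` (`up` iff fdr < 0.05 and
#'   log2fc >= 1; `down` iff fdr < 0.05 and log2fc <= -1; otherwise `ns`).
#' @export
nb_wald_test <- function(counts, samples, comparison, pseudo_count = 0.5) {
  conds <- strsplit(comparison, "_vs_", fixed = TRUE)[[1]]
  if (length(conds) != 2L || !all(conds %in% samples$condition))
    stop("comparison must be 'A_vs_B' with both conditions in the sample ",
         "sheet; got '", comparison, "'")
  cols_a <- samples$sample_id[samples$condition == conds[1]]
  cols_b <- samples$sample_id[samples$condition == conds[2]]
  if (length(cols_a) < 2L || length(cols_b) < 2L)
    stop("both conditions need >= 2 replicates")
  sf <- size_factors(counts)
  sub <- counts[, c(cols_a, cols_b), drop = FALSE]
  tested <- rowSums(sub) > 0L
  q <- sweep(counts[tested, , drop = FALSE], 2L, sf, "/")
  qa <- q[, cols_a, drop = FALSE]
  qb <- q[, cols_b, drop = FALSE]
  na <- length(cols_a); nb <- length(cols_b)
  mu_a <- rowMeans(qa); mu_b <- rowMeans(qb)
  var_a <- rowSums((qa - mu_a)^2) / (na - 1)
  var_b <- rowSums((qb - mu_b)^2) / (nb - 1)

  ## Method-of-moments dispersion per condition, df-weighted pool.  With
  ## only 2 residual df per condition the raw estimate is so noisy that its
  ## frequent collapse below the truth would inflate the Wald statistic, so
  ## each feature's dispersion is floored at the genome-wide median of the
  ## raw estimates (information sharing across features, in the spirit of
  ## DESeq2's fitted-trend lower bound) and then at 1e-8.
  mom <- function(m, v) ifelse(m > 0, (v - m) / m^2, NA_real_)
  aa <- mom(mu_a, var_a); ab <- mom(mu_b, var_b)
  w_a <- ifelse(is.na(aa), 0, na - 1); w_b <- ifelse(is.na(ab), 0, nb - 1)
  alpha_raw <- (ifelse(is.na(aa), 0, aa) * w_a +
                ifelse(is.na(ab), 0, ab) * w_b) / pmax(w_a + w_b, 1)
  alpha_global <- median(alpha_raw, na.rm = TRUE)
  alpha <- pmax(alpha_raw, alpha_global, 1e-8)

  log2fc <- log2((mu_b + pseudo_count) / (mu_a + pseudo_count))
  v_mu_a <- (mu_a + alpha * mu_a^2) / na
  v_mu_b <- (mu_b + alpha * mu_b^2) / nb
  se <- sqrt(v_mu_a / (mu_a + pseudo_count)^2 +
             v_mu_b / (mu_b + pseudo_count)^2) / log(2)
  z <- ifelse(se > 0, log2fc / se, 0)
  p <- 2 * pnorm(-abs(z))
  fdr <- bh_adjust(p)
  direction <- ifelse(fdr < 0.05 & log2fc >= 1, "up",
                      ifelse(fdr < 0.05 & log2fc <= -1, "down", "ns"))
  data.frame(feature_id = rownames(q),
             comparison = comparison,
             base_mean = rowMeans(cbind(qa, qb)),
             log2fc = log2fc,
             p_value = p,
             fdr = fdr,
             direction = direction,
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Tabulate differential-expression calls across comparisons
#'
#' Produces the per-comparison, per-feature-kind up/down/total counts (the
#' shape of the study's DE summary table).
#'
#' @param results named list of [nb_wald_test()] data.frames (one per
#'   comparison, possibly concatenating feature kinds).
#' @param kind_of optional named character vector mapping feature ids to a
#'   kind label (e.g. `"lncRNA"` / `"mRNA"`); unnamed features are labelled
#'   `"feature"`.
#' @return data.frame with columns `comparison`, `kind`, `total`, `up`,
#'   `down`.
#' @export
de_summary <- function(results, kind_of = NULL) {
  rows <- list()
  for (res in results) {
    kind <- if (is.null(kind_of)) rep("feature", nrow(res)) else {
      k <- kind_of[res$feature_id]
      ifelse(is.na(k), "feature", k)
    }
    for (kk in unique(kind)) {
      d <- res$direction[kind == kk]
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = res$comparison[1],
        kind = kk,
        total = sum(d != "ns"),
        up = sum(d == "up"),
        down = sum(d == "down"),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
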