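## Hypergeometric over-representation analysis of target gene sets.

#' Hypergeometric upper-tail test
#'
#' `P(X >= k)` where `X ~ Hypergeometric(N, K, n)`: drawing `n` genes from a
#' universe of `N` of which `K` carry the term, the probability of seeing at
#' least the observed `k` hits.
#'
#' @param k observed hits in the query.
#' @param K term size within the universe.
#' @param n query size.
#' @param N universe size.
#' @return upper-tail p-value.
#' @export
hypergeom_test <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(K, n))
    stop("inconsistent hypergeometric arguments: k=", k, " K=", K,
         " n=", n, " N=", N)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Gene-set over-representation analysis
#'
#' For every term with at least one universe gene, tests whether the query
#' set over-represents the term's genes via [hypergeom_test()]; raw p-values
#' are BH-corrected across all tested terms (a term is significant at
#' corrected p < 0.05).  Annotation rows are treated as sets, so duplicated
#' (term, gene) rows never double-count.
#'
#' @param query character vector of query gene ids (must be a subset of
#'   `universe`).
#' @param universe character vector of background gene ids.
#' @param gene_sets data.frame with columns `term_id`, `term_name`,
#'   `gene_id`.
#' @return data.frame sorted by `corrected_p` then `term_id`, with columns
#'   `term_id`, `term_name`, `k`, `K`, `n`, `N`, `p_value`, `corrected_p`.
#' @export
enrich <- function(query, universe, gene_sets) {
  query <- unique(query)
  universe <- unique(universe)
  outside <- setdiff(query, universe)
  if (length(outside) > 0L)
    stop("query gene(s) missing from the universe: ",
         paste(head(outside, 5), collapse = ", "))
  N <- length(universe)
  n <- length(query)
  gene_sets <- gene_sets[gene_sets$gene_id %in% universe, , drop = FALSE]
  terms <- unique(gene_sets$term_id)
  if (length(terms) == 0L)
    return(data.frame(term_id = character(), term_name = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p_value = numeric(),
                      corrected_p = numeric(), stringsAsFactors = FALSE))
  rows <- lapply(terms, function(tid) {
    sub <- gene_sets[gene_sets$term_id == tid, , drop = FALSE]
    genes <- unique(sub$gene_id)
    k <- length(intersect(genes, query))
    data.frame(term_id = tid, term_name = sub$term_name[1],
               k = k, K = length(genes), n = n, N = N,
               p_value = hypergeom_test(k, length(genes), n, N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$corrected_p <- bh_adjust(out$p_value)
  out <- out[order(out$corrected_p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
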