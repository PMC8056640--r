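## Bipartite lncRNA-mRNA regulatory networks, their intersection, and
## degree/hub statistics.

#' Build the regulatory network of one flowering label
#'
#' Induces the bipartite subnetwork on lncRNAs carrying the given label:
#' their cis and trans target pairs become mode-tagged edges; duplicate
#' (lncRNA, mRNA, mode) edges are collapsed.
#'
#' @param calls [call_flowering()] result.
#' @param pairs target pairs over the full universe (rows from
#'   [cis_targets()] and/or [trans_targets()], row-bound; missing `pcc` /
#'   `distance_bp` columns are filled with `NA`).
#' @param label `"positive"` or `"negative"`.
#' @return object of class `regulatory_network`: list with `label`, `edges`
#'   (data.frame `lncrna_id`, `mrna_id`, `mode`, `distance_bp`, `pcc`,
#'   `p_value`), `lncrna_nodes`, `mrna_nodes`, and `degree` (named integer
#'   vector over all nodes).
#' @export
build_network <- function(calls, pairs, label = c("positive", "negative")) {
  label <- match.arg(label)
  for (col in c("distance_bp", "pcc", "p_value"))
    if (is.null(pairs[[col]])) pairs[[col]] <- NA_real_
  keep_lnc <- calls$lncrna_id[calls$label == label]
  e <- pairs[pairs$lncrna_id %in% keep_lnc, , drop = FALSE]
  e <- e[!duplicated(e[, c("lncrna_id", "mrna_id", "mode")]), , drop = FALSE]
  e <- e[order(e$lncrna_id, e$mrna_id, e$mode), , drop = FALSE]
  rownames(e) <- NULL
  deg <- table(c(e$lncrna_id, e$mrna_id))
  structure(list(
    label = label,
    edges = e[, c("lncrna_id", "mrna_id", "mode", "distance_bp", "pcc",
                  "p_value")],
    lncrna_nodes = sort(unique(e$lncrna_id)),
    mrna_nodes = sort(unique(e$mrna_id)),
    degree = setNames(as.integer(deg), names(deg))),
    class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat("regulatory_network (", x$label, "): ",
      length(x$lncrna_nodes), " lncRNAs, ", length(x$mrna_nodes),
      " mRNA targets, ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Common targets of the positive and negative networks
#'
#' Intersects the mRNA target sets (union of cis and trans targets per
#' network) and reports each network's share of common targets as a
#' percentage rounded to 2 decimals.
#'
#' @param pos,neg [build_network()] results.
#' @param mode `"union"` (default; pooled cis+trans targets) or `"trans"`
#'   (trans targets only).
#' @return list with `common` (sorted character vector),
#'   `share_of_pos_pct`, `share_of_neg_pct` (`NA` for an empty target set).
#' @export
common_targets <- function(pos, neg, mode = c("union", "trans")) {
  mode <- match.arg(mode)
  tset <- function(net) {
    e <- net$edges
    if (mode == "trans") e <- e[e$mode == "trans", , drop = FALSE]
    unique(e$mrna_id)
  }
  tp <- tset(pos); tn <- tset(neg)
  common <- sort(intersect(tp, tn))
  share <- function(tt) if (length(tt) == 0L) NA_real_ else
    round(100 * length(common) / length(tt), 2)
  list(common = common,
       share_of_pos_pct = share(tp),
       share_of_neg_pct = share(tn))
}

#' Top-k hub nodes per network side
#'
#' Stable degree ranking (ties broken lexicographically by node id) of the
#' lncRNA and mRNA sides separately.
#'
#' @param net [build_network()] result; must be non-empty.
#' @param k number of top nodes per side (> 0).
#' @return data.frame with columns `side` (`lncRNA`/`mRNA`), `node`,
#'   `degree`; at most `k` rows per side.
#' @export
hub_report <- function(net, k) {
  stopifnot(inherits(net, "regulatory_network"))
  if (k <= 0) stop("k must be > 0")
  if (nrow(net$edges) == 0L) stop("network is empty")
  side_top <- function(nodes, side) {
    deg <- net$degree[nodes]
    o <- order(-deg, names(deg))
    data.frame(side = side,
               node = names(deg)[o][seq_len(min(k, length(deg)))],
               degree = as.integer(deg[o][seq_len(min(k, length(deg)))]),
               stringsAsFactors = FALSE)
  }
  out <- rbind(side_top(net$lncrna_nodes, "lncRNA"),
               side_top(net$mrna_nodes, "mRNA"))
  rownames(out) <- NULL
  out
}
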