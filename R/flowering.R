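## The two-comparison direction logic: antagonistic SD/NB responses define
## putative positive and negative flowering regulators.

#' Call putative positive and negative flowering lncRNAs
#'
#' A lncRNA up-regulated in SD1_vs_SD2 (SD-induced) and down-regulated in
#' SD2_vs_NB (NB-repressed) is a putative **positive** flowering regulator;
#' the reverse pattern is **negative**; every other combination (including
#' lncRNAs differentially expressed in only one comparison) is `none`.
#'
#' @param de_sd [nb_wald_test()] results for the SD1_vs_SD2 comparison,
#'   restricted to lncRNAs.
#' @param de_nb likewise for SD2_vs_NB.
#' @return data.frame with columns `lncrna_id`, `dir_sd`, `dir_nb`, `label`
#'   (`positive` / `negative` / `none`) over the union of the two feature
#'   universes (features absent from one comparison are `ns` there).
#' @export
call_flowering <- function(de_sd, de_nb) {
  for (res in list(de_sd, de_nb)) {
    dup <- res$feature_id[duplicated(res$feature_id)]
    conflict <- vapply(unique(dup), function(id) {
      length(unique(res$direction[res$feature_id == id])) > 1L
    }, logical(1))
    if (any(conflict))
      stop("conflicting duplicate DE rows for: ",
           paste(unique(dup)[conflict], collapse = ", "))
  }
  ids <- union(de_sd$feature_id, de_nb$feature_id)
  dir_sd <- de_sd$direction[match(ids, de_sd$feature_id)]
  dir_nb <- de_nb$direction[match(ids, de_nb$feature_id)]
  dir_sd[is.na(dir_sd)] <- "ns"
  dir_nb[is.na(dir_nb)] <- "ns"
  label <- ifelse(dir_sd == "up" & dir_nb == "down", "positive",
                  ifelse(dir_sd == "down" & dir_nb == "up", "negative",
                         "none"))
  data.frame(lncrna_id = ids, dir_sd = dir_sd, dir_nb = dir_nb,
             label = label, stringsAsFactors = FALSE)
}

#' Two-comparison Venn census of DE lncRNAs
#'
#' Standard two-set census (sole responders, shared responders, union) plus
#' the count of shared members whose directions are opposite in the two
#' comparisons (the antagonistic pool that the flowering labels partition).
#'
#' @param de_sd,de_nb [nb_wald_test()] result data.frames for the two
#'   comparisons.
#' @return named integer vector: `n_sd_only`, `n_nb_only`, `n_both`,
#'   `n_union`, `n_opposite`.
#' @export
venn_census <- function(de_sd, de_nb) {
  set_sd <- de_sd$feature_id[de_sd$direction != "ns"]
  set_nb <- de_nb$feature_id[de_nb$direction != "ns"]
  both <- intersect(set_sd, set_nb)
  d_sd <- de_sd$direction[match(both, de_sd$feature_id)]
  d_nb <- de_nb$direction[match(both, de_nb$feature_id)]
  c(n_sd_only = length(setdiff(set_sd, set_nb)),
    n_nb_only = length(setdiff(set_nb, set_sd)),
    n_both = length(both),
    n_union = length(union(set_sd, set_nb)),
    n_opposite = sum(d_sd != d_nb))
}
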