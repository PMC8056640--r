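## End-to-end orchestration: simulate (or load) inputs, then identify ->
## express -> de -> targets -> flower -> network -> enrich, with a
## machine-readable JSON summary.  Identical config + seed give a
## byte-identical summary.

#' Pipeline configuration
#'
#' Collects every stage threshold; the defaults reproduce the study's
#' stated cutoffs (lncRNA candidates > 200 bp and >= 2 exons, 300 nt ORF
#' coding rule, expressed at mean FPKM > 0.1 / > 1 for lncRNA / mRNA,
#' FDR < 0.05 with |log2FC| >= 1, 100 kb cis window, |PCC| > 0.9 with
#' p < 0.01 for trans pairs, enrichment at corrected p < 0.05).
#'
#' @param seed integer seed driving simulation and gene-set fixtures.
#' @param min_length_bp,min_exons lncRNA candidate filter.
#' @param orf_threshold_nt in-house coding-potential ORF cutoff.
#' @param fpkm_threshold_lncrna,fpkm_threshold_mrna expressed-set cutoffs.
#' @param fdr_threshold,lfc_threshold DE call thresholds (`fdr_threshold`
#'   feeds the direction rule through the fdr < 0.05 contract only when
#'   left at 0.05; other values re-derive directions).
#' @param window_bp cis window.
#' @param pcc_cutoff,p_cutoff trans-pair cutoffs.
#' @param enrich_threshold significance cutoff on corrected p.
#' @param comparisons character vector of `A_vs_B` comparisons; the first
#'   is the SD progression, the second the NB response.
#' @param simulation a [simulation_config()] used when `run_pipeline()` is
#'   asked to simulate; its seed is overridden by `seed`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            min_length_bp = 200L,
                            min_exons = 2L,
                            orf_threshold_nt = 300L,
                            fpkm_threshold_lncrna = 0.1,
                            fpkm_threshold_mrna = 1,
                            fdr_threshold = 0.05,
                            lfc_threshold = 1,
                            window_bp = 100000L,
                            pcc_cutoff = 0.9,
                            p_cutoff = 0.01,
                            enrich_threshold = 0.05,
                            comparisons = c("SD1_vs_SD2", "SD2_vs_NB"),
                            simulation = simulation_config()) {
  cfg <- as.list(environment())
  cfg$simulation$seed <- as.integer(seed)
  stopifnot(length(cfg$comparisons) == 2L)
  structure(cfg, class = "pipeline_config")
}

redirect <- function(res, fdr_threshold, lfc_threshold) {
  res$direction <- ifelse(res$fdr < fdr_threshold &
                            res$log2fc >= lfc_threshold, "up",
                          ifelse(res$fdr < fdr_threshold &
                                   res$log2fc <= -lfc_threshold, "down",
                                 "ns"))
  res
}

#' Run the full inference chain
#'
#' With `simulate = TRUE` (default) the study inputs come from
#' [simulate_study()] under `config$simulation`; alternatively pass an
#' existing `lnc_study`-shaped list (`annotation`, `reference`,
#' `sequences`, `lengths`, `counts`, `samples`, `feature_kind`, optionally
#' `truth` and `chrom_lengths`).  Stage outputs are written as TSV to
#' `out_dir` together with `summary.json`; when planted truth is available
#' the summary also reports recovery metrics (flowering-label precision and
#' recall, exact cis-pair agreement, trans-pair recall).
#'
#' @param out_dir output directory; created if needed.
#' @param config a [pipeline_config()].
#' @param simulate generate the inputs with the simulator?
#' @param study study inputs when `simulate = FALSE`.
#' @param external_verdicts optional external coding-potential table
#'   (see [score_coding_potential()]).
#' @return the summary, invisibly (a nested list mirroring
#'   `summary.json`).
#' @export
run_pipeline <- function(out_dir, config = pipeline_config(),
                         simulate = TRUE, study = NULL,
                         external_verdicts = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (simulate) study <- simulate_study(config$simulation)
  if (is.null(study)) stop("either simulate = TRUE or supply `study`")

  samples <- study$samples
  reference_ids <- study$reference$transcripts$transcript_id
  tr <- study$annotation$transcripts

  ## ---- identify -----------------------------------------------------------
  novel_ids <- setdiff(tr$transcript_id, reference_ids)
  verdicts <- score_coding_potential(study$sequences[novel_ids],
                                     external = external_verdicts,
                                     orf_threshold_nt = config$orf_threshold_nt)
  candidates <- filter_lncrna_candidates(study$annotation, verdicts,
                                         reference_ids = reference_ids,
                                         min_length_bp = config$min_length_bp,
                                         min_exons = config$min_exons)
  lnc_ann <- subset_annotation(study$annotation, candidates$transcript_id)
  classification <- classify_position(lnc_ann, study$reference)
  census <- if (!is.null(study$chrom_lengths))
    class_census(classification, lnc_ann, study$chrom_lengths) else NULL
  write.table(merge(candidates, classification, by = "transcript_id"),
              file.path(out_dir, "lncrnas.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  lnc_genes <- sort(unique(candidates$gene_id))
  mrna_genes <- sort(unique(study$reference$transcripts$gene_id))

  ## ---- express ------------------------------------------------------------
  counts <- study$counts
  fpkm <- compute_fpkm(counts, study$lengths)
  venn_lnc <- expressed_sets(fpkm[rownames(fpkm) %in% lnc_genes, ,
                                  drop = FALSE],
                             samples, "lncRNA",
                             threshold = config$fpkm_threshold_lncrna)
  venn_mrna <- expressed_sets(fpkm[rownames(fpkm) %in% mrna_genes, ,
                                   drop = FALSE],
                              samples, "mRNA",
                              threshold = config$fpkm_threshold_mrna)
  qc <- sample_correlation(fpkm)

  ## ---- differential expression -------------------------------------------
  de <- lapply(config$comparisons, function(cmp)
    redirect(nb_wald_test(counts, samples, cmp),
             config$fdr_threshold, config$lfc_threshold))
  names(de) <- config$comparisons
  kind <- setNames(ifelse(names(study$feature_kind) %in% lnc_genes,
                          "lncRNA",
                          ifelse(names(study$feature_kind) %in% mrna_genes,
                                 "mRNA", "other")),
                   names(study$feature_kind))
  summary_de <- de_summary(de, kind_of = kind)
  for (cmp in config$comparisons)
    write.table(de[[cmp]], file.path(out_dir, paste0("de_", cmp, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)

  ## ---- targets ------------------------------------------------------------
  cis <- cis_targets(lnc_ann, study$reference, window_bp = config$window_bp)
  trans <- trans_targets(fpkm[intersect(rownames(fpkm), lnc_genes), ,
                              drop = FALSE],
                         fpkm[intersect(rownames(fpkm), mrna_genes), ,
                              drop = FALSE],
                         pcc_cutoff = config$pcc_cutoff,
                         p_cutoff = config$p_cutoff)
  pairs <- rbind(
    data.frame(lncrna_id = cis$lncrna_id, mrna_id = cis$mrna_id,
               mode = "cis", distance_bp = cis$distance_bp,
               pcc = NA_real_, p_value = NA_real_,
               stringsAsFactors = FALSE),
    data.frame(lncrna_id = trans$lncrna_id, mrna_id = trans$mrna_id,
               mode = "trans", distance_bp = NA_integer_, pcc = trans$pcc,
               p_value = trans$p_value, stringsAsFactors = FALSE))
  write.table(pairs, file.path(out_dir, "target_pairs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  ## ---- flowering calls ----------------------------------------------------
  de_lnc <- lapply(de, function(res)
    res[res$feature_id %in% lnc_genes, , drop = FALSE])
  calls <- call_flowering(de_lnc[[1]], de_lnc[[2]])
  venn <- venn_census(de_lnc[[1]], de_lnc[[2]])
  write.table(calls, file.path(out_dir, "flowering_calls.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  ## ---- networks -----------------------------------------------------------
  net_pos <- build_network(calls, pairs, "positive")
  net_neg <- build_network(calls, pairs, "negative")
  shared <- common_targets(net_pos, net_neg)
  write_edge_list(net_pos, file.path(out_dir, "network_positive.tsv"))
  write_edge_list(net_neg, file.path(out_dir, "network_negative.tsv"))

  ## ---- enrichment ---------------------------------------------------------
  universe <- rownames(counts)[rowSums(counts) > 0]
  universe <- intersect(universe, mrna_genes)
  set.seed(config$seed + 1L)
  gene_sets <- if (!is.null(study$truth))
    emit_gene_sets(study$truth, universe) else NULL
  enr_pos <- if (!is.null(gene_sets) && length(net_pos$mrna_nodes) > 0L)
    enrich(intersect(net_pos$mrna_nodes, universe), universe, gene_sets)
  else NULL
  if (!is.null(enr_pos))
    write.table(enr_pos, file.path(out_dir, "enrichment_positive.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)

  ## ---- recovery metrics (simulated truth only) ----------------------------
  recovery <- NULL
  if (!is.null(study$truth)) {
    truth <- study$truth
    prf <- function(label) {
      called <- calls$lncrna_id[calls$label == label]
      planted <- truth$planted_class$gene_id[truth$planted_class$label ==
                                               label]
      tp <- length(intersect(called, planted))
      list(precision = if (length(called) > 0) tp / length(called) else NA,
           recall = if (length(planted) > 0) tp / length(planted) else NA)
    }
    key <- function(df) paste(df$lncrna_id, df$mrna_id)
    cls_truth <- truth$positional_class
    cls_hat <- classification$class[match(cls_truth$transcript_id,
                                          classification$transcript_id)]
    trans_truth_keys <- key(truth$trans_pairs)
    recovery <- list(
      positive = prf("positive"),
      negative = prf("negative"),
      positional_agreement = mean(cls_hat == cls_truth$class, na.rm = TRUE),
      cis_exact = setequal(key(cis), key(truth$cis_pairs)),
      trans_recall = if (length(trans_truth_keys) > 0)
        mean(trans_truth_keys %in% key(trans)) else NA)
  }

  summary <- list(
    thresholds = config[c("min_length_bp", "min_exons", "orf_threshold_nt",
                          "fpkm_threshold_lncrna", "fpkm_threshold_mrna",
                          "fdr_threshold", "lfc_threshold", "window_bp",
                          "pcc_cutoff", "p_cutoff", "enrich_threshold")],
    seed = config$seed,
    n_transcripts = nrow(tr),
    n_lncrnas = nrow(candidates),
    class_counts = if (!is.null(census)) as.list(census$class_counts)
    else as.list(table(classification$class)),
    overall_density_per_mb = if (!is.null(census))
      census$overall_density_per_mb else NULL,
    expressed_venn_lncrna = as.list(venn_lnc$venn),
    expressed_venn_mrna = as.list(venn_mrna$venn),
    min_sample_spearman = min(qc, na.rm = TRUE),
    de_summary = summary_de,
    de_venn = as.list(venn),
    n_positive = sum(calls$label == "positive"),
    n_negative = sum(calls$label == "negative"),
    n_cis_pairs = nrow(cis),
    n_trans_pairs = nrow(trans),
    network_positive = list(n_lncrna = length(net_pos$lncrna_nodes),
                            n_targets = length(net_pos$mrna_nodes),
                            n_edges = nrow(net_pos$edges)),
    network_negative = list(n_lncrna = length(net_neg$lncrna_nodes),
                            n_targets = length(net_neg$mrna_nodes),
                            n_edges = nrow(net_neg$edges)),
    n_common_targets = length(shared$common),
    common_target_share_pos_pct = shared$share_of_pos_pct,
    common_target_share_neg_pct = shared$share_of_neg_pct,
    top_enriched_term = if (!is.null(enr_pos) && nrow(enr_pos) > 0)
      list(term_id = enr_pos$term_id[1],
           corrected_p = enr_pos$corrected_p[1]) else NULL,
    recovery = recovery)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(summary)
}
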