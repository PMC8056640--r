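## Synthetic study generator: a toy multi-chromosome annotation with
## noncoding transcripts of every positional class, transcript sequences
## (long ORFs for coding genes, short ORFs for lncRNAs), and a
## negative-binomial count matrix with planted condition effects and
## planted cis / trans target structure.  Ground truth is recorded so every
## downstream stage can be validated end-to-end.

#' Configuration for the study simulator
#'
#' Defaults encode the study design the pipeline targets: 3 conditions
#' (SD1, SD2, NB) x 3 replicates, planted regulators whose condition means
#' move up SD1->SD2 and down SD2->NB (positive) or the reverse (negative)
#' by `effect_log2fc`, a shared NB dispersion `alpha` (variance
#' `mu + alpha mu^2`), and trans targets tied to their regulator through a
#' shared per-sample latent factor scaled to reach `trans_target_corr`.
#'
#' @param seed integer RNG seed; a fixed seed makes all outputs
#'   bit-identical across runs.
#' @param n_chromosomes,chrom_length toy genome shape (default 2 x 2 Mb).
#' @param n_coding_genes number of protein-coding genes (default 200).
#' @param n_lncrnas_per_class named integer vector over
#'   `lincRNA`/`intronic`/`sense`/`antisense` (default 25/5/5/5).
#' @param n_planted_positive,n_planted_negative planted regulator counts
#'   (drawn from the lincRNA pool).
#' @param effect_log2fc planted |log2 fold change| per condition transition
#'   (>= 1 if planted regulators must pass the DE threshold).
#' @param nb_dispersion NB dispersion `alpha` shared genome-wide (0 gives
#'   Poisson counts).
#' @param mean_expression_log_range log10 range for baseline means; lncRNAs
#'   are shifted half a decade lower than mRNAs, and planted features are
#'   drawn from the top decade so regulators are well expressed.
#' @param cis_fraction fraction of planted regulators placed within 100 kb
#'   of a coding gene (the rest sit in a gene desert > 100 kb from all
#'   genes).
#' @param trans_target_corr target Pearson correlation for planted trans
#'   pairs, in \[0, 1\].
#' @param n_trans_targets_per_lncrna planted trans targets per regulator.
#' @param library_size_range per-sample library-size factors are drawn
#'   log-uniformly from this interval, so size-factor estimation is
#'   exercised non-trivially.
#' @return object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(seed = 1L,
                              n_chromosomes = 2L,
                              chrom_length = 2e6,
                              n_coding_genes = 200L,
                              n_lncrnas_per_class = c(lincRNA = 25L,
                                                      intronic = 5L,
                                                      sense = 5L,
                                                      antisense = 5L),
                              n_planted_positive = 10L,
                              n_planted_negative = 10L,
                              effect_log2fc = 3,
                              nb_dispersion = 0.05,
                              mean_expression_log_range = c(1, 3),
                              cis_fraction = 0.5,
                              trans_target_corr = 0.99,
                              n_trans_targets_per_lncrna = 5L,
                              library_size_range = c(0.7, 1.4)) {
  cfg <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
              chrom_length = chrom_length,
              n_coding_genes = as.integer(n_coding_genes),
              n_lncrnas_per_class = n_lncrnas_per_class,
              n_planted_positive = as.integer(n_planted_positive),
              n_planted_negative = as.integer(n_planted_negative),
              effect_log2fc = effect_log2fc,
              nb_dispersion = nb_dispersion,
              mean_expression_log_range = mean_expression_log_range,
              cis_fraction = cis_fraction,
              trans_target_corr = trans_target_corr,
              n_trans_targets_per_lncrna = as.integer(n_trans_targets_per_lncrna),
              library_size_range = library_size_range)
  classes <- c("lincRNA", "intronic", "sense", "antisense")
  if (!all(classes %in% names(cfg$n_lncrnas_per_class)))
    stop("n_lncrnas_per_class needs entries for ",
         paste(classes, collapse = ", "))
  cfg$n_lncrnas_per_class <- cfg$n_lncrnas_per_class[classes]
  stopifnot(cfg$n_chromosomes >= 1, cfg$chrom_length > 0,
            cfg$n_coding_genes >= 1, all(cfg$n_lncrnas_per_class >= 0),
            cfg$n_planted_positive >= 0, cfg$n_planted_negative >= 0,
            cfg$effect_log2fc >= 0, cfg$nb_dispersion >= 0,
            length(cfg$mean_expression_log_range) == 2,
            diff(cfg$mean_expression_log_range) >= 0,
            cfg$cis_fraction >= 0, cfg$cis_fraction <= 1,
            cfg$trans_target_corr >= 0, cfg$trans_target_corr <= 1,
            cfg$n_trans_targets_per_lncrna >= 0,
            all(cfg$library_size_range > 0))
  n_planted <- cfg$n_planted_positive + cfg$n_planted_negative
  if (n_planted > cfg$n_lncrnas_per_class[["lincRNA"]])
    stop("planted regulators exceed the lincRNA pool")
  structure(cfg, class = "simulation_config")
}

sense_codons <- function() {
  bases <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
}

random_noncoding_seq <- function(len, max_orf_nt) {
  bases <- c("A", "C", "G", "T")
  for (try in 1:100) {
    s <- paste(sample(bases, len, replace = TRUE), collapse = "")
    if (find_longest_orf(s) < max_orf_nt) return(s)
  }
  stop("failed to draw a short-ORF sequence of length ", len)
}

coding_seq <- function(total_len, orf_len = 990L) {
  bases <- c("A", "C", "G", "T")
  utr5 <- floor((total_len - orf_len) / 2)
  utr3 <- total_len - orf_len - utr5
  paste0(paste(sample(bases, utr5, replace = TRUE), collapse = ""),
         "ATG",
         paste(sample(sense_codons(), orf_len / 3 - 2, replace = TRUE),
               collapse = ""),
         "TAA",
         paste(sample(bases, utr3, replace = TRUE), collapse = ""))
}

## independent brute-force cis scan used to record the planted truth
brute_force_cis <- function(lnc_tr, ref_tr, window_bp = 100000L) {
  gene_span <- function(tr) {
    by_g <- split(seq_len(nrow(tr)), tr$gene_id)
    data.frame(gene_id = names(by_g),
               chrom = vapply(by_g, function(i) tr$chrom[i][1], character(1)),
               start = vapply(by_g, function(i) min(tr$start[i]), integer(1)),
               end = vapply(by_g, function(i) max(tr$end[i]), integer(1)),
               stringsAsFactors = FALSE)
  }
  ls <- gene_span(lnc_tr); rs <- gene_span(ref_tr)
  rows <- list()
  for (i in seq_len(nrow(ls))) {
    same <- rs[rs$chrom == ls$chrom[i], , drop = FALSE]
    if (nrow(same) == 0L) next
    gap <- ifelse(same$start > ls$end[i], same$start - ls$end[i] - 1L,
                  ifelse(ls$start[i] > same$end, ls$start[i] - same$end - 1L,
                         0L))
    hit <- which(gap <= window_bp)
    if (length(hit) > 0L)
      rows[[length(rows) + 1L]] <- data.frame(
        lncrna_id = ls$gene_id[i], mrna_id = same$gene_id[hit],
        distance_bp = as.integer(gap[hit]), stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(lncrna_id = character(), mrna_id = character(),
                      distance_bp = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$lncrna_id, out$mrna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate a complete toy study with planted ground truth
#'
#' Generates the genome geometry (coding genes plus lncRNAs of all four
#' positional classes, realized unambiguously), transcript sequences (long
#' ORFs in coding genes, short ORFs in lncRNAs), and a gene-level NB count
#' matrix for the 3 x 3 design, then records planted truth: regulator
#' labels, positional classes, all cis pairs within the 100 kb window
#' (computed by an independent brute-force scan), and planted trans pairs.
#'
#' @param config a [simulation_config()].
#' @return object of class `lnc_study`: list with `config`,
#'   `chrom_lengths`, `annotation` (assembled models: coding + lncRNA),
#'   `reference` (coding only), `sequences`, `lengths`, `counts`, `samples`,
#'   `feature_kind` (named vector gene -> `mRNA`/`lncRNA`),
#'   `base_mean_log10` and `lib_factors` (the drawn expression model), and
#'   `truth`
#'   (list: `planted_class`, `positional_class`, `cis_pairs`,
#'   `trans_pairs`).
#' @export
simulate_study <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  window_bp <- 100000L
  L <- config$chrom_length
  n_chr <- config$n_chromosomes
  chrom_lengths <- setNames(rep(L, n_chr), paste0("chr", seq_len(n_chr)))

  ## ---- coding gene placement (span 4200 bp, 3 exons) ----------------------
  per_chr <- diff(floor(seq(0, config$n_coding_genes, length.out = n_chr + 1)))
  region_start <- 10001L
  region_end <- round(0.7 * L)
  gene_tab <- list()
  for (ci in seq_len(n_chr)) {
    ng <- per_chr[ci]
    if (ng == 0L) next
    slot <- (region_end - region_start) / ng
    if (slot < 10000)
      stop("chromosome too short for the requested number of coding genes")
    starts <- as.integer(region_start + (seq_len(ng) - 1L) * slot +
                           sample(0:1000, ng, replace = TRUE))
    gene_tab[[ci]] <- data.frame(
      chrom = names(chrom_lengths)[ci],
      gstart = starts,
      strand = sample(c("+", "-"), ng, replace = TRUE),
      stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, gene_tab)
  genes$gene_id <- sprintf("AUR%05d", seq_len(nrow(genes)))
  genes$transcript_id <- paste0(genes$gene_id, ".1")

  exon_offsets <- list(c(0L, 299L), c(1800L, 2199L), c(3700L, 4199L))
  coding_exons <- do.call(rbind, lapply(exon_offsets, function(off)
    data.frame(chrom = genes$chrom, start = genes$gstart + off[1],
               end = genes$gstart + off[2], strand = genes$strand,
               gene_id = genes$gene_id, transcript_id = genes$transcript_id,
               stringsAsFactors = FALSE)))

  ## ---- lncRNA layout ------------------------------------------------------
  npc <- config$n_lncrnas_per_class
  n_pos <- config$n_planted_positive
  n_neg <- config$n_planted_negative
  n_planted <- n_pos + n_neg
  n_linc <- npc[["lincRNA"]]
  n_lnc <- sum(npc)

  ## interleave positive/negative so cis placement covers both labels
  planted_label <- rep("none", n_linc)
  inter <- as.vector(rbind(
    c(rep("positive", n_pos), rep(NA, max(0, n_neg - n_pos))),
    c(rep("negative", n_neg), rep(NA, max(0, n_pos - n_neg)))))
  inter <- inter[!is.na(inter)]
  planted_label[seq_len(n_planted)] <- inter

  lnc <- data.frame(
    idx = seq_len(n_lnc),
    class = rep(c("lincRNA", "intronic", "sense", "antisense"), npc),
    label = c(planted_label, rep("none", n_lnc - n_linc)),
    stringsAsFactors = FALSE)
  lnc$gene_id <- sprintf("MSTRG.%d", lnc$idx)
  lnc$transcript_id <- paste0(lnc$gene_id, ".1")

  n_cis <- round(config$cis_fraction * n_planted)
  lnc$placement <- "desert"
  if (n_cis > 0L) lnc$placement[seq_len(n_cis)] <- "near_gene"
  lnc$placement[lnc$class != "lincRNA"] <- "host"

  n_hosts <- n_cis + sum(npc[c("intronic", "sense", "antisense")])
  if (n_hosts > nrow(genes))
    stop("config demands more cis/host placements than available coding genes")
  hosts <- sample(genes$gene_id, n_hosts)
  host_of <- character(n_lnc)
  host_of[lnc$placement == "near_gene"] <- hosts[seq_len(n_cis)]
  host_of[lnc$class == "intronic"] <-
    hosts[n_cis + seq_len(npc[["intronic"]])]
  host_of[lnc$class == "sense"] <-
    hosts[n_cis + npc[["intronic"]] + seq_len(npc[["sense"]])]
  host_of[lnc$class == "antisense"] <-
    hosts[n_cis + npc[["intronic"]] + npc[["sense"]] +
            seq_len(npc[["antisense"]])]

  desert_cursor <- setNames(rep(as.integer(region_end + window_bp + 10000L),
                                n_chr), names(chrom_lengths))
  desert_chr <- 1L

  lnc_exons <- list()
  for (i in seq_len(n_lnc)) {
    cls <- lnc$class[i]
    if (lnc$placement[i] == "desert") {
      chrom <- names(chrom_lengths)[desert_chr]
      s0 <- desert_cursor[[chrom]]
      if (s0 + 600L > L - 1000L)
        stop("gene desert exhausted; reduce lincRNA count or enlarge genome")
      desert_cursor[[chrom]] <- s0 + 2000L
      desert_chr <- desert_chr %% n_chr + 1L
      strand <- sample(c("+", "-"), 1)
      ex <- data.frame(start = s0 + c(0L, 280L), end = s0 + c(179L, 459L))
    } else {
      hg <- genes[genes$gene_id == host_of[i], , drop = FALSE]
      chrom <- hg$chrom; g0 <- hg$gstart
      if (lnc$placement[i] == "near_gene") {
        strand <- sample(c("+", "-"), 1)
        ex <- data.frame(start = g0 + 6200L + c(0L, 280L),
                         end = g0 + 6200L + c(179L, 459L))
      } else if (cls == "intronic") {
        strand <- hg$strand
        ex <- data.frame(start = g0 + c(400L, 680L),
                         end = g0 + c(599L, 829L))
      } else if (cls == "sense") {
        strand <- hg$strand
        ex <- data.frame(start = g0 + c(100L, 600L),
                         end = g0 + c(349L, 749L))
      } else {  # antisense
        strand <- if (hg$strand == "+") "-" else "+"
        ex <- data.frame(start = g0 + c(2000L, 2400L),
                         end = g0 + c(2199L, 2549L))
      }
    }
    lnc_exons[[i]] <- data.frame(chrom = chrom, start = ex$start,
                                 end = ex$end, strand = strand,
                                 gene_id = lnc$gene_id[i],
                                 transcript_id = lnc$transcript_id[i],
                                 stringsAsFactors = FALSE)
  }
  lnc_exons <- do.call(rbind, lnc_exons)

  reference <- annotation_set(coding_exons)
  annotation <- annotation_set(rbind(coding_exons, lnc_exons))

  ## ---- sequences ----------------------------------------------------------
  tr <- annotation$transcripts
  sequences <- character(nrow(tr))
  names(sequences) <- tr$transcript_id
  for (tid in genes$transcript_id)
    sequences[tid] <- coding_seq(
      tr$spliced_length[tr$transcript_id == tid])
  for (tid in lnc$transcript_id)
    sequences[tid] <- random_noncoding_seq(
      tr$spliced_length[tr$transcript_id == tid], max_orf_nt = 300L)

  ## ---- expression model ---------------------------------------------------
  samples <- sample_sheet()
  conds <- c("SD1", "SD2", "NB")
  n_s <- nrow(samples)
  feature_ids <- c(genes$gene_id, lnc$gene_id)
  feature_kind <- setNames(c(rep("mRNA", nrow(genes)),
                             rep("lncRNA", n_lnc)), feature_ids)

  lo <- config$mean_expression_log_range[1]
  hi <- config$mean_expression_log_range[2]
  planted_lo <- max(lo, hi - 1)

  base_log10 <- setNames(numeric(length(feature_ids)), feature_ids)
  base_log10[genes$gene_id] <- runif(nrow(genes), lo, hi)
  base_log10[lnc$gene_id] <- runif(n_lnc, lo, hi) - 0.5

  planted_lnc <- lnc[lnc$label != "none", , drop = FALSE]
  e <- config$effect_log2fc
  profile_of <- function(label)  # log2 multiplier per condition
    if (label == "positive") c(SD1 = 0, SD2 = e, NB = 0) else
      c(SD1 = e, SD2 = 0, NB = e)

  ## planted trans targets: disjoint mRNA modules per regulator
  target_pool <- genes$gene_id
  trans_pairs <- list()
  group_of <- setNames(rep(NA_integer_, length(feature_ids)), feature_ids)
  for (j in seq_len(nrow(planted_lnc))) {
    n_t <- min(config$n_trans_targets_per_lncrna, length(target_pool))
    tg <- if (n_t > 0L) sample(target_pool, n_t) else character()
    target_pool <- setdiff(target_pool, tg)
    group_of[c(planted_lnc$gene_id[j], tg)] <- j
    if (n_t > 0L)
      trans_pairs[[j]] <- data.frame(lncrna_id = planted_lnc$gene_id[j],
                                     mrna_id = tg, stringsAsFactors = FALSE)
  }
  trans_pairs <- if (length(trans_pairs) > 0L) do.call(rbind, trans_pairs) else
    data.frame(lncrna_id = character(), mrna_id = character(),
               stringsAsFactors = FALSE)

  ## planted features are well expressed (top decade)
  planted_features <- feature_ids[!is.na(group_of)]
  base_log10[planted_features] <- runif(length(planted_features),
                                        planted_lo, hi)

  ## Count model.  Regulators (and all non-target features) are drawn first
  ## as plain NB around their condition means, so planted DE signal carries
  ## no extra within-condition variance.  Each planted target then shares
  ## its regulator's realized normalized log2 profile as the module latent
  ## factor, with a loading sized so the pair correlation reaches
  ## trans_target_corr in expectation against the target's own NB noise.
  alpha <- config$nb_dispersion
  ln2sq <- log(2)^2
  rho <- min(config$trans_target_corr, 0.999)
  cond_of_sample <- samples$condition
  lsr <- config$library_size_range
  lib_factor <- exp(runif(n_s, log(lsr[1]), log(lsr[2])))
  draw_counts <- function(mu)
    if (alpha > 0) rnbinom(length(mu), mu = mu, size = 1 / alpha)
    else rpois(length(mu), lambda = mu)

  log2mu <- matrix(rep(base_log10 * log2(10), n_s),
                   nrow = length(feature_ids), ncol = n_s,
                   dimnames = list(feature_ids, samples$sample_id))
  for (j in seq_len(nrow(planted_lnc))) {
    prof <- profile_of(planted_lnc$label[j])
    lid <- planted_lnc$gene_id[j]
    log2mu[lid, ] <- log2mu[lid, ] + prof[cond_of_sample]
  }

  is_target <- feature_ids %in% trans_pairs$mrna_id
  counts <- matrix(0L, nrow = length(feature_ids), ncol = n_s,
                   dimnames = list(feature_ids, samples$sample_id))
  mu_first <- sweep(2^log2mu[!is_target, , drop = FALSE], 2L, lib_factor,
                    "*")
  counts[!is_target, ] <- draw_counts(mu_first)

  if (any(is_target)) {
    v_target_noise <- (10^-planted_lo + alpha) / ln2sq
    for (j in seq_len(nrow(planted_lnc))) {
      lid <- planted_lnc$gene_id[j]
      tg <- trans_pairs$mrna_id[trans_pairs$lncrna_id == lid]
      if (length(tg) == 0L) next
      x <- log2(counts[lid, ] / lib_factor + 0.5)  # module latent profile
      sx <- stats::sd(x)
      loading <- if (rho > 0 && sx > 1e-6)
        sqrt(rho^2 / (1 - rho^2) * v_target_noise) / sx else 0
      shift <- loading * (x - mean(x))
      mu_t <- sweep(2^(log2mu[tg, , drop = FALSE] +
                         matrix(rep(shift, each = length(tg)),
                                nrow = length(tg))),
                    2L, lib_factor, "*")
      counts[tg, ] <- draw_counts(mu_t)
    }
  }
  storage.mode(counts) <- "integer"

  lengths <- setNames(tr$spliced_length, tr$transcript_id)
  names(lengths) <- tr$gene_id[match(names(lengths), tr$transcript_id)]

  truth <- list(
    planted_class = data.frame(gene_id = lnc$gene_id,
                               transcript_id = lnc$transcript_id,
                               label = lnc$label, stringsAsFactors = FALSE),
    positional_class = data.frame(transcript_id = lnc$transcript_id,
                                  class = lnc$class,
                                  stringsAsFactors = FALSE),
    cis_pairs = brute_force_cis(annotation$transcripts[
      annotation$transcripts$gene_id %in% lnc$gene_id, , drop = FALSE],
      reference$transcripts, window_bp),
    trans_pairs = trans_pairs)

  structure(list(config = config, chrom_lengths = chrom_lengths,
                 annotation = annotation, reference = reference,
                 sequences = sequences, lengths = lengths, counts = counts,
                 samples = samples, feature_kind = feature_kind,
                 base_mean_log10 = base_log10, lib_factors = lib_factor,
                 truth = truth),
            class = "lnc_study")
}

#' Write a simulated study to disk in the pipeline's input dialects
#'
#' Emits `assembled.gtf`, `reference.gtf`, `transcripts.fa`, `counts.tsv`,
#' `samples.tsv` and the ground-truth tables as TSV; running twice with the
#' same config yields byte-identical files.
#'
#' @param study a [simulate_study()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "lnc_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_gtf(study$annotation, file.path(dir, "assembled.gtf"))
  write_gtf(study$reference, file.path(dir, "reference.gtf"))
  write_fasta(study$sequences, file.path(dir, "transcripts.fa"))
  write_counts(study$counts, file.path(dir, "counts.tsv"))
  write.table(study$samples, file.path(dir, "samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(study$truth$planted_class,
              file.path(dir, "truth_planted_class.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(study$truth$cis_pairs, file.path(dir, "truth_cis_pairs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(study$truth$trans_pairs,
              file.path(dir, "truth_trans_pairs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Emit a gene-set fixture with one term enriched by construction
#'
#' The first term collects the planted regulators' trans-target genes
#' (enriched among planted targets by construction); the remaining terms are
#' random draws from the universe.  Uses the current RNG state; seed before
#' calling for reproducibility.
#'
#' @param truth `truth` element of a [simulate_study()] result.
#' @param universe character vector of background gene ids.
#' @param n_random_terms number of random terms, default 5.
#' @param random_term_size genes per random term (drawn without
#'   replacement), default 25.
#' @return data.frame with columns `term_id`, `term_name`, `gene_id`.
#' @export
emit_gene_sets <- function(truth, universe, n_random_terms = 5L,
                           random_term_size = 25L) {
  enr <- unique(truth$trans_pairs$mrna_id)
  enr <- intersect(enr, universe)
  rows <- list()
  if (length(enr) > 0L)
    rows[[1]] <- data.frame(term_id = "SET0000",
                            term_name = "planted_target_module",
                            gene_id = enr, stringsAsFactors = FALSE)
  for (j in seq_len(n_random_terms)) {
    size <- min(random_term_size, length(universe))
    rows[[length(rows) + 1L]] <- data.frame(
      term_id = sprintf("SET%04d", j),
      term_name = sprintf("random_set_%d", j),
      gene_id = sample(universe, size),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
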