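# Fixture builders and independent brute-force oracles shared across tests.
# Oracles deliberately use plain loops over data frames, never the package's
# GRanges machinery.

exon_row <- function(chrom, start, end, strand, gene, tx) {
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             gene_id = gene, transcript_id = tx, stringsAsFactors = FALSE)
}

# a single multi-exon transcript
toy_tx <- function(chrom, strand, exon_starts, exon_ends, tx,
                   gene = sub("\\.\\d+$", "", tx)) {
  exon_row(chrom, exon_starts, exon_ends, strand, gene, tx)
}

# random annotation pair (reference + queries) for oracle-equivalence tests;
# geometry is unconstrained so every classification rule gets exercised
random_annotation_pair <- function(n_ref, n_query, chrom_len = 200000L) {
  rand_tx <- function(id_prefix, i) {
    chrom <- sample(c("chrA", "chrB"), 1)
    strand <- sample(c("+", "-"), 1)
    s1 <- sample.int(chrom_len - 6000L, 1)
    w1 <- sample(100:800, 1)
    gap <- sample(50:2000, 1)
    w2 <- sample(100:800, 1)
    toy_tx(chrom, strand, c(s1, s1 + w1 + gap),
           c(s1 + w1 - 1L, s1 + w1 + gap + w2 - 1L),
           sprintf("%s%04d.1", id_prefix, i))
  }
  ref <- annotation_set(do.call(rbind, lapply(seq_len(n_ref), function(i)
    rand_tx("REF", i))))
  qry <- annotation_set(do.call(rbind, lapply(seq_len(n_query), function(i)
    rand_tx("QRY", i))))
  list(ref = ref, query = qry)
}

# brute-force positional classification (all-pairs interval scan)
oracle_classify <- function(query, ref) {
  q_tr <- query$transcripts; r_tr <- ref$transcripts
  q_ex <- query$exons; r_ex <- ref$exons
  overlaps <- function(s1, e1, s2, e2) s1 <= e2 & s2 <= e1
  cls <- character(nrow(q_tr))
  for (i in seq_len(nrow(q_tr))) {
    qt <- q_tr[i, ]
    qe <- q_ex[q_ex$transcript_id == qt$transcript_id, ]
    sense <- FALSE; intronic <- FALSE; anti <- FALSE
    for (j in seq_len(nrow(r_tr))) {
      rt <- r_tr[j, ]
      if (rt$chrom != qt$chrom) next
      re <- r_ex[r_ex$transcript_id == rt$transcript_id, ]
      if (rt$strand == qt$strand) {
        for (a in seq_len(nrow(qe)))
          for (b in seq_len(nrow(re)))
            if (overlaps(qe$start[a], qe$end[a], re$start[b], re$end[b]))
              sense <- TRUE
        if (nrow(re) > 1)
          for (b in seq_len(nrow(re) - 1)) {
            istart <- re$end[b] + 1; iend <- re$start[b + 1] - 1
            if (qt$start >= istart && qt$end <= iend) intronic <- TRUE
          }
      } else {
        if (overlaps(qt$start, qt$end, rt$start, rt$end)) anti <- TRUE
      }
    }
    cls[i] <- if (sense) "sense" else if (intronic) "intronic" else
      if (anti) "antisense" else "lincRNA"
  }
  data.frame(transcript_id = q_tr$transcript_id, class = cls,
             stringsAsFactors = FALSE)
}

# brute-force ORF scan: every ATG, walk codon-by-codon to the first stop
oracle_longest_orf <- function(seq) {
  s <- toupper(seq)
  n <- nchar(s)
  best <- 0L
  if (n < 6L) return(best)
  for (i in seq_len(n - 2L)) {
    if (substring(s, i, i + 2L) != "ATG") next
    j <- i + 3L
    while (j + 2L <= n) {
      cod <- substring(s, j, j + 2L)
      if (cod %in% c("TAA", "TAG", "TGA")) {
        best <- max(best, j + 2L - i + 1L)
        break
      }
      j <- j + 3L
    }
  }
  best
}

# brute-force all-pairs cis distance scan over gene spans
oracle_cis <- function(lnc, ref, window_bp = 100000L) {
  span <- function(ann) {
    tr <- ann$transcripts
    do.call(rbind, lapply(split(tr, tr$gene_id), function(g)
      data.frame(gene_id = g$gene_id[1], chrom = g$chrom[1],
                 start = min(g$start), end = max(g$end),
                 stringsAsFactors = FALSE)))
  }
  ls <- span(lnc); rs <- span(ref)
  rows <- list()
  for (i in seq_len(nrow(ls))) for (j in seq_len(nrow(rs))) {
    if (ls$chrom[i] != rs$chrom[j]) next
    gap <- if (rs$start[j] > ls$end[i]) rs$start[j] - ls$end[i] - 1L
    else if (ls$start[i] > rs$end[j]) ls$start[i] - rs$end[j] - 1L
    else 0L
    if (gap <= window_bp)
      rows[[length(rows) + 1L]] <- data.frame(
        lncrna_id = ls$gene_id[i], mrna_id = rs$gene_id[j],
        distance_bp = gap, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(lncrna_id = character(), mrna_id = character(),
                      distance_bp = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$lncrna_id, out$mrna_id), , drop = FALSE]
}

# hypergeometric upper tail by exhaustive enumeration of the pmf
oracle_hyper <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# NB count matrix with no condition effect (shared null fixture)
null_count_matrix <- function(n_features, n_per_group = 3, alpha = 0.05,
                              mean_log10_range = c(1, 3),
                              lib_range = c(0.7, 1.4)) {
  mu <- 10^runif(n_features, mean_log10_range[1], mean_log10_range[2])
  sf <- exp(runif(2 * n_per_group, log(lib_range[1]), log(lib_range[2])))
  cnt <- sapply(seq_along(sf), function(j)
    rnbinom(n_features, mu = mu * sf[j], size = 1 / alpha))
  samp <- sample_sheet(conditions = rep(c("SD1", "SD2"), each = n_per_group),
                       replicates = rep(seq_len(n_per_group), 2))
  rownames(cnt) <- sprintf("g%05d", seq_len(n_features))
  colnames(cnt) <- samp$sample_id
  list(counts = cnt, samples = samp, mu = mu)
}

# two profiles with an exactly prescribed Pearson correlation
profiles_with_r <- function(r, n = 9) {
  x <- seq_len(n)
  z <- rnorm(n)
  xs <- scale(x)[, 1]
  zs <- z - mean(z)
  zs <- zs - sum(zs * xs) / sum(xs^2) * xs   # orthogonal to x
  zs <- zs / sqrt(sum(zs^2) / (n - 1))
  y <- r * xs + sqrt(1 - r^2) * zs
  list(x = x, y = y)
}
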