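make_verdicts <- function(ids, call = "noncoding") {
  data.frame(transcript_id = ids, orf_length_nt = 0L,
             in_house_call = call, consensus = call, stringsAsFactors = FALSE)
}

test_that("lncRNA candidate filter applies strict length, exon and coding rules", {
  ex <- rbind(
    toy_tx("chr1", "+", 1000, 1499, "ONEEX.1"),                 # 1 exon, 500 bp
    toy_tx("chr1", "+", c(3000, 3150), c(3099, 3249), "LEN200.1"),  # 200 bp
    toy_tx("chr1", "+", c(5000, 5150), c(5099, 5250), "LEN201.1"),  # 201 bp
    toy_tx("chr1", "+", c(7000, 7500), c(7299, 7799), "CODING.1"),
    toy_tx("chr1", "+", c(9000, 9500), c(9299, 9799), "REFTX.1"))
  ann <- annotation_set(ex)
  v <- make_verdicts(ann$transcripts$transcript_id)
  v$consensus[v$transcript_id == "CODING.1"] <- "coding"

  kept <- filter_lncrna_candidates(ann, v, reference_ids = "REFTX.1")
  expect_setequal(kept$transcript_id, "LEN201.1")

  # verdict coverage is mandatory for every non-reference transcript
  expect_error(
    filter_lncrna_candidates(ann, v[v$transcript_id != "ONEEX.1", ],
                             reference_ids = "REFTX.1"),
    "no coding-potential verdict")
})

test_that("positional classification follows the sense > intronic > antisense > lincRNA cascade", {
  # reference gene: chr1 +, exons 10000-10999 and 13000-13999 (intron between)
  ref <- annotation_set(toy_tx("chr1", "+", c(10000, 13000),
                               c(10999, 13999), "REF1.1"))
  qry <- annotation_set(rbind(
    toy_tx("chr1", "+", c(10500, 11500), c(11099, 11799), "SENSE.1"),
    toy_tx("chr1", "+", c(11200, 12000), c(11399, 12299), "INTRONIC.1"),
    toy_tx("chr1", "-", c(13500, 14500), c(13799, 14799), "ANTI.1"),
    toy_tx("chr1", "-", c(11200, 12000), c(11399, 12299), "ANTI_INTRON.1"),
    toy_tx("chr1", "+", c(50000, 50500), c(50299, 50799), "LINC.1"),
    toy_tx("chr2", "+", c(10500, 11500), c(10799, 11799), "OTHERCHR.1")))
  cls <- classify_position(qry, ref)
  got <- setNames(cls$class, cls$transcript_id)
  expect_equal(got[["SENSE.1"]], "sense")
  expect_equal(got[["INTRONIC.1"]], "intronic")
  expect_equal(got[["ANTI.1"]], "antisense")
  # opposite-strand containment inside an intron is antisense (strand-defined)
  expect_equal(got[["ANTI_INTRON.1"]], "antisense")
  expect_equal(got[["LINC.1"]], "lincRNA")
  expect_equal(got[["OTHERCHR.1"]], "lincRNA")
})

test_that("classification is a partition and matches the brute-force scan", {
  set.seed(21)
  for (rep in 1:3) {
    pair <- random_annotation_pair(n_ref = 25, n_query = 60)
    got <- classify_position(pair$query, pair$ref)
    expect_equal(nrow(got), nrow(pair$query$transcripts))
    expect_true(all(got$class %in%
                      c("lincRNA", "intronic", "sense", "antisense")))
    want <- oracle_classify(pair$query, pair$ref)
    expect_equal(got[order(got$transcript_id), ],
                 want[order(want$transcript_id), ],
                 ignore_attr = TRUE)
  }
})

test_that("classification recovers the simulator's planted positional classes", {
  st <- simulate_study(simulation_config(seed = 7))
  lnc_ann <- subset_annotation(st$annotation,
                               st$truth$positional_class$transcript_id)
  cls <- classify_position(lnc_ann, st$reference)
  truth <- st$truth$positional_class
  got <- cls$class[match(truth$transcript_id, cls$transcript_id)]
  expect_equal(got, truth$class)
})

test_that("class census reports counts and per-Mb density", {
  cls <- data.frame(transcript_id = paste0("L", 1:7),
                    class = c(rep("lincRNA", 4), "sense", "intronic",
                              "antisense"), stringsAsFactors = FALSE)
  ex <- do.call(rbind, lapply(1:7, function(i)
    toy_tx("chr1", "+", c(i * 1000, i * 1000 + 500),
           c(i * 1000 + 99, i * 1000 + 699), sprintf("L%d.1", i),
           gene = sprintf("L%d", i))))
  ex$transcript_id <- sub("\\.1$", "", ex$transcript_id)  # ids L1..L7
  ann <- annotation_set(ex)
  cen <- class_census(cls, ann, c(chr1 = 2e6))
  expect_equal(sum(cen$class_counts), 7L)
  expect_equal(cen$overall_density_per_mb, 3.5)
  expect_equal(cen$chrom_density$density_per_mb, 3.5)
  expect_error(class_census(cls, ann, c(chrX = 1e6)), "chromosome length")

  empty <- class_census(cls[0, ], ann, c(chr1 = 2e6))
  expect_true(all(empty$class_counts == 0L))
})
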