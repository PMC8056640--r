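test_that("cis window is inclusive at 100 kb and distance-0 on overlap", {
  ref <- annotation_set(rbind(
    toy_tx("chr1", "+", c(200000, 202000), c(200999, 202999), "NEAR.1"),
    toy_tx("chr1", "+", c(400000, 402000), c(400999, 402999), "FARGENE.1"),
    toy_tx("chr1", "-", c(100000, 102000), c(100999, 102999), "HOST.1"),
    toy_tx("chr2", "+", c(150000, 152000), c(150999, 152999), "OTHER.1")))
  lnc <- annotation_set(rbind(
    toy_tx("chr1", "+", c(149700, 149900), c(149799, 149999), "L1.1"),
    toy_tx("chr1", "+", c(101500, 101800), c(101599, 101899), "L2.1")))
  # L1 span 149700-149999: gap to NEAR (200000-202999) = 50000;
  # to FARGENE = 250000 (out); to HOST (ends 102999) = 46700
  res <- cis_targets(lnc, ref)
  expect_setequal(res$mrna_id[res$lncrna_id == "L1"], c("NEAR", "HOST"))
  expect_equal(res$distance_bp[res$lncrna_id == "L1" &
                                 res$mrna_id == "NEAR"], 50000L)
  # L2 overlaps HOST's span: distance 0 (strand-agnostic)
  expect_equal(res$distance_bp[res$lncrna_id == "L2" &
                                 res$mrna_id == "HOST"], 0L)

  # boundary: gap of exactly window_bp is included, window_bp + 1 is not
  ref2 <- annotation_set(toy_tx("chr1", "+", c(300000, 302000),
                                c(300999, 302999), "G.1"))
  lnc_at <- annotation_set(toy_tx("chr1", "+", c(199699, 199899),
                                  c(199799, 199999), "LA.1"))
  expect_equal(nrow(cis_targets(lnc_at, ref2)), 1L)       # gap = 100000
  lnc_out <- annotation_set(toy_tx("chr1", "+", c(199698, 199898),
                                   c(199798, 199998), "LB.1"))
  expect_equal(nrow(cis_targets(lnc_out, ref2)), 0L)      # gap = 100001
})

test_that("cis targets equal the brute-force all-pairs distance scan", {
  set.seed(51)
  for (rep in 1:3) {
    pair <- random_annotation_pair(n_ref = 30, n_query = 30)
    got <- cis_targets(pair$query, pair$ref, window_bp = 20000L)
    want <- oracle_cis(pair$query, pair$ref, window_bp = 20000L)
    expect_equal(got[, c("lncrna_id", "mrna_id", "distance_bp")], want,
                 ignore_attr = TRUE)
  }
})

test_that("Pearson test matches cor.test and is invariant to joint permutation", {
  x <- c(1, 3, 2, 5, 4, 7, 6, 9, 8)
  y <- 2 * x + 1
  r <- pearson_test(x, y)
  expect_equal(r$pcc, 1)
  expect_equal(r$p_value, 0)

  set.seed(52)
  pr <- profiles_with_r(0.9, n = 9)
  got <- pearson_test(pr$x, pr$y)
  expect_equal(got$pcc, 0.9, tolerance = 1e-10)
  ct <- cor.test(pr$x, pr$y)
  expect_equal(got$p_value, ct$p.value, tolerance = 1e-6)

  perm <- sample(9)
  z <- rnorm(9)
  expect_equal(pearson_test(pr$x[perm], z[perm]),
               pearson_test(pr$x, z))

  expect_error(pearson_test(rep(1, 9), z), "constant")
  expect_error(pearson_test(1:4, 1:5), "equal length")
})

test_that("trans pairs require both strict cutoffs", {
  set.seed(53)
  pr <- profiles_with_r(0.9, n = 9)   # |r| exactly at the cutoff: excluded
  le <- matrix(pr$x, nrow = 1, dimnames = list("L1", paste0("s", 1:9)))
  me <- matrix(pr$y, nrow = 1, dimnames = list("M1", paste0("s", 1:9)))
  expect_equal(nrow(trans_targets(le, me, log_transform = FALSE)), 0L)
  expect_equal(nrow(trans_targets(le, me, pcc_cutoff = 0.89,
                                  log_transform = FALSE)), 1L)

  pr2 <- profiles_with_r(-0.95, n = 9)
  me2 <- matrix(pr2$y, nrow = 1, dimnames = list("M2", paste0("s", 1:9)))
  le2 <- matrix(pr2$x, nrow = 1, dimnames = list("L1", paste0("s", 1:9)))
  res <- trans_targets(le2, me2, log_transform = FALSE)
  expect_equal(nrow(res), 1L)            # anti-correlation passes |PCC|
  expect_lt(res$pcc, -0.9)
  expect_lt(res$p_value, 0.01)

  colnames(me2) <- paste0("t", 1:9)
  expect_error(trans_targets(le2, me2), "share identical sample columns")
})

test_that("planted trans modules are recovered and null pairs rarely pass", {
  st <- simulate_study(simulation_config(seed = 54))
  fpkm <- compute_fpkm(st$counts, st$lengths)
  lnc_ids <- unique(st$truth$trans_pairs$lncrna_id)
  mrna_ids <- rownames(fpkm)[st$feature_kind[rownames(fpkm)] == "mRNA"]
  res <- trans_targets(fpkm[lnc_ids, , drop = FALSE],
                       fpkm[mrna_ids, , drop = FALSE])
  key <- function(d) paste(d$lncrna_id, d$mrna_id)
  recall <- mean(key(st$truth$trans_pairs) %in% key(res))
  expect_gte(recall, 0.9)
  # every emitted pair satisfies the TargetPair invariants
  expect_true(all(abs(res$pcc) > 0.9 & res$p_value < 0.01))

  # null profiles pass at well under the 1% p cutoff
  set.seed(55)
  le <- matrix(rnorm(50 * 9), nrow = 50,
               dimnames = list(paste0("L", 1:50), paste0("s", 1:9)))
  me <- matrix(rnorm(40 * 9), nrow = 40,
               dimnames = list(paste0("M", 1:40), paste0("s", 1:9)))
  null_hits <- nrow(trans_targets(le, me, log_transform = FALSE))
  n_pairs <- 50 * 40
  expect_lte(null_hits / n_pairs, 0.01 + 3 * sqrt(0.01 * 0.99 / n_pairs))
})
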