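test_that("size factors are median-of-ratios with geometric-mean-1 scaling", {
  a <- c(10L, 20L, 40L, 80L, 160L)
  m1 <- cbind(s1 = a, s2 = a)
  rownames(m1) <- paste0("g", 1:5)
  expect_equal(size_factors(m1), c(s1 = 1, s2 = 1))

  m2 <- cbind(s1 = a, s2 = 2L * a)
  rownames(m2) <- paste0("g", 1:5)
  sf <- size_factors(m2)
  expect_equal(unname(sf["s2"] / sf["s1"]), 2)
  expect_equal(exp(mean(log(sf))), 1)

  # hand-computed oracle on a 5-gene worked matrix
  m3 <- cbind(s1 = c(2L, 4L, 6L, 100L, 1L),
              s2 = c(4L, 8L, 18L, 100L, 2L),
              s3 = c(8L, 16L, 6L, 100L, 4L))
  rownames(m3) <- paste0("g", 1:5)
  gm <- apply(m3, 1, function(x) prod(x)^(1/3))
  raw <- apply(m3 / gm, 2, median)
  expect_equal(size_factors(m3), raw / exp(mean(log(raw))))

  m4 <- cbind(s1 = c(0L, 5L), s2 = c(5L, 0L))
  rownames(m4) <- c("g1", "g2")
  expect_error(size_factors(m4), "pseudo-reference")
})

test_that("BH step-up matches the definition and the reference implementation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.42), 0.42)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(41)
  for (i in 1:200) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    q <- bh_adjust(p)
    expect_equal(q, p.adjust(p, method = "BH"))
    expect_true(all(q <= 1))
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone on sorted input
  }
})

test_that("NB Wald test handles flat features and orients the fold change", {
  samples <- sample_sheet()
  cnt <- matrix(50L, nrow = 3, ncol = 9,
                dimnames = list(c("flat", "up2", "zero"), samples$sample_id))
  cnt["up2", samples$condition == "SD2"] <- 400L
  cnt["zero", ] <- 0L
  # a stable background block keeps size factors at the library scale
  bg <- matrix(100L, nrow = 50, ncol = 9,
               dimnames = list(sprintf("bg%02d", 1:50), samples$sample_id))
  res <- nb_wald_test(rbind(cnt, bg), samples, "SD1_vs_SD2")

  # all-zero features are excluded from testing and the BH family
  expect_false("zero" %in% res$feature_id)

  flat <- res[res$feature_id == "flat", ]
  expect_equal(flat$log2fc, 0)
  expect_equal(flat$p_value, 1)
  expect_equal(flat$direction, "ns")

  # second-named condition over first: higher in SD2 means positive log2fc
  expect_gt(res$log2fc[res$feature_id == "up2"], 1)
  expect_equal(res$direction[res$feature_id == "up2"], "up")

  expect_error(nb_wald_test(cnt, samples, "SD1_vs_LD"), "comparison")
})

test_that("null simulation keeps the raw type-I error near nominal", {
  set.seed(42)
  nm <- null_count_matrix(2000)
  res <- nb_wald_test(nm$counts, nm$samples, "SD1_vs_SD2")
  frac <- mean(res$p_value < 0.05)
  se3 <- 3 * sqrt(0.05 * 0.95 / nrow(res))
  expect_lt(abs(frac - 0.05), se3)
})

test_that("planted effects are detected and estimated without bias", {
  set.seed(43)
  n <- 200
  samples <- sample_sheet(conditions = rep(c("SD1", "SD2"), each = 3),
                          replicates = rep(1:3, 2))
  mu <- rep(200, n)
  cnt <- sapply(seq_len(6), function(j) {
    fold <- if (samples$condition[j] == "SD2") 8 else 1
    rnbinom(n, mu = mu * fold, size = 1 / 0.05)
  })
  rownames(cnt) <- sprintf("g%03d", seq_len(n))
  colnames(cnt) <- samples$sample_id
  # size factors would absorb a genome-wide fold change, so add a large
  # stable background block
  bg <- matrix(rep(10^runif(2000, 1, 3), 6), ncol = 6)
  bg <- matrix(rnbinom(length(bg), mu = bg, size = 1 / 0.05), ncol = 6,
               dimnames = list(sprintf("b%04d", 1:2000), samples$sample_id))
  res <- nb_wald_test(rbind(cnt, bg), samples, "SD1_vs_SD2")
  planted <- res[grepl("^g", res$feature_id), ]
  expect_gte(mean(planted$direction == "up" & planted$fdr < 0.05), 0.95)
  # mean estimated log2FC over planted features within +/- 0.3 of truth
  expect_lt(abs(mean(planted$log2fc) - 3), 0.3)
})

test_that("DE summary counts satisfy total = up + down per comparison and kind", {
  r1 <- data.frame(feature_id = c("a", "b", "c", "d"),
                   comparison = "SD1_vs_SD2", base_mean = 1, log2fc = 0,
                   p_value = 1, fdr = 1,
                   direction = c("up", "down", "down", "ns"),
                   stringsAsFactors = FALSE)
  kind <- c(a = "lncRNA", b = "lncRNA", c = "mRNA", d = "mRNA")
  s <- de_summary(list(r1), kind_of = kind)
  expect_equal(s$total, s$up + s$down)
  expect_equal(s$total[s$kind == "lncRNA"], 2L)
  expect_equal(s$total[s$kind == "mRNA"], 1L)

  r0 <- r1; r0$direction <- "ns"
  s0 <- de_summary(list(r0))
  expect_true(all(s0[, c("total", "up", "down")] == 0L))
})
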