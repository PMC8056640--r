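test_that("identical config and seed give byte-identical study files", {
  cfg <- simulation_config(seed = 71)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_study(simulate_study(cfg), d1)
  write_study(simulate_study(cfg), d2)
  files <- list.files(d1)
  expect_true(length(files) >= 5)
  for (f in files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("planted regulators show the antagonistic sign pattern in raw condition means", {
  cfg <- simulation_config(seed = 72, n_planted_positive = 5,
                           n_planted_negative = 5, effect_log2fc = 3,
                           nb_dispersion = 0.05)
  st <- simulate_study(cfg)
  cond_mean <- function(g, cc)
    mean(st$counts[g, st$samples$sample_id[st$samples$condition == cc]] /
           st$lib_factors[st$samples$condition == cc])
  for (g in st$truth$planted_class$gene_id[
    st$truth$planted_class$label == "positive"]) {
    expect_gt(cond_mean(g, "SD2"), cond_mean(g, "SD1"))
    expect_gt(cond_mean(g, "SD2"), cond_mean(g, "NB"))
  }
  for (g in st$truth$planted_class$gene_id[
    st$truth$planted_class$label == "negative"]) {
    expect_lt(cond_mean(g, "SD2"), cond_mean(g, "SD1"))
    expect_lt(cond_mean(g, "SD2"), cond_mean(g, "NB"))
  }
})

test_that("background counts match the configured NB means (pooled z within 3 SE)", {
  st <- simulate_study(simulation_config(seed = 73))
  alpha <- st$config$nb_dispersion
  planted <- unique(c(st$truth$trans_pairs$mrna_id,
                      st$truth$trans_pairs$lncrna_id,
                      st$truth$planted_class$gene_id[
                        st$truth$planted_class$label != "none"]))
  bg <- setdiff(rownames(st$counts), planted)
  mu <- outer(10^st$base_mean_log10[bg], st$lib_factors)
  z <- (sum(st$counts[bg, ]) - sum(mu)) / sqrt(sum(mu + alpha * mu^2))
  expect_lt(abs(z), 3)
})

test_that("planted trans pairs reach the target correlation on log FPKM", {
  st <- simulate_study(simulation_config(seed = 74))
  tp <- st$truth$trans_pairs
  expect_gte(nrow(tp), 50)
  fpkm <- log10(compute_fpkm(st$counts, st$lengths) + 0.01)
  r <- vapply(seq_len(nrow(tp)), function(i)
    cor(fpkm[tp$lncrna_id[i], ], fpkm[tp$mrna_id[i], ]), numeric(1))
  expect_gte(mean(abs(r) > 0.9), 0.9)
})

test_that("a zero-effect config plants nothing detectable", {
  cfg <- simulation_config(seed = 75, effect_log2fc = 0,
                           trans_target_corr = 0)
  st <- simulate_study(cfg)
  de1 <- nb_wald_test(st$counts, st$samples, "SD1_vs_SD2")
  de2 <- nb_wald_test(st$counts, st$samples, "SD2_vs_NB")
  lnc <- st$truth$planted_class$gene_id
  calls <- call_flowering(de1[de1$feature_id %in% lnc, ],
                          de2[de2$feature_id %in% lnc, ])
  # positive/negative calls stay at the chance level of a double BH pass
  expect_lte(sum(calls$label != "none"), 2L)
})

test_that("impossible configurations are rejected", {
  expect_error(simulation_config(n_planted_positive = 20,
                                 n_planted_negative = 20),
               "exceed the lincRNA pool")
  expect_error(
    simulate_study(simulation_config(n_coding_genes = 20,
                                     n_lncrnas_per_class = c(lincRNA = 25,
                                                             intronic = 10,
                                                             sense = 10,
                                                             antisense = 10))),
    "more cis/host placements")
})

test_that("simulated sequences separate coding from noncoding by ORF length", {
  st <- simulate_study(simulation_config(seed = 76))
  v <- score_coding_potential(st$sequences)
  coding_tx <- st$reference$transcripts$transcript_id
  lnc_tx <- st$truth$positional_class$transcript_id
  expect_true(all(v$in_house_call[v$transcript_id %in% coding_tx] ==
                    "coding"))
  expect_true(all(v$in_house_call[v$transcript_id %in% lnc_tx] ==
                    "noncoding"))
})
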