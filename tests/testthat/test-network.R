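toy_calls <- data.frame(
  lncrna_id = c("L1", "L2", "L3", "L4"),
  dir_sd = c("up", "up", "down", "ns"),
  dir_nb = c("down", "down", "up", "ns"),
  label = c("positive", "positive", "negative", "none"),
  stringsAsFactors = FALSE)

toy_pairs <- data.frame(
  lncrna_id = c("L1", "L1", "L1", "L2", "L3", "L3", "L4"),
  mrna_id   = c("M1", "M2", "M3", "M1", "M1", "M4", "M5"),
  mode      = c("trans", "trans", "cis", "trans", "trans", "cis", "trans"),
  distance_bp = c(NA, NA, 1000L, NA, NA, 0L, NA),
  pcc = c(0.99, 0.95, NA, 0.93, -0.97, NA, 0.91),
  p_value = c(1e-6, 1e-4, NA, 1e-4, 1e-5, NA, 1e-3),
  stringsAsFactors = FALSE)

test_that("network induction keeps labelled lncRNAs and tags edge modes", {
  net <- build_network(toy_calls, toy_pairs, "positive")
  expect_equal(nrow(net$edges), 4L)               # L1 x3 + L2 x1
  expect_setequal(net$lncrna_nodes, c("L1", "L2"))
  expect_equal(unname(net$degree["M1"]), 2L)      # shared target
  # degree sums: both sides equal the edge count
  expect_equal(sum(net$degree[net$lncrna_nodes]), nrow(net$edges))
  expect_equal(sum(net$degree[net$mrna_nodes]), nrow(net$edges))

  # duplicated (lncRNA, mRNA, mode) rows collapse
  net_dup <- build_network(toy_calls, rbind(toy_pairs, toy_pairs), "positive")
  expect_equal(net_dup$edges, net$edges)

  # no lncRNA with the label: empty network, not an error
  none_calls <- toy_calls; none_calls$label <- "none"
  expect_equal(nrow(build_network(none_calls, toy_pairs, "positive")$edges),
               0L)
})

test_that("degrees agree with an independent graph library", {
  skip_if_not_installed("igraph")
  net <- build_network(toy_calls, toy_pairs, "positive")
  g <- igraph::graph_from_data_frame(net$edges[, c("lncrna_id", "mrna_id")],
                                     directed = FALSE)
  ideg <- igraph::degree(g)
  expect_equal(net$degree[names(ideg)], ideg)
})

test_that("common-target shares follow the percentage definition", {
  pos <- build_network(toy_calls, toy_pairs, "positive")
  neg <- build_network(toy_calls, toy_pairs, "negative")
  ct <- common_targets(pos, neg)
  # pos targets {M1,M2,M3}, neg targets {M1,M4}; common {M1}
  expect_equal(ct$common, "M1")
  expect_equal(ct$share_of_pos_pct, round(100 / 3, 2))
  expect_equal(ct$share_of_neg_pct, 50)
  expect_true(all(ct$common %in% pos$mrna_nodes) &&
                all(ct$common %in% neg$mrna_nodes))
  # symmetric in the set output
  expect_equal(common_targets(neg, pos)$common, ct$common)
  # trans-only pooling drops cis-only targets
  expect_equal(common_targets(pos, neg, mode = "trans")$common, "M1")
})

test_that("hub report ranks by degree with lexicographic ties", {
  star_pairs <- data.frame(
    lncrna_id = "L1", mrna_id = paste0("M", 1:5), mode = "trans",
    distance_bp = NA_integer_, pcc = 0.95, p_value = 1e-4,
    stringsAsFactors = FALSE)
  star <- build_network(toy_calls, star_pairs, "positive")
  top <- hub_report(star, k = 3)
  expect_equal(top$node[top$side == "lncRNA"], "L1")
  expect_equal(top$degree[top$side == "lncRNA"], 5L)
  # all target degrees equal: lexicographic order, length min(k, n)
  expect_equal(top$node[top$side == "mRNA"], c("M1", "M2", "M3"))
  expect_error(hub_report(star, k = 0), "k must be > 0")
})
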