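test_that("generators are deterministic in their seed", {
  g1 <- generate_network(50, 30, 10, 5, 0.1, families = 4, seed = 7)
  g2 <- generate_network(50, 30, 10, 5, 0.1, families = 4, seed = 7)
  expect_identical(g1, g2)
  g3 <- generate_network(50, 30, 10, 5, 0.1, families = 4, seed = 8)
  expect_false(identical(g1$network$edges, g3$network$edges))

  e1 <- generate_expression(g1$network, g1$truth, seed = 7)
  e2 <- generate_expression(g1$network, g1$truth, seed = 7)
  expect_identical(e1$values, e2$values)

  p1 <- generate_ortholog_pair(g1$network, seed = 7)
  p2 <- generate_ortholog_pair(g1$network, seed = 7)
  expect_identical(p1$omap$pairs, p2$omap$pairs)
  expect_identical(p1$net_b$edges, p2$net_b$edges)

  d1 <- generate_deg_table(g1$network, seed = 7)
  d2 <- generate_deg_table(g1$network, seed = 7)
  expect_identical(d1, d2)
})

test_that("hub mixing inflates outdegree variance", {
  hubbed <- generate_network(100, 60, 0, 4, hub_fraction = 0.15, seed = 13)
  flat <- generate_network(100, 60, 0, 4, hub_fraction = 0, seed = 13)
  var_h <- stats::var(degree_table(hubbed$network)$outdegree[
    pdinet:::role_is_tf(hubbed$network$nodes$role)])
  var_f <- stats::var(degree_table(flat$network)$outdegree[
    pdinet:::role_is_tf(flat$network$nodes$role)])
  expect_gt(var_h, var_f)
})

test_that("structural impossibilities are rejected or vacuous", {
  expect_error(generate_network(mean_outdegree = 1000, n_promoters = 10,
                                n_dual_nodes = 0),
               class = "pdinet_domain_error")
  expect_error(generate_network(n_dual_nodes = 200, n_tfs = 100),
               class = "pdinet_domain_error")
  # without dual nodes there are no TF -> TF edges, hence no loops
  gen <- generate_network(n_tfs = 40, n_promoters = 30, n_dual_nodes = 0,
                          seed = 3)
  expect_equal(nrow(enumerate_ffls(gen$network)), 0)
  expect_equal(nrow(gen$truth$planted_ffls), 0)
})

test_that("generated artifacts satisfy the consuming modules' invariants", {
  gen <- generate_network(seed = 19)
  expect_silent(validate_grn(gen$network))
  expect_equal(nrow(gen$truth$edge_signs), nrow(gen$network$edges))
  expect_true(all(gen$truth$edge_signs$sign %in% c("+", "-")))

  expr <- generate_expression(gen$network, gen$truth, seed = 19)
  expect_true(all(expr$values >= 0))          # TPM-like
  expect_s3_class(expr, "expr_set")
  expect_equal(nrow(expr$values), nrow(gen$network$nodes))
  # replicate structure: 2 tissues x 6 times x 3 replicates
  expect_equal(ncol(expr$values), 36)

  degs <- generate_deg_table(gen$network, seed = 19)
  expect_equal(deg_status(degs$log2fc, degs$padj), degs$status)
})

test_that("planted DEG rates are recovered through the overlay", {
  gen <- generate_network(n_tfs = 600, n_promoters = 400, n_dual_nodes = 0,
                          mean_outdegree = 2, seed = 23)
  n_nodes <- nrow(gen$network$nodes)
  expect_gte(n_nodes, 900)
  degs <- generate_deg_table(gen$network, tissues = "leaf", time_points = 3,
                             frac_up = 0.2, frac_down = 0.1, seed = 23)
  ov <- overlay_degs(gen$network, degs, tissue = "leaf", time_h = 3)
  n_up <- sum(ov$status == "up")
  # binomial tolerance: 4 sd around the planted rate
  expect_lt(abs(n_up - 0.2 * n_nodes), 4 * sqrt(n_nodes * 0.2 * 0.8))
  expect_lt(abs(sum(ov$status == "down") - 0.1 * n_nodes),
            4 * sqrt(n_nodes * 0.1 * 0.9))

  d0 <- generate_deg_table(gen$network, frac_up = 0, frac_down = 0, seed = 5)
  expect_true(all(d0$status == "not_de"))
  expect_error(generate_deg_table(gen$network, frac_up = 0.7, frac_down = 0.7),
               class = "pdinet_domain_error")
})

test_that("noiseless single-regulator expression recovers every polarity", {
  bench <- polarity_benchmark(seed = 29)
  expr <- generate_expression(bench$network, bench$truth, noise_sigma = 0,
                              seed = 29)
  sn <- sign_edges(bench$network, expr, "root")
  m <- merge(sn$edges, bench$truth$edge_signs,
             by = c("tf_id", "promoter_id"))
  expect_true(all((m$polarity == "activating") == (m$sign == "+")))
})

test_that("ortholog pair generator honours its rate parameters", {
  gen <- generate_network(n_tfs = 60, n_promoters = 40, n_dual_nodes = 10,
                          seed = 37)
  pair <- generate_ortholog_pair(gen$network, conservation_fraction = 1,
                                 one2many_rate = 0, noise_edge_fraction = 0,
                                 seed = 37)
  rep1 <- conserved_edges(gen$network, pair$net_b, pair$omap)
  expect_equal(rep1$fraction_a, 1)
  expect_true(all(pair$omap$pairs$relation == "one2one"))

  pair0 <- generate_ortholog_pair(gen$network, conservation_fraction = 0,
                                  seed = 37)
  rep0 <- conserved_edges(gen$network, pair0$net_b, pair0$omap)
  expect_equal(rep0$conserved_a, 0)

  pair_m <- generate_ortholog_pair(gen$network, one2many_rate = 0.5, seed = 37)
  expect_gt(sum(pair_m$omap$pairs$relation == "one2many"), 0)
  expect_gt(nrow(pair_m$omap$pairs), nrow(gen$network$nodes))
})

test_that("the FFL benchmark plants disjoint loops across all eight types", {
  bench <- generate_ffl_benchmark(n_loops = 50, seed = 41)
  expect_equal(nrow(bench$network$edges), 150)
  expect_equal(nrow(bench$truth$planted_ffls), 50)
  # loops are node-disjoint, so enumeration finds exactly the planted set
  found <- enumerate_ffls(bench$network)
  expect_setequal(paste(found$tf1, found$tf2, found$target),
                  paste(bench$truth$planted_ffls$tf1,
                        bench$truth$planted_ffls$tf2,
                        bench$truth$planted_ffls$target))
  # planted types agree with the classification of the planted signs
  p <- bench$truth$planted_ffls
  expect_equal(p$ffl_type, classify_ffl(p$s1, p$s2, p$s3))
  expect_gte(length(unique(p$ffl_type)), 7)
})
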