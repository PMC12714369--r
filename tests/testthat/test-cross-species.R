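test_that("projection expands orthologs and drops unmapped edges", {
  net <- suppressMessages(grn(data.frame(tf_id = c("T1", "T2"),
                                         promoter_id = c("P1", "P2")),
                              species = "A"))
  omap <- ortholog_map(data.frame(gene_a = c("T1", "T1", "P1"),
                                  gene_b = c("t1a", "t1b", "p1")),
                       species_a = "A", species_b = "B")
  proj <- suppressMessages(project_network(net, omap))
  expect_equal(nrow(proj$edges), 2)  # {t1a, t1b} x {p1}
  expect_setequal(paste(proj$edges$tf_id, proj$edges$promoter_id),
                  c("t1a p1", "t1b p1"))
  expect_equal(attr(proj, "n_dropped_edges"), 1)  # T2/P2 unmapped
  expect_true(all(proj$edges$provenance == "projected"))
  expect_true(all(proj$nodes$species == "B"))

  omap_wrong <- ortholog_map(data.frame(gene_a = "T1", gene_b = "t1"),
                             species_a = "C", species_b = "B")
  expect_error(project_network(net, omap_wrong),
               class = "pdinet_config_error")
})

test_that("projection through a one-to-one map preserves mapped edge counts", {
  set.seed(610)
  net <- random_grn(30, p = 0.1)
  ids <- net$nodes$node_id
  omap <- ortholog_map(data.frame(gene_a = ids, gene_b = paste0("b_", ids)))
  proj <- suppressMessages(project_network(net, omap))
  expect_equal(nrow(proj$edges), nrow(net$edges))
})

test_that("syntenic restriction filters projection pairs", {
  net <- suppressMessages(grn(data.frame(tf_id = "T1", promoter_id = "P1"),
                              species = "A"))
  omap <- ortholog_map(data.frame(gene_a = c("T1", "T1", "P1"),
                                  gene_b = c("t1a", "t1b", "p1"),
                                  syntenic = c(1, 0, 1)),
                       species_a = "A", species_b = "B")
  expect_equal(nrow(suppressMessages(project_network(net, omap))$edges), 1)
  expect_equal(nrow(suppressMessages(
    project_network(net, omap, require_syntenic = FALSE))$edges), 2)
})

test_that("conservation scoring follows the both-endpoints criterion", {
  a <- suppressMessages(grn(data.frame(tf_id = "T", promoter_id = "P")))
  b <- suppressMessages(grn(data.frame(tf_id = "t", promoter_id = "p")))
  omap <- ortholog_map(data.frame(gene_a = c("T", "P"), gene_b = c("t", "p")))
  rep1 <- conserved_edges(a, b, omap)
  expect_equal(rep1$tested_a, 1)
  expect_equal(rep1$conserved_a, 1)
  expect_equal(rep1$fraction_a, 1)

  b2 <- suppressMessages(grn(data.frame(tf_id = "p", promoter_id = "t")))
  rep2 <- conserved_edges(a, b2, omap)
  expect_equal(rep2$tested_a, 1)   # both orthologs present in B's nodes
  expect_equal(rep2$conserved_a, 0)

  expect_error(conserved_edges(a, b, ortholog_map(
    data.frame(gene_a = character(), gene_b = character()))),
    class = "pdinet_domain_error")
})

test_that("conserved edge sets are direction-consistent on one-to-one maps", {
  set.seed(611)
  gen <- generate_network(n_tfs = 30, n_promoters = 20, n_dual_nodes = 5,
                          mean_outdegree = 3, seed = 611)
  pair <- generate_ortholog_pair(gen$network, conservation_fraction = 0.4,
                                 one2many_rate = 0, seed = 611)
  rep <- conserved_edges(gen$network, pair$net_b, pair$omap)
  translated <- data.frame(
    tf_id = paste0("b_", rep$conserved_edges_a$tf_id),
    promoter_id = paste0("b_", rep$conserved_edges_a$promoter_id))
  expect_setequal(paste(translated$tf_id, translated$promoter_id),
                  paste(rep$conserved_edges_b$tf_id,
                        rep$conserved_edges_b$promoter_id))
})

test_that("planted conservation fractions are recovered", {
  gen <- generate_network(n_tfs = 120, n_promoters = 80, n_dual_nodes = 20,
                          mean_outdegree = 9, hub_fraction = 0.1, seed = 612)
  expect_gte(nrow(gen$network$edges), 1000)
  pair <- generate_ortholog_pair(gen$network, conservation_fraction = 0.3,
                                 one2many_rate = 0.1, seed = 612)
  rep <- conserved_edges(gen$network, pair$net_b, pair$omap)
  expect_equal(rep$tested_a, nrow(gen$network$edges))
  expect_lt(abs(rep$fraction_a - 0.3), 0.05)
  expect_equal(rep$conserved_a, nrow(pair$truth$planted_conserved))
})

test_that("network merging flags shared and private edges", {
  a <- suppressMessages(grn(data.frame(tf_id = c("X", "Y"),
                                       promoter_id = c("p", "q"))))
  b <- suppressMessages(grn(data.frame(tf_id = c("U", "V", "W"),
                                       promoter_id = c("r", "s", "t"))))
  m1 <- merge_networks(a, b)
  expect_equal(nrow(m1$edges), 5)
  expect_equal(sum(m1$edges$source == "both"), 0)

  m2 <- merge_networks(a, a)
  expect_true(all(m2$edges$source == "both"))

  b3 <- suppressMessages(grn(data.frame(tf_id = c("X", "V", "W"),
                                        promoter_id = c("p", "s", "t"))))
  a3 <- suppressMessages(grn(data.frame(tf_id = c("X", "Y", "Z"),
                                        promoter_id = c("p", "q", "r"))))
  m3 <- merge_networks(a3, b3)
  expect_equal(nrow(m3$edges), 5)
  expect_equal(sum(m3$edges$source == "both"), 1)
  expect_equal(m3$edges$tf_id[m3$edges$source == "both"], "X")
})
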