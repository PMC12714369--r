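test_that("edge-list parsing infers roles and counts from positions", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("tf_id\tpromoter_id", "A\tp1", "A\tp2", "B\tp1"), path)
  net <- read_edge_list(path)
  expect_s3_class(net, "grn")
  expect_equal(nrow(net$edges), 3)
  expect_setequal(net$nodes$node_id[net$nodes$role == "TF"], c("A", "B"))
  expect_setequal(net$nodes$node_id[net$nodes$role == "promoter"],
                  c("p1", "p2"))

  # a node on both sides becomes TF_and_promoter
  writeLines(c("tf_id\tpromoter_id", "A\tB", "A\tp1", "B\tp1"), path)
  net2 <- read_edge_list(path)
  expect_equal(net2$nodes$role[net2$nodes$node_id == "B"], "TF_and_promoter")
})

test_that("duplicate rows collapse with a logged count and blanks are rejected", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("tf_id\tpromoter_id", "A\tp1", "A\tp2", "B\tp1", "A\tp1"),
             path)
  expect_message(net <- read_edge_list(path), "1 duplicate")
  expect_equal(nrow(net$edges), 3)
  expect_equal(attr(net, "n_duplicates"), 1)

  writeLines(c("tf_id\tpromoter_id", "A\tp1", "\tp2"), path)
  expect_warning(net <- read_edge_list(path), "blank identifier")
  expect_equal(nrow(net$edges), 1)
})

test_that("missing columns and empty files raise classed errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("x\ty", "A\tp1"), path)
  expect_error(read_edge_list(path), class = "pdinet_config_error")
  writeLines("tf_id\tpromoter_id", path)
  expect_error(read_edge_list(path), class = "pdinet_domain_error")
})

test_that("column remapping and node-attribute overrides are honoured", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("TF\tProm", "A\tp1", "B\tp1"), path)
  attrs <- data.frame(node_id = c("A", "p1"), family = c("bZIP", ""),
                      process = c("", "Nitrogen transporter"),
                      stringsAsFactors = FALSE)
  net <- read_edge_list(path, column_map = c(tf = "TF", promoter = "Prom"),
                        node_attrs = attrs)
  expect_equal(net$nodes$family[net$nodes$node_id == "A"], "bZIP")
  expect_equal(net$nodes$process[net$nodes$node_id == "p1"],
               "Nitrogen transporter")
})

test_that("degree table counts distinct partners", {
  deg <- degree_table(toy_net())
  expect_equal(deg$outdegree[match(c("A", "B"), deg$node_id)], c(2, 1))
  expect_equal(deg$indegree[match(c("p1", "p2"), deg$node_id)], c(2, 1))
  expect_equal(deg$indegree[match(c("A", "B"), deg$node_id)], c(0, 0))
})

test_that("hub report applies strict thresholds and complement counts", {
  net <- suppressMessages(grn(data.frame(tf_id = "A", promoter_id = "p1")))
  rep0 <- hub_report(net, indegree_threshold = 0, outdegree_threshold = 0)
  expect_equal(rep0$promoter_hubs$node_id, "p1")
  expect_equal(rep0$tf_hubs$node_id, "A")

  rep1 <- hub_report(toy_net(), indegree_threshold = 1,
                     outdegree_threshold = 1)
  expect_equal(rep1$promoter_hubs$node_id, "p1")   # indegree 2 > 1
  expect_equal(rep1$counts$n_promoters_at_or_below, 1)
  expect_equal(rep1$tf_hubs$node_id, "A")          # outdegree 2 > 1
  expect_error(hub_report(toy_net(), indegree_threshold = -1),
               class = "pdinet_domain_error")
})

test_that("degree conservation holds on random networks", {
  set.seed(401)
  for (i in 1:20) {
    net <- random_grn(sample(5:40, 1))
    deg <- degree_table(net)
    expect_equal(sum(deg$indegree), nrow(net$edges))
    expect_equal(sum(deg$outdegree), nrow(net$edges))
  }
})

test_that("reading a file concatenated with itself is idempotent", {
  path <- withr::local_tempfile(fileext = ".tsv")
  body <- c("A\tp1", "A\tp2", "B\tp1")
  writeLines(c("tf_id\tpromoter_id", body), path)
  once <- read_edge_list(path)
  writeLines(c("tf_id\tpromoter_id", body, body), path)
  twice <- suppressMessages(read_edge_list(path))
  expect_equal(once$edges, twice$edges)
  expect_equal(once$nodes, twice$nodes)
})

test_that("tsv serialization round-trips edges and roles exactly", {
  net <- toy_net()
  epath <- withr::local_tempfile(fileext = ".tsv")
  npath <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, epath, "tsv", nodes_path = npath)
  back <- read_edge_list(epath, node_attrs = npath, name = "toy")
  expect_setequal(paste(back$edges$tf_id, back$edges$promoter_id),
                  paste(net$edges$tf_id, net$edges$promoter_id))
  expect_equal(back$nodes[order(back$nodes$node_id), ],
               net$nodes[order(net$nodes$node_id), ],
               ignore_attr = TRUE)
})

test_that("sif export writes pd-relation lines and graphml carries roles", {
  net <- toy_net()
  spath <- withr::local_tempfile(fileext = ".sif")
  write_network(net, spath, "sif")
  lines <- readLines(spath)
  expect_length(lines, 3)
  expect_true(all(grepl("\tpd\t", lines)))

  gpath <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, gpath, "graphml")
  g <- igraph::read_graph(gpath, format = "graphml")
  expect_equal(igraph::gorder(g), 4)
  expect_setequal(igraph::V(g)$role, c("TF", "TF", "promoter", "promoter"))

  expect_error(write_network(net, spath, "xlsx"),
               class = "pdinet_config_error")
})
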