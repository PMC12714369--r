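test_that("expression I/O validates and round-trips", {
  vals <- matrix(c(1, 0, 2, 0, 0, 0, 0, 0), nrow = 2, byrow = TRUE,
                 dimnames = list(c("g1", "g2"), NULL))
  expr <- simple_expr(vals, times = c(0, 0.5, 3, 24))
  expect_equal(attr(expr, "all_zero_genes"), "g2")

  mpath <- withr::local_tempfile(fileext = ".tsv")
  spath <- withr::local_tempfile(fileext = ".tsv")
  write_expression(expr, mpath, spath)
  back <- read_expression(mpath, spath)
  expect_equal(back$values, expr$values)
  expect_equal(back$samples, expr$samples, ignore_attr = TRUE)

  # negative value rejected with coordinates
  vals2 <- vals; vals2[2, 3] <- -1
  expect_error(simple_expr(vals2, times = c(0, 0.5, 3, 24)),
               "g2.*s3", class = "pdinet_domain_error")

  # metadata mismatch names the offenders
  meta_bad <- expr$samples
  meta_bad$sample_id[1] <- "nope"
  bpath <- withr::local_tempfile(fileext = ".tsv")
  pdinet:::write_tsv_file(meta_bad, bpath)
  expect_error(read_expression(mpath, bpath), "nope",
               class = "pdinet_config_error")
})

test_that("DEG status is a strict pure function of effect and p", {
  expect_equal(deg_status(1.5, 0.01), "up")
  expect_equal(deg_status(3.0, 0.06), "not_de")
  expect_equal(deg_status(-2.0, 0.001), "down")
  # boundary values fall on the not_de side under strict inequalities
  expect_equal(deg_status(1, 0.01), "not_de")
  expect_equal(deg_status(-1, 0.01), "not_de")
  expect_equal(deg_status(1.5, 0.05), "not_de")
  expect_equal(deg_status(c(2, -2, NA), c(0.01, 0.2, 0.01)),
               c("up", "not_de", "not_de"))
  # configurable thresholds
  expect_equal(deg_status(0.8, 0.09, padj_max = 0.1, lfc_min = 0.5), "up")
})

test_that("overlay labels every node and summarises by process", {
  net <- suppressMessages(grn(
    data.frame(tf_id = c("A", "B"), promoter_id = c("p1", "p2")),
    node_attrs = data.frame(node_id = c("p1", "p2"),
                            process = c("Nitrogen transporter", ""))))
  degs <- data.frame(gene_id = c("A", "p1", "p2"), tissue = "leaf",
                     time_h = 3,
                     log2fc = c(1.5, -2, 0.2), padj = c(0.01, 0.001, 0.5))
  ov <- overlay_degs(net, degs, tissue = "leaf", time_h = 3)
  expect_equal(ov$status[match(c("A", "p1", "p2", "B"), ov$node_id)],
               c("up", "down", "not_de", "no_data"))
  summ <- attr(ov, "module_summary")
  expect_equal(summ$Freq[summ$process == "Nitrogen transporter" &
                           summ$status == "down"], 1)
  # context filter: no rows for the requested time -> all no_data
  ov2 <- overlay_degs(net, degs, tissue = "leaf", time_h = 24)
  expect_true(all(ov2$status == "no_data"))
})

test_that("tissue-specificity Gini matches closed forms and is scale-free", {
  # 4 groups, one replicate each
  vals <- matrix(c(5, 5, 5, 5,
                   8, 0, 0, 0,
                   1, 2, 3, 3), nrow = 3, byrow = TRUE,
                 dimnames = list(c("flat", "solo", "grad"), NULL))
  samples <- data.frame(sample_id = paste0("s", 1:4),
                        tissue = c("leaf", "root", "stem", "seed"),
                        phase = "deprivation", time_h = c(3, 3, 3, 3),
                        replicate = 1)
  expr <- expression_set(vals, samples)
  expect_equal(tissue_specificity_gini(expr, "flat"), 0)
  expect_equal(tissue_specificity_gini(expr, "solo"), 0.75)

  # means (1, 2, 3) over 3 groups -> 4/18
  vals3 <- matrix(c(1, 2, 3), nrow = 1, dimnames = list("g", NULL))
  expr3 <- expression_set(vals3, samples[1:3, ])
  expect_equal(tissue_specificity_gini(expr3, "g"), 4 / 18)

  # scale invariance
  expr3b <- expression_set(vals3 * 37.5, samples[1:3, ])
  expect_equal(tissue_specificity_gini(expr3b, "g"),
               tissue_specificity_gini(expr3, "g"))
  expect_error(tissue_specificity_gini(expr, "absent"),
               class = "pdinet_domain_error")
})

test_that("profile clustering recovers planted groups deterministically", {
  set.seed(7)
  times <- rep(c(0, 0.5, 3, 24), each = 2)
  up <- t(sapply(1:15, function(i) rep(c(1, 2, 4, 8), each = 2) +
                   stats::rnorm(8, sd = 0.05)))
  down <- t(sapply(1:15, function(i) rep(c(8, 4, 2, 1), each = 2) +
                     stats::rnorm(8, sd = 0.05)))
  vals <- abs(rbind(up, down))
  rownames(vals) <- c(paste0("up", 1:15), paste0("dn", 1:15))
  expr <- simple_expr(vals, times)

  cl <- cluster_profiles(expr, k = 2, seed = 99)
  planted <- rep(0:1, each = 15)
  # label-permutation-invariant comparison
  agreement <- max(mean(cl$cluster_id == planted),
                   mean(cl$cluster_id == 1 - planted))
  expect_equal(agreement, 1)
  expect_setequal(unique(cl$cluster_id), 0:1)

  cl2 <- cluster_profiles(expr, k = 2, seed = 99)
  expect_identical(cl, cl2)

  # constant gene is excluded and reported
  vals_c <- rbind(vals, const = rep(3, 8))
  expr_c <- simple_expr(vals_c, times)
  cl3 <- cluster_profiles(expr_c, k = 2, seed = 99)
  expect_equal(attr(cl3, "skipped"), "const")
  expect_false("const" %in% cl3$gene_id)

  expect_error(cluster_profiles(expr, k = 40, seed = 1),
               class = "pdinet_domain_error")
  expect_error(cluster_profiles(expr, k = 1, seed = 1),
               class = "pdinet_domain_error")
})
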