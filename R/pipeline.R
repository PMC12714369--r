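# Pipeline runner: configuration, stage dispatch and run manifest.
#
# The package's analysis surface is functional; `run_pipeline()` ties the
# stages together for batch use, reading a validated configuration,
# writing explicitly sorted output tables (so identical configurations
# and seeds produce byte-identical runs) and a machine-readable manifest.

PIPELINE_STAGES <- c("simulate", "stats", "enrich", "overlay", "cluster",
                     "gini", "ffl", "project", "conserve")

CONFIG_DEFAULTS <- list(
  network = NULL, node_attrs = NULL,
  expression = NULL, expression_meta = NULL,
  degs = NULL, ortholog_map = NULL, network_b = NULL,
  gcc_threshold = 0.5, padj = 0.05, log2fc = 1.0, alpha = 0.05,
  k_clusters = 10, indegree_threshold = 35, outdegree_threshold = 20,
  tissues = c("leaf", "root"), seed = 1, out_dir = "pdinet_out"
)

#' Build and validate a pipeline configuration
#'
#' Starts from the package defaults (GCC polarity threshold 0.5, DEG
#' thresholds padj 0.05 / log2fc 1, enrichment alpha 0.05, 10 clusters)
#' and overrides them with the supplied values. Unknown keys are rejected
#' by name; thresholds must be positive. A configuration can also be read
#' from a YAML file with [read_pipeline_config()].
#'
#' @param ... configuration values to override; see `pdinet:::CONFIG_DEFAULTS`
#'   for the full key set (input paths `network`, `node_attrs`,
#'   `expression`, `expression_meta`, `degs`, `ortholog_map`, `network_b`;
#'   thresholds; `tissues`; `seed`; `out_dir`).
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  override <- list(...)
  if (length(override) > 0 &&
      (is.null(names(override)) || any(names(override) == ""))) {
    stop_config("all configuration values must be named")
  }
  unknown <- setdiff(names(override), names(CONFIG_DEFAULTS))
  if (length(unknown) > 0) {
    stop_config("unknown configuration key(s): ",
                paste(unknown, collapse = ", "))
  }
  config <- utils::modifyList(CONFIG_DEFAULTS, override, keep.null = TRUE)
  for (key in c("gcc_threshold", "padj", "log2fc", "alpha", "k_clusters")) {
    if (!is.numeric(config[[key]]) || config[[key]] <= 0) {
      stop_config("configuration value '", key, "' must be positive")
    }
  }
  structure(config, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys are configuration values;
#'   unknown keys are rejected.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: ", path)
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the analysis pipeline
#'
#' Executes the requested stages against the configured inputs and writes
#' one output table per stage into `config$out_dir`, plus a JSON run
#' manifest recording inputs, parameters, seed and output row counts.
#' Stage `simulate` generates a full synthetic fixture set (network, node
#' attributes, expression + metadata, DEG table, ortholog map and partner
#' network) which later stages consume when no external inputs are
#' configured. Stage `ffl` degrades gracefully: without expression data it
#' writes the unsigned enumeration only.
#'
#' All tables are explicitly sorted, so a rerun with the same
#' configuration, inputs and seed is byte-identical.
#'
#' @param config a `pipeline_config` (or arguments for one, via a list).
#' @param stages character vector of stages to run, or `"all"`.
#' @return Invisibly, a named list of written file paths.
#' @export
run_pipeline <- function(config = pipeline_config(), stages = "all") {
  if (!inherits(config, "pipeline_config")) {
    config <- do.call(pipeline_config, as.list(config))
  }
  if (identical(stages, "all")) stages <- PIPELINE_STAGES
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad) > 0) {
    stop_config("unknown stage(s): ", paste(bad, collapse = ", "))
  }
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  state <- list()

  if ("simulate" %in% stages) {
    gen <- generate_network(seed = config$seed)
    expr <- generate_expression(gen$network, gen$truth,
                                tissues = config$tissues,
                                seed = config$seed)
    degs <- generate_deg_table(gen$network, tissues = config$tissues,
                               seed = config$seed)
    pair <- generate_ortholog_pair(gen$network, seed = config$seed)
    paths$sim_network <- file.path(out_dir, "sim_network.tsv")
    paths$sim_nodes <- file.path(out_dir, "sim_nodes.tsv")
    write_network(gen$network, paths$sim_network, "tsv",
                  nodes_path = paths$sim_nodes)
    paths$sim_expression <- file.path(out_dir, "sim_expression.tsv")
    paths$sim_expression_meta <- file.path(out_dir, "sim_expression_meta.tsv")
    write_expression(expr, paths$sim_expression, paths$sim_expression_meta)
    paths$sim_degs <- file.path(out_dir, "sim_degs.tsv")
    write_tsv_file(degs, paths$sim_degs)
    paths$sim_orthologs <- file.path(out_dir, "sim_orthologs.tsv")
    write_tsv_file(pair$omap$pairs, paths$sim_orthologs)
    paths$sim_network_b <- file.path(out_dir, "sim_network_b.tsv")
    write_network(pair$net_b, paths$sim_network_b, "tsv")
    paths$sim_truth <- file.path(out_dir, "sim_truth.json")
    jsonlite::write_json(list(edge_signs = gen$truth$edge_signs,
                              planted_ffls = gen$truth$planted_ffls,
                              planted_conserved = pair$truth$planted_conserved,
                              seed = config$seed),
                         paths$sim_truth, auto_unbox = TRUE, digits = NA)
    state$net <- gen$network; state$expr <- expr; state$degs <- degs
    state$omap <- pair$omap; state$net_b <- pair$net_b
  }

  load_net <- function() {
    if (!is.null(state$net)) return(state$net)
    if (is.null(config$network)) stop_config("no network input configured")
    read_edge_list(config$network, node_attrs = config$node_attrs)
  }
  load_expr <- function() {
    if (!is.null(state$expr)) return(state$expr)
    if (is.null(config$expression) || is.null(config$expression_meta)) {
      return(NULL)
    }
    read_expression(config$expression, config$expression_meta)
  }

  if ("stats" %in% stages) {
    net <- state$net <- load_net()
    deg <- degree_table(net)
    deg <- deg[order(deg$node_id), ]
    paths$degrees <- file.path(out_dir, "degrees.tsv")
    write_tsv_file(deg, paths$degrees)
    hubs <- hub_report(net, config$indegree_threshold,
                       config$outdegree_threshold)
    paths$hub_promoters <- file.path(out_dir, "hub_promoters.tsv")
    write_tsv_file(hubs$promoter_hubs, paths$hub_promoters)
    paths$hub_tfs <- file.path(out_dir, "hub_tfs.tsv")
    write_tsv_file(hubs$tf_hubs, paths$hub_tfs)
  }

  if ("enrich" %in% stages) {
    net <- state$net <- load_net()
    paths$enrichment <- file.path(out_dir, "family_enrichment.tsv")
    write_tsv_file(family_enrichment_table(net, alpha = config$alpha),
                   paths$enrichment)
  }

  if ("overlay" %in% stages) {
    net <- state$net <- load_net()
    degs <- state$degs %||% {
      if (is.null(config$degs)) stop_config("no DEG input configured")
      read_tsv_file(config$degs)
    }
    contexts <- unique(degs[, c("tissue", "time_h")])
    contexts <- contexts[order(contexts$tissue, contexts$time_h), ]
    overlays <- do.call(rbind, lapply(seq_len(nrow(contexts)), function(i) {
      ov <- overlay_degs(net, degs, contexts$tissue[i], contexts$time_h[i],
                         padj_max = config$padj, lfc_min = config$log2fc)
      data.frame(tissue = contexts$tissue[i], time_h = contexts$time_h[i],
                 ov, stringsAsFactors = FALSE)
    }))
    overlays <- overlays[order(overlays$tissue, overlays$time_h,
                               overlays$node_id), ]
    paths$overlay <- file.path(out_dir, "deg_overlay.tsv")
    write_tsv_file(overlays, paths$overlay)
  }

  if ("cluster" %in% stages) {
    expr <- state$expr <- load_expr()
    if (is.null(expr)) stop_config("no expression input configured")
    clusters <- do.call(rbind, lapply(sort(unique(expr$samples$tissue)),
                                      function(tis) {
      cl <- cluster_profiles(expr, k = config$k_clusters,
                             seed = config$seed, tissue = tis)
      data.frame(tissue = tis, cl, stringsAsFactors = FALSE)
    }))
    clusters <- clusters[order(clusters$tissue, clusters$gene_id), ]
    paths$clusters <- file.path(out_dir, "clusters.tsv")
    write_tsv_file(clusters, paths$clusters)
  }

  snet <- NULL
  if (any(c("gini", "ffl") %in% stages)) {
    net <- state$net <- load_net()
    expr <- state$expr <- load_expr()
    if (!is.null(expr)) {
      contexts <- sort(intersect(config$tissues, unique(expr$samples$tissue)))
      snet <- sign_edges(net, expr, contexts,
                         threshold = config$gcc_threshold)
    }
  }

  if ("gini" %in% stages) {
    if (is.null(snet)) stop_config("no expression input configured")
    se <- snet$edges[order(snet$edges$context, snet$edges$tf_id,
                           snet$edges$promoter_id), ]
    paths$signed_edges <- file.path(out_dir, "signed_edges.tsv")
    write_tsv_file(se, paths$signed_edges)
  }

  if ("ffl" %in% stages) {
    net <- state$net
    ffls <- enumerate_ffls(net)
    paths$ffls <- file.path(out_dir, "ffls.tsv")
    write_tsv_file(ffls, paths$ffls)
    if (!is.null(snet) && nrow(ffls) > 0) {
      classified <- do.call(rbind, lapply(
        sort(unique(snet$edges$context)), function(ctx) {
          significant_ffls(snet, ffls, ctx)
        }))
      classified <- classified[order(classified$context, classified$tf1,
                                     classified$tf2, classified$target), ]
      paths$ffls_classified <- file.path(out_dir, "ffls_classified.tsv")
      write_tsv_file(classified, paths$ffls_classified)
    }
  }

  omap <- state$omap
  if (any(c("project", "conserve") %in% stages) && is.null(omap)) {
    if (is.null(config$ortholog_map)) {
      stop_config("no ortholog map configured")
    }
    omap <- read_ortholog_map(config$ortholog_map)
  }

  if ("project" %in% stages) {
    net <- state$net <- load_net()
    proj <- suppressMessages(project_network(net, omap))
    pe <- proj$edges[order(proj$edges$tf_id, proj$edges$promoter_id), ]
    paths$projected <- file.path(out_dir, "projected_network.tsv")
    write_tsv_file(pe, paths$projected)
  }

  if ("conserve" %in% stages) {
    net <- state$net <- load_net()
    net_b <- state$net_b %||% {
      if (is.null(config$network_b)) stop_config("no partner network configured")
      read_edge_list(config$network_b)
    }
    rep <- conserved_edges(net, net_b, omap)
    paths$conservation <- file.path(out_dir, "conservation_report.tsv")
    write_tsv_file(data.frame(direction = c("a_to_b", "b_to_a"),
                              tested = c(rep$tested_a, rep$tested_b),
                              conserved = c(rep$conserved_a, rep$conserved_b),
                              fraction = c(rep$fraction_a, rep$fraction_b)),
                   paths$conservation)
    ce <- rep$conserved_edges_a
    ce <- ce[order(ce$tf_id, ce$promoter_id), ]
    paths$conserved_edges <- file.path(out_dir, "conserved_edges.tsv")
    write_tsv_file(ce, paths$conserved_edges)
  }

  manifest <- list(
    package = "pdinet",
    version = as.character(utils::packageVersion("pdinet")),
    stages = stages,
    seed = config$seed,
    parameters = config[c("gcc_threshold", "padj", "log2fc", "alpha",
                          "k_clusters", "indegree_threshold",
                          "outdegree_threshold")],
    inputs = Filter(Negate(is.null),
                    config[c("network", "node_attrs", "expression",
                             "expression_meta", "degs", "ortholog_map",
                             "network_b")]),
    outputs = lapply(paths, function(p) {
      list(path = p, rows = length(readLines(p)) - 1L)
    })
  )
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
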