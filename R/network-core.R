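# Data model and I/O for protein-DNA interaction (PDI) networks.
#
# A network is a directed graph of TF -> promoter edges established by an
# assay such as enhanced yeast one-hybrid, or projected from another species
# through an ortholog map. Nodes carry a role: "TF" (appears only as a
# regulator), "promoter" (appears only as a bound target), or
# "TF_and_promoter" (participates on both sides, the "T/P" diamond nodes of
# a typical network figure).

ROLE_LEVELS <- c("TF", "promoter", "TF_and_promoter")

role_is_tf <- function(role) role %in% c("TF", "TF_and_promoter")
role_is_promoter <- function(role) role %in% c("promoter", "TF_and_promoter")

#' Construct a regulatory network from an edge table
#'
#' Builds a validated PDI network from a data frame of TF -> promoter edges.
#' Node roles are inferred from edge positions (a node appearing only as a
#' TF gets role `"TF"`, only as a promoter `"promoter"`, both
#' `"TF_and_promoter"`) and may be overridden, together with family and
#' process annotations, through `node_attrs`.
#'
#' Identifiers are matched exactly (case-sensitive) after trimming
#' surrounding whitespace. Duplicate (tf, promoter) rows collapse to a
#' single edge with a message reporting the number collapsed; rows with a
#' blank identifier are rejected with a warning. Self-binding edges (a TF
#' bound to its own promoter) are retained.
#'
#' @param edges data frame with at least the columns named by `tf_col` and
#'   `promoter_col`; an optional provenance column is carried through.
#' @param node_attrs optional data frame with columns `node_id` and any of
#'   `role`, `family`, `process`, `display_name`; values override inference.
#' @param name network label.
#' @param species species tag applied to all nodes.
#' @param tf_col,promoter_col,provenance_col column names in `edges`.
#' @return An object of class `grn`: a list with elements `nodes`
#'   (data frame: node_id, display_name, role, family, species, process),
#'   `edges` (data frame: tf_id, promoter_id, provenance) and `name`.
#'   The number of duplicate rows collapsed is stored in
#'   `attr(, "n_duplicates")`.
#' @examples
#' edges <- data.frame(tf = c("A", "A", "B"), promoter = c("p1", "p2", "p1"))
#' net <- grn(edges, tf_col = "tf", promoter_col = "promoter")
#' degree_table(net)
#' @export
grn <- function(edges, node_attrs = NULL, name = "network", species = "",
                tf_col = "tf_id", promoter_col = "promoter_id",
                provenance_col = "provenance") {
  if (!is.data.frame(edges)) stop_config("`edges` must be a data frame")
  missing_cols <- setdiff(c(tf_col, promoter_col), names(edges))
  if (length(missing_cols) > 0) {
    stop_config("missing required edge columns: ",
                paste(missing_cols, collapse = ", "))
  }
  if (nrow(edges) == 0) stop_domain("empty input: no edge rows")

  tf <- trim_ws(as.character(edges[[tf_col]]))
  pr <- trim_ws(as.character(edges[[promoter_col]]))
  prov <- if (provenance_col %in% names(edges)) {
    as.character(edges[[provenance_col]])
  } else {
    rep("", length(tf))
  }

  blank <- is.na(tf) | is.na(pr) | tf == "" | pr == ""
  if (any(blank)) {
    warning(sum(blank), " edge row(s) with a blank identifier rejected")
    tf <- tf[!blank]; pr <- pr[!blank]; prov <- prov[!blank]
  }
  if (length(tf) == 0) stop_domain("empty input: no usable edge rows")

  key <- paste(tf, pr, sep = "\r")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  if (n_dup > 0) {
    message(n_dup, " duplicate (tf, promoter) row(s) collapsed")
    tf <- tf[!dup]; pr <- pr[!dup]; prov <- prov[!dup]
  }
  edge_df <- data.frame(tf_id = tf, promoter_id = pr, provenance = prov,
                        stringsAsFactors = FALSE)

  ids <- unique(c(tf, pr))
  role <- ifelse(ids %in% tf,
                 ifelse(ids %in% pr, "TF_and_promoter", "TF"),
                 "promoter")
  nodes <- data.frame(node_id = ids, display_name = ids, role = role,
                      family = "", species = species, process = "",
                      stringsAsFactors = FALSE)

  if (!is.null(node_attrs)) {
    if (!"node_id" %in% names(node_attrs)) {
      stop_config("`node_attrs` must contain a node_id column")
    }
    node_attrs$node_id <- trim_ws(as.character(node_attrs$node_id))
    idx <- match(nodes$node_id, node_attrs$node_id)
    for (col in intersect(c("role", "family", "process", "display_name"),
                          names(node_attrs))) {
      val <- as.character(node_attrs[[col]])[idx]
      keep <- !is.na(val) & val != ""
      nodes[[col]][keep] <- val[keep]
    }
    bad_role <- !nodes$role %in% ROLE_LEVELS
    if (any(bad_role)) {
      stop_config("invalid role value(s): ",
                  paste(unique(nodes$role[bad_role]), collapse = ", "))
    }
  }

  # family labels only make sense on TF-capable nodes
  nodes$family[!role_is_tf(nodes$role)] <- ""

  net <- structure(list(nodes = nodes, edges = edge_df, name = name),
                   class = "grn", n_duplicates = n_dup)
  validate_grn(net)
  net
}

#' Validate a regulatory network object
#'
#' Checks the structural invariants of a `grn`: unique node identifiers,
#' every edge endpoint present in the node table, TF-capable roles on edge
#' sources and promoter-capable roles on edge targets, and family labels
#' only on TF-capable nodes.
#'
#' @param net a `grn` object.
#' @return `net`, invisibly; errors on violation.
#' @export
validate_grn <- function(net) {
  stopifnot(inherits(net, "grn"))
  nodes <- net$nodes; edges <- net$edges
  if (anyDuplicated(nodes$node_id)) {
    stop_domain("duplicate node_id in network ", net$name)
  }
  if (!all(edges$tf_id %in% nodes$node_id) ||
      !all(edges$promoter_id %in% nodes$node_id)) {
    stop_domain("edge endpoint missing from node table in ", net$name)
  }
  role <- nodes$role[match(edges$tf_id, nodes$node_id)]
  if (!all(role_is_tf(role))) {
    stop_domain("edge source without TF-capable role in ", net$name)
  }
  role <- nodes$role[match(edges$promoter_id, nodes$node_id)]
  if (!all(role_is_promoter(role))) {
    stop_domain("edge target without promoter-capable role in ", net$name)
  }
  fam_bad <- nodes$family != "" & !role_is_tf(nodes$role)
  if (any(fam_bad)) stop_domain("family label on non-TF node in ", net$name)
  invisible(net)
}

#' @export
print.grn <- function(x, ...) {
  n_tf <- sum(role_is_tf(x$nodes$role))
  n_pr <- sum(role_is_promoter(x$nodes$role))
  cat(sprintf("<grn> %s: %d nodes (%d TF-capable, %d promoter-capable), %d edges\n",
              x$name, nrow(x$nodes), n_tf, n_pr, nrow(x$edges)))
  invisible(x)
}

#' Read a PDI network from an edge-list TSV
#'
#' Parses a tab-separated edge list with a header row into a validated
#' network. Logical fields are mapped to file columns through `column_map`,
#' so deposited tables with arbitrary column names can be ingested without
#' editing the file.
#'
#' @param path path to a TSV file with a header row.
#' @param column_map named character vector mapping logical fields to column
#'   names; `tf` and `promoter` are required, `provenance` optional.
#' @param node_attrs optional path to a node-attribute TSV (columns
#'   `node_id`, `role`, `family`, `process`) or a data frame; overrides
#'   role inference.
#' @param name,species passed to [grn()].
#' @return A `grn` object.
#' @seealso [write_network()] for the inverse operation.
#' @export
read_edge_list <- function(path,
                           column_map = c(tf = "tf_id", promoter = "promoter_id"),
                           node_attrs = NULL, name = NULL, species = "") {
  df <- read_tsv_file(path)
  if (nrow(df) == 0) stop_domain("empty input: ", path)
  for (field in c("tf", "promoter")) {
    col <- if (field %in% names(column_map)) column_map[[field]] else NULL
    if (is.null(col) || !col %in% names(df)) {
      stop_config("column for '", field, "' (", col %||% "unset",
                  ") not found in ", path)
    }
  }
  attrs <- node_attrs
  if (is.character(attrs)) attrs <- read_tsv_file(attrs)
  prov_col <- if ("provenance" %in% names(column_map)) {
    column_map[["provenance"]]
  } else {
    "provenance"
  }
  grn(df, node_attrs = attrs,
      name = name %||% sub("\\.[^.]*$", "", basename(path)),
      species = species,
      tf_col = column_map[["tf"]], promoter_col = column_map[["promoter"]],
      provenance_col = prov_col)
}

#' Per-node indegree and outdegree
#'
#' Indegree is the number of distinct TFs bound to a node's promoter;
#' outdegree is the number of distinct promoters the node's TF binds.
#' Counts are over the deduplicated edge set, so each partner contributes
#' at most once.
#'
#' @param net a `grn` object.
#' @return Data frame with columns `node_id`, `indegree`, `outdegree`,
#'   one row per node, in node-table order.
#' @export
degree_table <- function(net) {
  validate_grn(net)
  ids <- net$nodes$node_id
  outd <- table(factor(net$edges$tf_id, levels = ids))
  ind <- table(factor(net$edges$promoter_id, levels = ids))
  data.frame(node_id = ids,
             indegree = as.integer(ind),
             outdegree = as.integer(outd),
             stringsAsFactors = FALSE)
}

#' Hub summary at degree thresholds
#'
#' Lists promoter-capable nodes whose indegree strictly exceeds
#' `indegree_threshold` and TF-capable nodes whose outdegree strictly
#' exceeds `outdegree_threshold`, together with the complement counts
#' (nodes at or below each threshold).
#'
#' @param net a `grn` object.
#' @param indegree_threshold,outdegree_threshold non-negative integers.
#' @return A list with elements `promoter_hubs` and `tf_hubs` (data frames
#'   sorted by decreasing degree) and a `counts` list holding
#'   `n_promoter_hubs`, `n_promoters_at_or_below`, `n_tf_hubs`,
#'   `n_tfs_at_or_below`.
#' @export
hub_report <- function(net, indegree_threshold = 35, outdegree_threshold = 20) {
  if (indegree_threshold < 0 || outdegree_threshold < 0) {
    stop_domain("thresholds must be >= 0")
  }
  deg <- degree_table(net)
  role <- net$nodes$role[match(deg$node_id, net$nodes$node_id)]
  prom <- deg[role_is_promoter(role), , drop = FALSE]
  tfs <- deg[role_is_tf(role), , drop = FALSE]
  prom_hubs <- prom[prom$indegree > indegree_threshold, , drop = FALSE]
  tf_hubs <- tfs[tfs$outdegree > outdegree_threshold, , drop = FALSE]
  prom_hubs <- prom_hubs[order(-prom_hubs$indegree, prom_hubs$node_id), ]
  tf_hubs <- tf_hubs[order(-tf_hubs$outdegree, tf_hubs$node_id), ]
  rownames(prom_hubs) <- rownames(tf_hubs) <- NULL
  list(promoter_hubs = prom_hubs,
       tf_hubs = tf_hubs,
       counts = list(n_promoter_hubs = nrow(prom_hubs),
                     n_promoters_at_or_below = nrow(prom) - nrow(prom_hubs),
                     n_tf_hubs = nrow(tf_hubs),
                     n_tfs_at_or_below = nrow(tfs) - nrow(tf_hubs)))
}

#' Serialize a network to TSV, SIF or GraphML
#'
#' `tsv` writes the edge table (round-trip safe through
#' [read_edge_list()]); `sif` writes Cytoscape simple-interaction lines
#' with relation token `pd`; `graphml` writes a GraphML document carrying
#' role, family, process and species as node attributes. For `tsv` an
#' optional `nodes_path` also writes the node-attribute table so role
#' overrides survive the round trip.
#'
#' @param net a `grn` object.
#' @param path output file path.
#' @param format one of `"tsv"`, `"sif"`, `"graphml"`.
#' @param nodes_path optional node-attribute TSV path (tsv format only).
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("tsv", "sif", "graphml"),
                          nodes_path = NULL) {
  validate_grn(net)
  format <- tryCatch(match.arg(format),
                     error = function(e) stop_config("unsupported format"))
  if (format == "tsv") {
    write_tsv_file(net$edges, path)
    if (!is.null(nodes_path)) {
      write_tsv_file(net$nodes[, c("node_id", "role", "family", "process",
                                   "display_name")], nodes_path)
    }
  } else if (format == "sif") {
    writeLines(paste(net$edges$tf_id, "pd", net$edges$promoter_id, sep = "\t"),
               path)
  } else {
    g <- as_igraph(net)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Convert a network to an igraph object
#'
#' Node role, family, process, species and display name are attached as
#' vertex attributes; edge provenance as an edge attribute.
#'
#' @param net a `grn` object.
#' @return An [igraph::graph] object.
#' @export
as_igraph <- function(net) {
  validate_grn(net)
  igraph::graph_from_data_frame(
    net$edges[, c("tf_id", "promoter_id", "provenance")],
    directed = TRUE, vertices = net$nodes)
}
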