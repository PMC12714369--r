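# Cross-species network projection and edge-conservation scoring.
#
# An ortholog map pairs genes of species A with genes of species B
# (one-to-one or one-to-many, optionally restricted to syntenic pairs).
# Projection transfers each edge to the partner species by expanding both
# endpoints over their orthologs; conservation scoring asks, for each edge
# of one experimentally tested network, whether any ortholog combination
# of its endpoints is an edge of the other.

#' Construct an ortholog map
#'
#' @param pairs data frame with columns `gene_a`, `gene_b` and optionally
#'   `relation` (one2one / one2many / many2many) and `syntenic` (logical
#'   or 0/1). Duplicate (gene_a, gene_b) pairs are an error.
#' @param species_a,species_b species labels.
#' @return An object of class `ortholog_map`.
#' @export
ortholog_map <- function(pairs, species_a = "A", species_b = "B") {
  req <- c("gene_a", "gene_b")
  missing_cols <- setdiff(req, names(pairs))
  if (length(missing_cols) > 0) {
    stop_config("ortholog table missing columns: ",
                paste(missing_cols, collapse = ", "))
  }
  pairs$gene_a <- trim_ws(as.character(pairs$gene_a))
  pairs$gene_b <- trim_ws(as.character(pairs$gene_b))
  if (anyDuplicated(paste(pairs$gene_a, pairs$gene_b, sep = "\r"))) {
    stop_domain("duplicate (gene_a, gene_b) ortholog pair")
  }
  if (!"relation" %in% names(pairs)) {
    pairs$relation <- rep("one2one", nrow(pairs))
  }
  if (!"syntenic" %in% names(pairs)) pairs$syntenic <- rep(TRUE, nrow(pairs))
  pairs$syntenic <- as.logical(as.integer(as.logical(pairs$syntenic)))
  structure(list(pairs = pairs, species_a = species_a,
                 species_b = species_b),
            class = "ortholog_map")
}

#' Read an ortholog map from TSV
#'
#' Expects columns `gene_a`, `gene_b` and optionally `relation` and
#' `syntenic` (0/1).
#'
#' @param path TSV file path.
#' @param species_a,species_b species labels.
#' @return An `ortholog_map`.
#' @export
read_ortholog_map <- function(path, species_a = "A", species_b = "B") {
  ortholog_map(read_tsv_file(path), species_a, species_b)
}

#' @export
print.ortholog_map <- function(x, ...) {
  cat(sprintf("<ortholog_map> %s <-> %s: %d pairs (%d syntenic)\n",
              x$species_a, x$species_b, nrow(x$pairs), sum(x$pairs$syntenic)))
  invisible(x)
}

# orthologs of `ids` on the other side; direction "a2b" or "b2a"
#' @noRd
ortho_lookup <- function(omap, direction = "a2b", syntenic_only = FALSE) {
  p <- omap$pairs
  if (syntenic_only) p <- p[p$syntenic, , drop = FALSE]
  if (direction == "a2b") {
    split(p$gene_b, p$gene_a)
  } else {
    split(p$gene_a, p$gene_b)
  }
}

#' Project a network into another species through an ortholog map
#'
#' Each edge (tf, promoter) expands to the Cartesian product of the
#' orthologs of its endpoints; duplicate projected edges collapse, and
#' edges with an unmapped endpoint are dropped and counted. One-to-many
#' relations therefore fan out into several projected edges. Projected
#' edges carry provenance `"projected"`.
#'
#' @param net a `grn` whose species matches `omap$species_a` (checked when
#'   both labels are non-empty).
#' @param omap an `ortholog_map`.
#' @param require_syntenic use only syntenic ortholog pairs (default
#'   `TRUE`, the convention for building a projected network).
#' @param name label for the projected network.
#' @return A `grn` in species-B coordinates; the number of source edges
#'   dropped for lack of an ortholog is stored in
#'   `attr(, "n_dropped_edges")`.
#' @export
project_network <- function(net, omap, require_syntenic = TRUE,
                            name = paste0(net$name, "_projected")) {
  validate_grn(net)
  stopifnot(inherits(omap, "ortholog_map"))
  net_species <- unique(net$nodes$species)
  if (length(net_species) == 1 && net_species != "" &&
      omap$species_a != "" && net_species != omap$species_a) {
    stop_config("network species '", net_species,
                "' does not match ortholog map species_a '",
                omap$species_a, "'")
  }
  lut <- ortho_lookup(omap, "a2b", syntenic_only = require_syntenic)
  pieces <- vector("list", nrow(net$edges))
  n_dropped <- 0L
  for (i in seq_len(nrow(net$edges))) {
    tfs <- lut[[net$edges$tf_id[i]]]
    prs <- lut[[net$edges$promoter_id[i]]]
    if (is.null(tfs) || is.null(prs)) {
      n_dropped <- n_dropped + 1L
      next
    }
    pieces[[i]] <- expand.grid(tf_id = tfs, promoter_id = prs,
                               KEEP.OUT.ATTRS = FALSE,
                               stringsAsFactors = FALSE)
  }
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (length(pieces) == 0) stop_domain("no edges could be projected")
  edges <- do.call(rbind, pieces)
  edges$provenance <- "projected"
  out <- grn(edges, name = name, species = omap$species_b)
  attr(out, "n_dropped_edges") <- n_dropped
  out
}

#' Score edge conservation between two networks
#'
#' An edge (tf, promoter) of network A is *tested* iff both endpoints have
#' at least one ortholog appearing among network B's nodes (the
#' interaction is assayable in both screens), and *conserved* iff any
#' ortholog combination of its endpoints is an edge of B. Bookkeeping is
#' symmetric: the same definitions are applied from B back to A. By
#' default all ortholog pairs are used regardless of synteny (the
#' convention for comparing two experimentally tested networks).
#'
#' @param net_a,net_b `grn` objects in species A and B coordinates.
#' @param omap an `ortholog_map` bridging the two species.
#' @param require_syntenic restrict to syntenic pairs (default `FALSE`).
#' @return An object of class `conservation_report`: a list with counts
#'   `tested_a`, `conserved_a`, `tested_b`, `conserved_b`, fractions
#'   `fraction_a`, `fraction_b`, and data frames `conserved_edges_a`,
#'   `conserved_edges_b` listing the conserved edges of each network.
#' @export
conserved_edges <- function(net_a, net_b, omap, require_syntenic = FALSE) {
  validate_grn(net_a); validate_grn(net_b)
  stopifnot(inherits(omap, "ortholog_map"))
  if (nrow(omap$pairs) == 0) stop_domain("empty ortholog map")

  score_dir <- function(from, to, direction) {
    lut <- ortho_lookup(omap, direction, syntenic_only = require_syntenic)
    to_nodes <- to$nodes$node_id
    to_key <- paste(to$edges$tf_id, to$edges$promoter_id, sep = "\r")
    tested <- logical(nrow(from$edges))
    conserved <- logical(nrow(from$edges))
    for (i in seq_len(nrow(from$edges))) {
      tfs <- intersect(lut[[from$edges$tf_id[i]]], to_nodes)
      prs <- intersect(lut[[from$edges$promoter_id[i]]], to_nodes)
      if (length(tfs) == 0 || length(prs) == 0) next
      tested[i] <- TRUE
      combos <- paste(rep(tfs, each = length(prs)), prs, sep = "\r")
      conserved[i] <- any(combos %in% to_key)
    }
    list(tested = tested, conserved = conserved)
  }

  ab <- score_dir(net_a, net_b, "a2b")
  ba <- score_dir(net_b, net_a, "b2a")
  structure(list(
    tested_a = sum(ab$tested), conserved_a = sum(ab$conserved),
    tested_b = sum(ba$tested), conserved_b = sum(ba$conserved),
    fraction_a = if (sum(ab$tested) > 0) sum(ab$conserved) / sum(ab$tested) else NA_real_,
    fraction_b = if (sum(ba$tested) > 0) sum(ba$conserved) / sum(ba$tested) else NA_real_,
    conserved_edges_a = net_a$edges[ab$conserved, c("tf_id", "promoter_id")],
    conserved_edges_b = net_b$edges[ba$conserved, c("tf_id", "promoter_id")]
  ), class = "conservation_report")
}

#' @export
print.conservation_report <- function(x, ...) {
  cat(sprintf("<conservation_report> A: %d/%d conserved (%.1f%%); B: %d/%d conserved (%.1f%%)\n",
              x$conserved_a, x$tested_a, 100 * x$fraction_a,
              x$conserved_b, x$tested_b, 100 * x$fraction_b))
  invisible(x)
}

#' Merge two networks in the same coordinate space
#'
#' Takes the node and edge union of two networks (one typically a
#' projection into the other's species) and flags every edge `a_only`,
#' `b_only` or `both`.
#'
#' @param net_a_projected,net_b `grn` objects sharing a gene-id space.
#' @param name label for the merged network.
#' @return A `grn` whose edge table carries a `source` column; counts per
#'   flag in `attr(, "source_counts")`.
#' @export
merge_networks <- function(net_a_projected, net_b,
                           name = paste(net_a_projected$name, net_b$name,
                                        sep = "+")) {
  validate_grn(net_a_projected); validate_grn(net_b)
  key_a <- paste(net_a_projected$edges$tf_id,
                 net_a_projected$edges$promoter_id, sep = "\r")
  key_b <- paste(net_b$edges$tf_id, net_b$edges$promoter_id, sep = "\r")
  all_key <- union(key_a, key_b)
  parts <- do.call(rbind, strsplit(all_key, "\r", fixed = TRUE))
  source_flag <- ifelse(all_key %in% key_a,
                        ifelse(all_key %in% key_b, "both", "a_only"),
                        "b_only")
  edges <- data.frame(tf_id = parts[, 1], promoter_id = parts[, 2],
                      provenance = "merged", source = source_flag,
                      stringsAsFactors = FALSE)
  out <- grn(edges, name = name)
  out$edges$source <- source_flag[match(paste(out$edges$tf_id,
                                              out$edges$promoter_id,
                                              sep = "\r"), all_key)]
  attr(out, "source_counts") <- table(out$edges$source)
  out
}
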