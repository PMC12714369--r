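# TF-family over-representation by expected outdegree.
#
# Under a null of regulatory interactions distributed across TFs in
# proportion to family size, a family with m of the network's T TFs is
# expected to emit E = m / T * M of the M edges. The departure of the
# observed family outdegree O from E is scored with a two-cell chi-square
# statistic (family vs all other TFs) on 1 degree of freedom; only this
# construction reproduces published p-values from the printed counts, and
# the single comparison category fixes df = 1.

#' Expected family outdegree under proportional allocation
#'
#' @param members number of TFs in the family.
#' @param total_tfs total TFs in the network (> 0).
#' @param total_edges total edges in the network.
#' @return `members * total_edges / total_tfs`, in edges.
#' @examples
#' expected_outdegree(53, 301, 1625) # 286.13
#' @export
expected_outdegree <- function(members, total_tfs, total_edges) {
  if (!is_count(total_tfs) || total_tfs == 0) {
    stop_domain("total_tfs must be a positive count")
  }
  if (!is_count(members) || members > total_tfs) {
    stop_domain("members must be a count <= total_tfs")
  }
  if (!is_count(total_edges)) stop_domain("total_edges must be a count")
  members * total_edges / total_tfs
}

#' Two-cell chi-square for one family's outdegree
#'
#' Compares the family's observed outgoing-edge count against its expected
#' count, with all remaining edges forming the complementary cell:
#' chi^2 = (O - E)^2 / E + ((T - O) - (T - E))^2 / (T - E), where T is the
#' total edge count. The p-value is the upper tail of the chi-square
#' distribution with 1 degree of freedom, reported in full double
#' precision (published values for strongly over-represented families
#' reach the 1e-59 range).
#'
#' @param observed observed family outdegree (count, 0..total_edges).
#' @param expected expected family outdegree (real, strictly between 0 and
#'   total_edges).
#' @param total_edges total edges in the network.
#' @return A list with elements `chi_square` and `p_value`.
#' @examples
#' family_chi_square(447, expected_outdegree(53, 301, 1625), 1625)
#' @export
family_chi_square <- function(observed, expected, total_edges) {
  if (!is_count(total_edges)) stop_domain("total_edges must be a count")
  if (!is.numeric(expected) || length(expected) != 1 ||
      expected <= 0 || expected >= total_edges) {
    stop_domain("expected must lie strictly between 0 and total_edges")
  }
  if (!is_count(observed) || observed > total_edges) {
    stop_domain("observed must be a count <= total_edges")
  }
  chi <- (observed - expected)^2 / expected +
    ((total_edges - observed) - (total_edges - expected))^2 /
      (total_edges - expected)
  list(chi_square = chi,
       p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE))
}

#' Family-level enrichment table for a network
#'
#' Computes, for every TF family in the network, the observed and expected
#' outdegree, the two-cell chi-square statistic and its p-value, and a
#' significance flag at raw `p < alpha` (matching the convention of
#' reporting raw p-values against 0.05). A Benjamini-Hochberg adjusted
#' column `p_bh` is reported alongside but does not drive the flag.
#' TFs without a family label are pooled into family `"unassigned"`.
#'
#' A family containing every TF in the network has no comparison cell; its
#' statistic and p-value are returned as `NA`.
#'
#' @param net a `grn` object; zero-edge networks yield an empty table.
#' @param alpha significance level for the flag (default 0.05).
#' @return Data frame sorted by p-value then family, with columns
#'   `family`, `members`, `observed`, `expected`, `chi_square`, `p_value`,
#'   `p_bh`, `significant`.
#' @export
family_enrichment_table <- function(net, alpha = 0.05) {
  validate_grn(net)
  if (alpha <= 0 || alpha >= 1) stop_domain("alpha must be in (0, 1)")
  tf_nodes <- net$nodes[role_is_tf(net$nodes$role), , drop = FALSE]
  if (nrow(net$edges) == 0 || nrow(tf_nodes) == 0) {
    return(data.frame(family = character(), members = integer(),
                      observed = integer(), expected = numeric(),
                      chi_square = numeric(), p_value = numeric(),
                      p_bh = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  }
  fam <- ifelse(tf_nodes$family == "", "unassigned", tf_nodes$family)
  total_tfs <- nrow(tf_nodes)
  total_edges <- nrow(net$edges)
  edge_fam <- fam[match(net$edges$tf_id, tf_nodes$node_id)]

  fams <- sort(unique(fam))
  members <- as.integer(table(factor(fam, levels = fams)))
  observed <- as.integer(table(factor(edge_fam, levels = fams)))
  expected <- members * total_edges / total_tfs

  chi <- p <- rep(NA_real_, length(fams))
  ok <- expected > 0 & expected < total_edges
  for (i in which(ok)) {
    res <- family_chi_square(observed[i], expected[i], total_edges)
    chi[i] <- res$chi_square
    p[i] <- res$p_value
  }
  out <- data.frame(family = fams, members = members, observed = observed,
                    expected = expected, chi_square = chi, p_value = p,
                    p_bh = stats::p.adjust(p, method = "BH"),
                    significant = !is.na(p) & p < alpha,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$family), ]
  rownames(out) <- NULL
  out
}
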