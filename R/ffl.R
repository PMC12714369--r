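# Feed-forward loop enumeration and coherent/incoherent classification.
#
# A feed-forward loop (FFL) is an ordered triple (tf1, tf2, target) of
# pairwise-distinct nodes with the three edges tf1 -> tf2, tf1 -> target
# and tf2 -> target all present: a top regulator controls a target both
# directly and through an intermediate TF. With each edge carrying an
# activating (+) or repressing (-) sign, the loop is coherent when the
# sign of the indirect path equals the sign of the direct edge
# (s1 * s2 == s3) and incoherent otherwise, giving four coherent (c1-c4)
# and four incoherent (i1-i4) types under the canonical taxonomy.

# Authoritative sign -> type table, ordering (s1, s2, s3) =
# (tf1->tf2, tf2->target, tf1->target).
FFL_TYPES <- data.frame(
  s1 = c("+", "-", "+", "-", "+", "-", "+", "-"),
  s2 = c("+", "+", "-", "-", "-", "-", "+", "+"),
  s3 = c("+", "-", "-", "+", "+", "-", "-", "+"),
  ffl_type = c("c1", "c2", "c3", "c4", "i1", "i2", "i3", "i4"),
  stringsAsFactors = FALSE
)

#' The eight-type feed-forward loop sign table
#'
#' Returns the authoritative mapping from sign triples
#' `(s1, s2, s3) = (tf1->tf2, tf2->target, tf1->target)` to the four
#' coherent (`c1`-`c4`) and four incoherent (`i1`-`i4`) loop types.
#' Coherent types satisfy `s1 * s2 == s3`.
#'
#' @return Data frame with columns `s1`, `s2`, `s3`, `ffl_type`.
#' @export
ffl_type_table <- function() FFL_TYPES

#' Enumerate feed-forward loops in a network
#'
#' Finds every ordered triple (tf1, tf2, target) of pairwise-distinct
#' nodes such that tf1 -> tf2, tf1 -> target and tf2 -> target are all
#' edges of the network. The enumeration equals a brute-force scan over
#' all ordered node triples; self-binding edges never participate because
#' the three nodes must be distinct. When both tf1 -> tf2 and tf2 -> tf1
#' exist, (tf1, tf2, target) and (tf2, tf1, target) are distinct ordered
#' instances; set `unordered = TRUE` to collapse such mirror pairs to a
#' single canonical instance (lexicographically smallest top regulator).
#'
#' @param net a `grn` object.
#' @param unordered collapse mirror instances sharing the same TF pair and
#'   target (default `FALSE`).
#' @return Data frame with columns `tf1`, `tf2`, `target`, sorted
#'   lexicographically; zero rows when the network has no TF -> TF edges.
#' @export
enumerate_ffls <- function(net, unordered = FALSE) {
  validate_grn(net)
  edges <- net$edges
  out_by_tf <- split(edges$promoter_id, edges$tf_id)
  # candidate tf1 -> tf2 edges: target node must itself regulate something
  tf_edges <- edges[edges$promoter_id %in% names(out_by_tf) &
                      edges$tf_id != edges$promoter_id, , drop = FALSE]
  res <- vector("list", nrow(tf_edges))
  for (i in seq_len(nrow(tf_edges))) {
    tf1 <- tf_edges$tf_id[i]; tf2 <- tf_edges$promoter_id[i]
    common <- intersect(out_by_tf[[tf1]], out_by_tf[[tf2]])
    common <- setdiff(common, c(tf1, tf2))
    if (length(common) > 0) {
      res[[i]] <- data.frame(tf1 = tf1, tf2 = tf2, target = common,
                             stringsAsFactors = FALSE)
    }
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0) {
    return(data.frame(tf1 = character(), tf2 = character(),
                      target = character(), stringsAsFactors = FALSE))
  }
  ffls <- do.call(rbind, res)
  if (unordered) {
    lo <- pmin(ffls$tf1, ffls$tf2)
    hi <- pmax(ffls$tf1, ffls$tf2)
    key <- paste(lo, hi, ffls$target, sep = "\r")
    ffls <- ffls[!duplicated(key), , drop = FALSE]
  }
  ffls <- ffls[order(ffls$tf1, ffls$tf2, ffls$target), , drop = FALSE]
  rownames(ffls) <- NULL
  ffls
}

#' Classify a signed feed-forward loop
#'
#' Maps sign triples to the eight canonical loop types (see
#' [ffl_type_table()]). Any undetermined sign makes the loop
#' `unclassified`. Vectorised over the three arguments.
#'
#' @param s1,s2,s3 signs of the tf1->tf2, tf2->target and tf1->target
#'   edges: `"+"`, `"-"`, or `"undetermined"` (`NA` is treated as
#'   undetermined).
#' @return Character vector of types: `c1`-`c4`, `i1`-`i4` or
#'   `unclassified`.
#' @examples
#' classify_ffl("+", "+", "+")  # "c1"
#' classify_ffl("+", "-", "+")  # "i1"
#' @export
classify_ffl <- function(s1, s2, s3) {
  n <- max(length(s1), length(s2), length(s3))
  s1 <- rep_len(as.character(s1), n)
  s2 <- rep_len(as.character(s2), n)
  s3 <- rep_len(as.character(s3), n)
  ok_tokens <- c("+", "-", "undetermined", NA)
  if (!all(c(s1, s2, s3) %in% ok_tokens)) {
    bad <- setdiff(unique(c(s1, s2, s3)), ok_tokens)
    stop_domain("invalid sign token(s): ", paste(bad, collapse = ", "))
  }
  idx <- match(paste(s1, s2, s3),
               paste(FFL_TYPES$s1, FFL_TYPES$s2, FFL_TYPES$s3))
  type <- FFL_TYPES$ffl_type[idx]
  type[is.na(type)] <- "unclassified"
  type
}

#' Filter and classify feed-forward loops by edge polarity
#'
#' Attaches per-context Gini-correlation signs from a signed network to an
#' enumerated FFL list, retains loops whose three edges all have
#' determined polarity (|GCC| beyond the threshold -- the strictest
#' reading of a correlation-based significance filter), and assigns each
#' retained loop its type.
#'
#' @param snet a `signed_grn` built from the same base network.
#' @param ffls data frame from [enumerate_ffls()].
#' @param context tissue context present in `snet`.
#' @return Data frame with columns `tf1`, `tf2`, `target`, `context`,
#'   `s1`, `s2`, `s3`, `gcc1`, `gcc2`, `gcc3`, `ffl_type`, `retained`;
#'   loops with any undetermined edge have `ffl_type` `"unclassified"` and
#'   `retained` `FALSE`. Per-type counts of retained loops in
#'   `attr(, "type_counts")`.
#' @export
significant_ffls <- function(snet, ffls, context) {
  stopifnot(inherits(snet, "signed_grn"))
  se <- snet$edges[snet$edges$context == context, , drop = FALSE]
  if (nrow(se) == 0) stop_domain("context not in signed network: ", context)
  base_key <- paste(snet$base$edges$tf_id, snet$base$edges$promoter_id)
  for (col in c("tf1", "tf2")) {
    if (!all(paste(ffls[[col]], ffls$target) %in% base_key)) {
      stop_domain("FFL list does not derive from the signed network's base")
    }
  }
  ekey <- paste(se$tf_id, se$promoter_id)
  sign_of <- function(tf, tg) {
    pol <- se$polarity[match(paste(tf, tg), ekey)]
    ifelse(pol == "activating", "+",
           ifelse(pol == "repressing", "-", "undetermined"))
  }
  gcc_of <- function(tf, tg) se$gcc[match(paste(tf, tg), ekey)]
  s1 <- sign_of(ffls$tf1, ffls$tf2)
  s2 <- sign_of(ffls$tf2, ffls$target)
  s3 <- sign_of(ffls$tf1, ffls$target)
  type <- classify_ffl(s1, s2, s3)
  out <- data.frame(ffls[, c("tf1", "tf2", "target")], context = context,
                    s1 = s1, s2 = s2, s3 = s3,
                    gcc1 = gcc_of(ffls$tf1, ffls$tf2),
                    gcc2 = gcc_of(ffls$tf2, ffls$target),
                    gcc3 = gcc_of(ffls$tf1, ffls$target),
                    ffl_type = type,
                    retained = type != "unclassified",
                    stringsAsFactors = FALSE)
  counts <- table(factor(out$ffl_type[out$retained],
                         levels = FFL_TYPES$ffl_type))
  attr(out, "type_counts") <- counts
  out
}
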