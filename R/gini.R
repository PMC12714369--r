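# Gini correlation and activating/repressing edge polarity.
#
# The Gini correlation coefficient (GCC) is an asymmetric rank-weighted
# association measure: the covariance of one variable's values with the
# other variable's ranks, normalised by the same-variable version. It is
# robust for skewed, non-normal expression distributions. Edges whose GCC
# exceeds +threshold are called activating, below -threshold repressing
# (default threshold 0.5, strict comparisons).

#' Gini correlation coefficient
#'
#' Computes `GCC(x; y) = sum_i (2i - n - 1) x_[pi_y(i)] /
#' sum_i (2i - n - 1) x_[pi_x(i)]`, where `pi_y` orders the samples by
#' ascending `y` and `pi_x` by ascending `x`; ties in the ordering variable
#' break by ascending original index (a stable, documented rule). The
#' result lies in `[-1, 1]`, reaching the bounds when `y` is a strictly
#' monotone function of `x`. The measure is asymmetric: `GCC(x; y)` ranks
#' by `y` and weighs values of `x`.
#'
#' @param x numeric vector whose values are weighted (must not be
#'   constant: the denominator would vanish).
#' @param y numeric vector supplying the ranking; same length as `x`,
#'   `n >= 3`.
#' @return A single value in `[-1, 1]`.
#' @examples
#' gini_correlation(c(1, 2, 3, 4, 5), c(2, 4, 6, 8, 10))   #  1
#' gini_correlation(c(1, 2, 3, 4, 5), c(10, 8, 6, 4, 2))   # -1
#' gini_correlation(c(1, 3, 2, 5, 4), 1:5)                 #  0.8
#' @export
gini_correlation <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop_domain("x and y must have equal length")
  if (n < 3) stop_domain("need n >= 3 observations")
  if (anyNA(x) || anyNA(y)) stop_domain("missing values not allowed")
  w <- 2 * seq_len(n) - n - 1
  denom <- sum(w * x[order(x, seq_len(n))])
  if (denom == 0) stop_domain("x is constant: Gini correlation undefined")
  sum(w * x[order(y, seq_len(n))]) / denom
}

#' Assign activating/repressing polarity to network edges
#'
#' For each edge of a PDI network, computes the Gini correlation between
#' the TF's and the target's expression over all samples of one tissue
#' context (every phase, time point and replicate; rank statistics benefit
#' from sample-level n, so replicates are not averaged). Both asymmetric
#' directions are computed: `gcc_tf_ranks` weighs target values by TF
#' ranks, `gcc_target_ranks` weighs TF values by target ranks. The
#' polarity-determining `gcc` is the direction with the larger absolute
#' value (ties favour `gcc_tf_ranks`); both are recorded so either
#' convention can be audited. Polarity is `activating` iff
#' `gcc > threshold`, `repressing` iff `gcc < -threshold`, else
#' `undetermined`. Edges whose TF or target is missing from the matrix or
#' has a constant in-context profile are `undetermined` with reason
#' `missing_gene` or `constant_profile`.
#'
#' @param net a `grn` object.
#' @param expr an `expr_set` containing samples for the context.
#' @param context tissue label (or vector of labels) selecting samples.
#' @param threshold polarity threshold (default 0.5; strict comparisons).
#' @return An object of class `signed_grn`: a list with elements `base`
#'   (the network), `edges` (data frame: tf_id, promoter_id, context,
#'   gcc_tf_ranks, gcc_target_ranks, gcc, polarity, reason) and
#'   `threshold`.
#' @export
sign_edges <- function(net, expr, context, threshold = 0.5) {
  validate_grn(net)
  if (threshold <= 0) stop_domain("threshold must be positive")
  per_context <- lapply(context, function(ctx) {
    keep <- expr$samples$tissue == ctx
    if (!any(keep)) stop_domain("no samples for context ", ctx)
    vals <- expr$values[, keep, drop = FALSE]
    edges <- net$edges
    n_edge <- nrow(edges)
    g1 <- g2 <- gcc <- rep(NA_real_, n_edge)
    polarity <- rep("undetermined", n_edge)
    reason <- rep("", n_edge)
    for (i in seq_len(n_edge)) {
      tf <- edges$tf_id[i]; tg <- edges$promoter_id[i]
      if (!(tf %in% rownames(vals)) || !(tg %in% rownames(vals))) {
        reason[i] <- "missing_gene"
        next
      }
      x_tf <- vals[tf, ]; x_tg <- vals[tg, ]
      if (length(unique(x_tf)) == 1 || length(unique(x_tg)) == 1) {
        reason[i] <- "constant_profile"
        next
      }
      g1[i] <- gini_correlation(x_tg, x_tf)   # target values, TF ranks
      g2[i] <- gini_correlation(x_tf, x_tg)   # TF values, target ranks
      gcc[i] <- if (abs(g2[i]) > abs(g1[i])) g2[i] else g1[i]
      if (gcc[i] > threshold) {
        polarity[i] <- "activating"
      } else if (gcc[i] < -threshold) {
        polarity[i] <- "repressing"
      } else {
        reason[i] <- "below_threshold"
      }
    }
    data.frame(tf_id = edges$tf_id, promoter_id = edges$promoter_id,
               context = ctx, gcc_tf_ranks = g1, gcc_target_ranks = g2,
               gcc = gcc, polarity = polarity, reason = reason,
               stringsAsFactors = FALSE)
  })
  structure(list(base = net,
                 edges = do.call(rbind, per_context),
                 threshold = threshold),
            class = "signed_grn")
}

#' @export
print.signed_grn <- function(x, ...) {
  cat(sprintf("<signed_grn> %s: %d signed edge records, threshold %.2f\n",
              x$base$name, nrow(x$edges), x$threshold))
  print(signed_summary(x)$by_context)
  invisible(x)
}

#' Polarity counts for a signed network
#'
#' @param snet a `signed_grn`.
#' @return A list with `by_context` (data frame: context, activating,
#'   repressing, undetermined) and `by_process` (the same split further
#'   broken down by the target node's functional-module `process`
#'   attribute).
#' @export
signed_summary <- function(snet) {
  stopifnot(inherits(snet, "signed_grn"))
  e <- snet$edges
  tab <- table(context = e$context,
               polarity = factor(e$polarity,
                                 levels = c("activating", "repressing",
                                            "undetermined")))
  by_context <- cbind(data.frame(context = rownames(tab),
                                 stringsAsFactors = FALSE),
                      as.data.frame.matrix(tab))
  rownames(by_context) <- NULL
  process <- snet$base$nodes$process[match(e$promoter_id,
                                           snet$base$nodes$node_id)]
  ptab <- as.data.frame(table(context = e$context, process = process,
                              polarity = e$polarity),
                        stringsAsFactors = FALSE)
  ptab <- ptab[ptab$Freq > 0, ]
  rownames(ptab) <- NULL
  list(by_context = by_context, by_process = ptab)
}
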