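# Shared fixtures and independent oracles, built in code at test time.

# three-edge toy network used across modules
toy_net <- function() {
  suppressMessages(grn(data.frame(tf_id = c("A", "A", "B"),
                                  promoter_id = c("p1", "p2", "p1"),
                                  stringsAsFactors = FALSE),
                       name = "toy"))
}

# Erdos-Renyi-style random directed network; every node may act on both
# sides, so TF->TF edges (and hence FFLs) arise freely
random_grn <- function(n_nodes, p = 0.08) {
  ids <- sprintf("N%02d", seq_len(n_nodes))
  A <- matrix(stats::runif(n_nodes^2) < p, n_nodes, n_nodes)
  idx <- which(A, arr.ind = TRUE)
  if (nrow(idx) == 0) idx <- cbind(1L, 2L)
  suppressMessages(grn(data.frame(tf_id = ids[idx[, 1]],
                                  promoter_id = ids[idx[, 2]],
                                  stringsAsFactors = FALSE)))
}

# independent FFL oracle: vectorised scan over all ordered node triples
brute_force_ffls <- function(net) {
  ids <- net$nodes$node_id
  n <- length(ids)
  A <- matrix(FALSE, n, n)
  A[cbind(match(net$edges$tf_id, ids),
          match(net$edges$promoter_id, ids))] <- TRUE
  tr <- expand.grid(i = seq_len(n), j = seq_len(n), k = seq_len(n))
  tr <- tr[tr$i != tr$j & tr$i != tr$k & tr$j != tr$k, ]
  keep <- A[cbind(tr$i, tr$j)] & A[cbind(tr$i, tr$k)] & A[cbind(tr$j, tr$k)]
  out <- data.frame(tf1 = ids[tr$i[keep]], tf2 = ids[tr$j[keep]],
                    target = ids[tr$k[keep]], stringsAsFactors = FALSE)
  out[order(out$tf1, out$tf2, out$target), ]
}

# independent GCC oracle: covariance of values with the partner's ranks,
# ties broken by original index
gcc_oracle <- function(x, y) {
  n <- length(x)
  ry <- integer(n); ry[order(y, seq_len(n))] <- seq_len(n)
  rx <- integer(n); rx[order(x, seq_len(n))] <- seq_len(n)
  stats::cov(x, ry) / stats::cov(x, rx)
}

# minimal expression set over one tissue from a genes-x-values matrix
# (columns become replicates of successive time points)
simple_expr <- function(values, times, tissue = "leaf") {
  samples <- data.frame(
    sample_id = sprintf("%s_s%d", tissue, seq_len(ncol(values))),
    tissue = tissue,
    phase = ifelse(times == 0, "baseline",
                   ifelse(times <= 24, "deprivation", "recovery")),
    time_h = times,
    replicate = stats::ave(seq_along(times), times, FUN = seq_along),
    stringsAsFactors = FALSE)
  colnames(values) <- samples$sample_id
  expression_set(values, samples)
}

# hand-assembled signed network (for summary/classification tests that
# need exact GCC values)
manual_signed <- function(net, gcc, context = "leaf", threshold = 0.5) {
  polarity <- ifelse(is.na(gcc), "undetermined",
                     ifelse(gcc > threshold, "activating",
                            ifelse(gcc < -threshold, "repressing",
                                   "undetermined")))
  structure(list(
    base = net,
    edges = data.frame(tf_id = net$edges$tf_id,
                       promoter_id = net$edges$promoter_id,
                       context = context, gcc_tf_ranks = gcc,
                       gcc_target_ranks = gcc, gcc = gcc,
                       polarity = polarity,
                       reason = ifelse(polarity == "undetermined",
                                       "below_threshold", ""),
                       stringsAsFactors = FALSE),
    threshold = threshold), class = "signed_grn")
}

# the 100-edge single-regulator polarity benchmark: 50 activating and 50
# repressing planted TF -> promoter relationships
polarity_benchmark <- function(seed) {
  edges <- data.frame(tf_id = sprintf("TF%03d", 1:100),
                      promoter_id = sprintf("PR%03d", 1:100),
                      stringsAsFactors = FALSE)
  net <- suppressMessages(grn(edges, name = "polarity_benchmark"))
  truth <- structure(list(
    edge_signs = data.frame(edges, sign = rep(c("+", "-"), each = 50),
                            stringsAsFactors = FALSE),
    seed = seed, params = list()), class = "synthetic_truth")
  list(network = net, truth = truth)
}
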