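# Seeded synthetic-data generators with known ground truth.
#
# Every generator is a deterministic function of its parameters and seed,
# so parameter-recovery tests can compare pipeline output against planted
# truth without external downloads. Defaults mirror a two-tissue nutrient
# deprivation/recovery time-course design: tissues leaf and root, time
# points 0, 0.5, 3, 24 h (deprivation) and 24.5, 48 h (recovery), three
# replicates.

#' Generate a hub-skewed PDI network with planted edge signs
#'
#' Draws a directed TF -> promoter network whose outdegree distribution is
#' a two-component mixture: a `hub_fraction` of TFs draw their outdegree
#' at five times the mean of the rest, giving the heavy-tailed
#' few-hubs/many-specific-TFs shape typical of eY1H screens.
#' `n_dual_nodes` of the TFs also appear as promoters (their own promoter
#' is in the network), which makes TF -> TF edges -- and hence
#' feed-forward loops -- possible. Each TF is assigned to one of
#' `families` families with Zipf-skewed probabilities. Every edge is
#' planted activating (`+`, probability 0.6, activators being the more
#' common regulatory mode) or repressing (`-`).
#'
#' @param n_tfs,n_promoters,n_dual_nodes node counts
#'   (`n_dual_nodes <= n_tfs`).
#' @param mean_outdegree mean TF outdegree for non-hub TFs; must not
#'   exceed the promoter pool size.
#' @param hub_fraction fraction of TFs drawn as hubs, in `[0, 1]`.
#' @param families number of TF families.
#' @param seed RNG seed.
#' @return A list with elements `network` (a `grn`) and `truth` (class
#'   `synthetic_truth`: `edge_signs` data frame, `planted_ffls` data frame
#'   with the type implied by the planted signs, `seed`, `params`).
#' @export
generate_network <- function(n_tfs = 100, n_promoters = 50,
                             n_dual_nodes = 20, mean_outdegree = 5,
                             hub_fraction = 0.1, families = 8, seed = 1) {
  if (n_tfs < 1 || n_promoters < 1 || families < 1) {
    stop_domain("counts must be >= 1")
  }
  if (n_dual_nodes > n_tfs) stop_domain("n_dual_nodes must be <= n_tfs")
  if (hub_fraction < 0 || hub_fraction > 1) {
    stop_domain("hub_fraction must be in [0, 1]")
  }
  tf_ids <- sprintf("TF%03d", seq_len(n_tfs))
  pr_ids <- sprintf("PR%03d", seq_len(n_promoters))
  set.seed(seed)
  dual_ids <- if (n_dual_nodes > 0) sample(tf_ids, n_dual_nodes) else character()
  pool <- c(pr_ids, dual_ids)
  if (mean_outdegree > length(pool)) {
    stop_domain("mean_outdegree exceeds promoter pool size")
  }
  n_hubs <- round(hub_fraction * n_tfs)
  hubs <- if (n_hubs > 0) sample(tf_ids, n_hubs) else character()
  lambda <- ifelse(tf_ids %in% hubs, 5 * mean_outdegree, mean_outdegree)
  outdeg <- pmin(pmax(stats::rpois(n_tfs, lambda), 1L), length(pool))
  edges <- do.call(rbind, lapply(seq_len(n_tfs), function(i) {
    data.frame(tf_id = tf_ids[i],
               promoter_id = sample(pool, outdeg[i]),
               stringsAsFactors = FALSE)
  }))
  # guarantee each dual TF is regulated so it can sit inside an FFL
  for (d in dual_ids) {
    if (!d %in% edges$promoter_id) {
      regulator <- sample(setdiff(tf_ids, d), 1)
      edges <- rbind(edges, data.frame(tf_id = regulator, promoter_id = d,
                                       stringsAsFactors = FALSE))
    }
  }
  fam_labels <- sprintf("F%02d", seq_len(families))
  fam_prob <- (1 / seq_len(families)) / sum(1 / seq_len(families))
  node_attrs <- data.frame(
    node_id = tf_ids,
    family = sample(fam_labels, n_tfs, replace = TRUE, prob = fam_prob),
    stringsAsFactors = FALSE)
  net <- suppressMessages(
    grn(edges, node_attrs = node_attrs, name = "synthetic", species = "synthA"))
  signs <- sample(c("+", "-"), nrow(net$edges), replace = TRUE,
                  prob = c(0.6, 0.4))
  edge_signs <- data.frame(tf_id = net$edges$tf_id,
                           promoter_id = net$edges$promoter_id,
                           sign = signs, stringsAsFactors = FALSE)
  ffls <- enumerate_ffls(net)
  if (nrow(ffls) > 0) {
    skey <- paste(edge_signs$tf_id, edge_signs$promoter_id)
    sign_of <- function(tf, tg) edge_signs$sign[match(paste(tf, tg), skey)]
    ffls$s1 <- sign_of(ffls$tf1, ffls$tf2)
    ffls$s2 <- sign_of(ffls$tf2, ffls$target)
    ffls$s3 <- sign_of(ffls$tf1, ffls$target)
    ffls$ffl_type <- classify_ffl(ffls$s1, ffls$s2, ffls$s3)
  }
  truth <- structure(list(edge_signs = edge_signs, planted_ffls = ffls,
                          seed = seed,
                          params = list(n_tfs = n_tfs,
                                        n_promoters = n_promoters,
                                        n_dual_nodes = n_dual_nodes,
                                        mean_outdegree = mean_outdegree,
                                        hub_fraction = hub_fraction,
                                        families = families)),
                     class = "synthetic_truth")
  list(network = net, truth = truth)
}

# smooth standardised profile over T points: random combination of an
# orthonormal polynomial basis (equal-weight coefficients, so the
# effective dimension -- and hence the chance correlation between
# independent profiles -- scales with the density of the time grid)
#' @noRd
smooth_profile <- function(n_points) {
  s <- seq(0, 1, length.out = n_points)
  k <- min(n_points - 1L, 12L)
  z <- as.numeric(stats::poly(s, k) %*% stats::rnorm(k))
  if (stats::sd(z) < 1e-8) z <- z + s  # degenerate draw: fall back to a ramp
  as.numeric(scale(z))
}

#' Generate a TPM-like expression matrix with planted regulation
#'
#' Builds per-tissue time courses in which every planted TF -> target
#' relationship is monotone with the planted sign. Unregulated TFs follow
#' random smooth time courses. A regulated node's profile is the weighted
#' sum over its regulators of `sign * weight * profile(TF)` (weights
#' log-normal, link monotone increasing); regulated TFs additionally keep
#' a 50% intrinsic component, reflecting upstream inputs outside the
#' assayed network, while pure targets are fully determined by their
#' regulators plus noise. Replicates add iid Gaussian noise of standard
#' deviation `noise_sigma` on the standardised profile scale. Profiles are
#' shifted per gene to be positive (TPM-like); any value still negative
#' after noise is clipped at 0 and the clip count recorded.
#'
#' Targets bound by regulators of mixed planted sign partially cancel
#' their own signal; their ids are flagged so recovery tests can condition
#' on single-sign regulation. Edges inside regulatory cycles (where a
#' regulator's profile could not be finalised first) are flagged likewise.
#'
#' @param net a `grn` from [generate_network()].
#' @param truth the matching `synthetic_truth`.
#' @param tissues character vector of tissue labels.
#' @param time_points hours; `0` is baseline, `(0, 24]` deprivation,
#'   `> 24` recovery.
#' @param n_replicates replicates per (tissue, time), `>= 1`.
#' @param noise_sigma replicate noise sd on the standardised scale.
#' @param seed RNG seed.
#' @return An `expr_set` over all network nodes. Generator bookkeeping
#'   (edge weights, `mixed_sign_targets`, `cycle_edges`, `n_clipped`) is
#'   stored in `attr(, "generator")`.
#' @export
generate_expression <- function(net, truth, tissues = c("leaf", "root"),
                                time_points = c(0, 0.5, 3, 24, 24.5, 48),
                                n_replicates = 3, noise_sigma = 0.05,
                                seed = 1) {
  validate_grn(net)
  stopifnot(inherits(truth, "synthetic_truth"))
  if (n_replicates < 1) stop_domain("n_replicates must be >= 1")
  set.seed(seed)
  edges <- merge(net$edges, truth$edge_signs,
                 by = c("tf_id", "promoter_id"), sort = FALSE)
  ids <- net$nodes$node_id
  n_t <- length(time_points)
  weights <- stats::rlnorm(nrow(edges), meanlog = 0, sdlog = 0.35)
  sgn <- ifelse(edges$sign == "+", 1, -1)
  regs_of <- split(seq_len(nrow(edges)), edges$promoter_id)
  is_tf_capable <- role_is_tf(net$nodes$role)
  names(is_tf_capable) <- ids

  mixed <- vapply(regs_of, function(ix) {
    length(unique(sgn[ix])) > 1
  }, logical(1))
  mixed_sign_targets <- names(mixed)[mixed]

  cycle_edges <- integer(0)
  profiles <- vector("list", length(tissues))
  names(profiles) <- tissues
  for (tis in tissues) {
    intrinsic <- matrix(NA_real_, length(ids), n_t, dimnames = list(ids, NULL))
    for (g in ids) intrinsic[g, ] <- smooth_profile(n_t)
    expressed <- matrix(NA_real_, length(ids), n_t, dimnames = list(ids, NULL))
    free_nodes <- setdiff(ids, names(regs_of))
    expressed[free_nodes, ] <- intrinsic[free_nodes, ]
    pending <- setdiff(ids, free_nodes)
    repeat {
      ready <- pending[vapply(pending, function(g) {
        all(edges$tf_id[regs_of[[g]]] %in%
              ids[!is.na(expressed[, 1])])
      }, logical(1))]
      if (length(ready) == 0) break
      for (g in ready) {
        ix <- regs_of[[g]]
        regsum <- colSums(matrix(sgn[ix] * weights[ix], length(ix), n_t) *
                            expressed[edges$tf_id[ix], , drop = FALSE])
        regsum <- as.numeric(scale(regsum))
        if (anyNA(regsum)) regsum <- rep(0, n_t)
        expressed[g, ] <- if (is_tf_capable[g]) {
          as.numeric(scale(0.5 * intrinsic[g, ] + 0.5 * regsum))
        } else {
          regsum
        }
      }
      pending <- setdiff(pending, ready)
    }
    # cycles: finalise remaining nodes using intrinsic stand-ins upstream
    for (g in sort(pending)) {
      ix <- regs_of[[g]]
      up <- expressed[edges$tf_id[ix], , drop = FALSE]
      for (j in seq_along(ix)) {
        if (anyNA(up[j, ])) {
          up[j, ] <- intrinsic[edges$tf_id[ix[j]], ]
          cycle_edges <- union(cycle_edges, ix[j])
        }
      }
      regsum <- as.numeric(scale(colSums(
        matrix(sgn[ix] * weights[ix], length(ix), n_t) * up)))
      if (anyNA(regsum)) regsum <- rep(0, n_t)
      expressed[g, ] <- if (is_tf_capable[g]) {
        as.numeric(scale(0.5 * intrinsic[g, ] + 0.5 * regsum))
      } else {
        regsum
      }
    }
    profiles[[tis]] <- expressed
  }

  phase <- ifelse(time_points == 0, "baseline",
                  ifelse(time_points <= 24, "deprivation", "recovery"))
  samples <- expand.grid(replicate = seq_len(n_replicates),
                         time_i = seq_len(n_t), tissue = tissues,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = sprintf("%s_t%g_r%d", samples$tissue,
                        time_points[samples$time_i], samples$replicate),
    tissue = samples$tissue, phase = phase[samples$time_i],
    time_h = time_points[samples$time_i], replicate = samples$replicate,
    stringsAsFactors = FALSE)

  values <- matrix(NA_real_, length(ids), nrow(samples),
                   dimnames = list(ids, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    ti <- match(samples$time_h[j], time_points)
    values[, j] <- profiles[[samples$tissue[j]]][, ti]
  }
  # shift each gene positive before noise, TPM-like; clip stragglers at 0
  shift <- 3 * noise_sigma + 0.1 - apply(values, 1, min)
  values <- values + shift
  values <- values + stats::rnorm(length(values), sd = noise_sigma)
  n_clipped <- sum(values < 0)
  values[values < 0] <- 0

  expr <- expression_set(values, samples)
  attr(expr, "generator") <- list(
    weights = data.frame(edges[, c("tf_id", "promoter_id", "sign")],
                         weight = weights, stringsAsFactors = FALSE),
    mixed_sign_targets = mixed_sign_targets,
    cycle_edges = edges[cycle_edges, c("tf_id", "promoter_id")],
    noise_sigma = noise_sigma, seed = seed, n_clipped = n_clipped,
    shift = shift)
  expr
}

#' Generate a planted feed-forward-loop benchmark network
#'
#' Builds a network of `n_loops` structurally disjoint feed-forward loops
#' (tf1 -> tf2, tf1 -> target, tf2 -> target; distinct nodes per loop,
#' `2 * n_loops` TFs in total) with a uniformly random planted sign on
#' every edge, covering all eight loop types. Because loops share no
#' nodes, each loop's signal is confounded only by its own intermediate
#' TF, which makes the construction a separable benchmark for end-to-end
#' type recovery (generate -> sign -> enumerate -> classify).
#'
#' Incoherent loops attenuate their own direct-edge signal -- the indirect
#' path opposes it by definition -- so under observational co-expression a
#' fraction of loops is expected to fall below the polarity threshold and
#' come back unclassified; recovery is therefore assessed over
#' classifiable loops.
#'
#' @param n_loops number of planted loops.
#' @param seed RNG seed.
#' @return A list with elements `network` (a `grn`) and `truth` (a
#'   `synthetic_truth` whose `planted_ffls` carries the sign-implied type
#'   per loop).
#' @export
generate_ffl_benchmark <- function(n_loops = 50, seed = 1) {
  if (n_loops < 1) stop_domain("n_loops must be >= 1")
  set.seed(seed)
  tf1 <- sprintf("TFA%03d", seq_len(n_loops))
  tf2 <- sprintf("TFB%03d", seq_len(n_loops))
  tg <- sprintf("PRT%03d", seq_len(n_loops))
  edges <- rbind(
    data.frame(tf_id = tf1, promoter_id = tf2, stringsAsFactors = FALSE),
    data.frame(tf_id = tf1, promoter_id = tg, stringsAsFactors = FALSE),
    data.frame(tf_id = tf2, promoter_id = tg, stringsAsFactors = FALSE))
  net <- grn(edges, name = "ffl_benchmark", species = "synthA")
  signs <- sample(c("+", "-"), nrow(edges), replace = TRUE)
  edge_signs <- data.frame(edges, sign = signs, stringsAsFactors = FALSE)
  planted <- data.frame(
    tf1 = tf1, tf2 = tf2, target = tg,
    s1 = signs[seq_len(n_loops)],
    s2 = signs[2 * n_loops + seq_len(n_loops)],
    s3 = signs[n_loops + seq_len(n_loops)],
    stringsAsFactors = FALSE)
  planted$ffl_type <- classify_ffl(planted$s1, planted$s2, planted$s3)
  truth <- structure(list(edge_signs = edge_signs, planted_ffls = planted,
                          seed = seed, params = list(n_loops = n_loops)),
                     class = "synthetic_truth")
  list(network = net, truth = truth)
}

#' Generate a DEG table with planted status rates
#'
#' For every gene x tissue x time combination, samples a status (`up` with
#' probability `frac_up`, `down` with `frac_down`, else `not_de`) and
#' draws (log2fc, padj) values consistent with the status under the
#' strict thresholds padj < 0.05, |log2fc| > 1: up draws log2fc from
#' U(1.1, 4) and padj from U(0, 0.049), down mirrors it, and not_de draws
#' log2fc from U(-0.9, 0.9) with padj from U(0, 1).
#'
#' @param net a `grn`; one record per node per context.
#' @param tissues,time_points contexts to cover.
#' @param frac_up,frac_down planted rates, `frac_up + frac_down <= 1`.
#' @param seed RNG seed.
#' @return Data frame with columns `gene_id`, `tissue`, `time_h`, `phase`,
#'   `log2fc`, `padj`, `status`.
#' @export
generate_deg_table <- function(net, tissues = c("leaf", "root"),
                               time_points = c(0.5, 3, 24, 24.5, 48),
                               frac_up = 0.1, frac_down = 0.1, seed = 1) {
  validate_grn(net)
  if (frac_up + frac_down > 1) stop_domain("frac_up + frac_down must be <= 1")
  set.seed(seed)
  grid <- expand.grid(gene_id = net$nodes$node_id, tissue = tissues,
                      time_h = time_points, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  n <- nrow(grid)
  u <- stats::runif(n)
  status <- ifelse(u < frac_up, "up",
                   ifelse(u < frac_up + frac_down, "down", "not_de"))
  log2fc <- numeric(n); padj <- numeric(n)
  up <- status == "up"; dn <- status == "down"; nd <- status == "not_de"
  log2fc[up] <- stats::runif(sum(up), 1.1, 4)
  padj[up] <- stats::runif(sum(up), 0, 0.049)
  log2fc[dn] <- stats::runif(sum(dn), -4, -1.1)
  padj[dn] <- stats::runif(sum(dn), 0, 0.049)
  log2fc[nd] <- stats::runif(sum(nd), -0.9, 0.9)
  padj[nd] <- stats::runif(sum(nd), 0, 1)
  data.frame(grid,
             phase = ifelse(grid$time_h <= 24, "deprivation", "recovery"),
             log2fc = log2fc, padj = padj, status = status,
             stringsAsFactors = FALSE)
}

#' Generate a partner network and ortholog map with planted conservation
#'
#' Mints a species-B ortholog for every node of `net_a` (with an extra
#' paralog at rate `one2many_rate`, relation `one2many`), copies each A
#' edge into B independently with probability `conservation_fraction`
#' (through the primary ortholog of each endpoint), and adds B-only noise
#' edges drawn to avoid every ortholog image of an A edge, so the planted
#' conserved set is exactly what [conserved_edges()] should find. All B
#' orthologs are present as nodes of the partner network, so every A edge
#' is tested.
#'
#' @param net_a a `grn` in species A.
#' @param conservation_fraction per-edge copy probability, in `[0, 1]`.
#' @param one2many_rate paralog-minting rate, in `[0, 1]`.
#' @param noise_edge_fraction B-only noise edges as a fraction of A's edge
#'   count.
#' @param seed RNG seed.
#' @return A list with elements `net_b` (a `grn`), `omap` (an
#'   `ortholog_map`) and `truth` (a `synthetic_truth` whose
#'   `planted_conserved` lists the copied A edges).
#' @export
generate_ortholog_pair <- function(net_a, conservation_fraction = 0.3,
                                   one2many_rate = 0.1,
                                   noise_edge_fraction = 0.2, seed = 1) {
  validate_grn(net_a)
  if (conservation_fraction < 0 || conservation_fraction > 1 ||
      one2many_rate < 0 || one2many_rate > 1) {
    stop_domain("rates must be in [0, 1]")
  }
  set.seed(seed)
  ids <- net_a$nodes$node_id
  primary <- paste0("b_", ids)
  extra <- stats::runif(length(ids)) < one2many_rate
  pairs <- data.frame(gene_a = ids, gene_b = primary,
                      relation = ifelse(extra, "one2many", "one2one"),
                      syntenic = TRUE, stringsAsFactors = FALSE)
  if (any(extra)) {
    pairs <- rbind(pairs, data.frame(gene_a = ids[extra],
                                     gene_b = paste0(primary[extra], "_2"),
                                     relation = "one2many", syntenic = TRUE,
                                     stringsAsFactors = FALSE))
  }
  omap <- ortholog_map(pairs, species_a = unique(net_a$nodes$species)[1],
                       species_b = "synthB")

  keep <- stats::runif(nrow(net_a$edges)) < conservation_fraction
  planted <- net_a$edges[keep, c("tf_id", "promoter_id"), drop = FALSE]
  b_edges <- data.frame(tf_id = paste0("b_", planted$tf_id),
                        promoter_id = paste0("b_", planted$promoter_id),
                        stringsAsFactors = FALSE)

  # noise edges must not coincide with any ortholog image of an A edge
  lut <- split(pairs$gene_b, pairs$gene_a)
  forbidden <- unlist(lapply(seq_len(nrow(net_a$edges)), function(i) {
    tfs <- lut[[net_a$edges$tf_id[i]]]
    prs <- lut[[net_a$edges$promoter_id[i]]]
    paste(rep(tfs, each = length(prs)), prs, sep = "\r")
  }))
  role_a <- net_a$nodes$role
  b_tf_pool <- paste0("b_", ids[role_is_tf(role_a)])
  b_pr_pool <- paste0("b_", ids[role_is_promoter(role_a)])
  n_noise <- round(noise_edge_fraction * nrow(net_a$edges))
  noise <- data.frame(tf_id = character(), promoter_id = character(),
                      stringsAsFactors = FALSE)
  tries <- 0
  while (nrow(noise) < n_noise && tries < 50) {
    cand <- data.frame(tf_id = sample(b_tf_pool, n_noise, replace = TRUE),
                       promoter_id = sample(b_pr_pool, n_noise, replace = TRUE),
                       stringsAsFactors = FALSE)
    key <- paste(cand$tf_id, cand$promoter_id, sep = "\r")
    ok <- !(key %in% forbidden) & !duplicated(key) &
      !(key %in% paste(noise$tf_id, noise$promoter_id, sep = "\r")) &
      !(key %in% paste(b_edges$tf_id, b_edges$promoter_id, sep = "\r"))
    noise <- rbind(noise, cand[ok, , drop = FALSE])
    tries <- tries + 1
  }
  noise <- utils::head(noise, n_noise)

  all_edges <- rbind(b_edges, noise)
  if (nrow(all_edges) == 0) {
    # degenerate but legal: fraction 0 with no noise; keep one placeholder
    # edge-free network is not representable, so reuse a single noise draw
    all_edges <- data.frame(tf_id = b_tf_pool[1], promoter_id = b_pr_pool[1],
                            stringsAsFactors = FALSE)
    noise <- all_edges
  }
  net_b <- suppressMessages(grn(all_edges, name = "synthetic_b",
                                species = "synthB"))
  # include every minted ortholog as a node so all A edges are assayable
  missing_ids <- setdiff(pairs$gene_b, net_b$nodes$node_id)
  if (length(missing_ids) > 0) {
    src <- sub("_2$", "", sub("^b_", "", missing_ids))
    net_b$nodes <- rbind(net_b$nodes, data.frame(
      node_id = missing_ids, display_name = missing_ids,
      role = role_a[match(src, ids)], family = "", species = "synthB",
      process = "", stringsAsFactors = FALSE))
    net_b$nodes$family[!role_is_tf(net_b$nodes$role)] <- ""
  }
  validate_grn(net_b)
  truth <- structure(list(planted_conserved = planted,
                          noise_edges = noise, seed = seed,
                          params = list(
                            conservation_fraction = conservation_fraction,
                            one2many_rate = one2many_rate,
                            noise_edge_fraction = noise_edge_fraction)),
                     class = "synthetic_truth")
  list(net_b = net_b, omap = omap, truth = truth)
}
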