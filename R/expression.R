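# Expression data model, DEG overlay, tissue specificity and temporal
# clustering.
#
# Expression is stored as a genes x samples matrix of TPM values with a
# sample-metadata table describing tissue, experimental phase (baseline /
# deprivation / recovery), time in hours and replicate. The overlay maps a
# table of differential-expression calls onto network nodes; temporal
# profiles are clustered with k-means on z-scored mean time courses.

PHASE_LEVELS <- c("baseline", "deprivation", "recovery")

#' Construct an expression set
#'
#' @param values numeric genes x samples matrix of TPM values (non-negative);
#'   row names are gene identifiers.
#' @param samples data frame with columns `sample_id`, `tissue`, `phase`
#'   (one of baseline/deprivation/recovery), `time_h`, `replicate`; one row
#'   per column of `values`, in the same order, with
#'   (tissue, phase, time_h, replicate) unique and recovery samples at
#'   `time_h > 24`.
#' @return An object of class `expr_set`: a list with elements `values` and
#'   `samples`. Genes whose row is all zero are retained and their ids
#'   recorded in `attr(, "all_zero_genes")`.
#' @export
expression_set <- function(values, samples) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_config("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values))) stop_config("`values` needs gene row names")
  req <- c("sample_id", "tissue", "phase", "time_h", "replicate")
  missing_cols <- setdiff(req, names(samples))
  if (length(missing_cols) > 0) {
    stop_config("sample metadata missing columns: ",
                paste(missing_cols, collapse = ", "))
  }
  if (nrow(samples) != ncol(values)) {
    stop_config("metadata rows (", nrow(samples),
                ") do not match expression columns (", ncol(values), ")")
  }
  if (!is.null(colnames(values)) &&
      !identical(colnames(values), as.character(samples$sample_id))) {
    bad <- colnames(values)[colnames(values) != as.character(samples$sample_id)]
    stop_config("sample columns do not match metadata sample_ids: ",
                paste(utils::head(bad, 5), collapse = ", "))
  }
  colnames(values) <- samples$sample_id
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stop_domain("negative expression value at gene ",
                rownames(values)[neg[1, 1]], ", sample ",
                colnames(values)[neg[1, 2]])
  }
  if (!all(samples$phase %in% PHASE_LEVELS)) {
    stop_config("phase must be one of: ", paste(PHASE_LEVELS, collapse = ", "))
  }
  key <- paste(samples$tissue, samples$phase, samples$time_h,
               samples$replicate)
  if (anyDuplicated(key)) {
    stop_config("duplicate (tissue, phase, time_h, replicate) combination")
  }
  if (any(samples$phase == "recovery" & samples$time_h <= 24)) {
    stop_config("recovery samples must have time_h > 24")
  }
  all_zero <- rownames(values)[rowSums(values) == 0]
  structure(list(values = values, samples = samples),
            class = "expr_set", all_zero_genes = all_zero)
}

#' @export
print.expr_set <- function(x, ...) {
  cat(sprintf("<expr_set> %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$samples$tissue), collapse = ", ")))
  invisible(x)
}

#' Read an expression matrix and its sample metadata from TSV
#'
#' The matrix file holds genes in rows (first column = gene id) and samples
#' in columns; the metadata file holds one row per sample. Sample columns
#' must match metadata `sample_id`s exactly and in order.
#'
#' @param matrix_path path to the genes x samples TPM table.
#' @param meta_path path to the sample-metadata table.
#' @return An `expr_set`.
#' @export
read_expression <- function(matrix_path, meta_path) {
  mat_df <- read_tsv_file(matrix_path)
  meta <- read_tsv_file(meta_path)
  genes <- as.character(mat_df[[1]])
  values <- as.matrix(mat_df[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- genes
  if (!identical(colnames(values), as.character(meta$sample_id))) {
    offenders <- union(setdiff(colnames(values), meta$sample_id),
                       setdiff(meta$sample_id, colnames(values)))
    stop_config("expression columns and metadata sample_ids disagree: ",
                paste(utils::head(offenders, 5), collapse = ", "))
  }
  expression_set(values, meta)
}

#' Write an expression set to TSV
#'
#' Inverse of [read_expression()]; round-trips values and metadata.
#'
#' @param expr an `expr_set`.
#' @param matrix_path,meta_path output paths.
#' @return `matrix_path`, invisibly.
#' @export
write_expression <- function(expr, matrix_path, meta_path) {
  df <- data.frame(gene_id = rownames(expr$values), expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_file(df, matrix_path)
  write_tsv_file(expr$samples, meta_path)
  invisible(matrix_path)
}

#' Differential-expression status from effect size and adjusted p
#'
#' A gene is `up` iff `padj < padj_max` and `log2fc > lfc_min`, `down` iff
#' `padj < padj_max` and `log2fc < -lfc_min`, otherwise `not_de`.
#' Inequalities are strict, so boundary values (padj exactly 0.05, log2fc
#' exactly 1) are `not_de`. The down threshold mirrors the up threshold:
#' only a symmetric reading is consistent with reporting down-regulated
#' genes under a "log2FC greater than 1" rule.
#'
#' @param log2fc,padj numeric vectors (recycled to common length).
#' @param padj_max,lfc_min thresholds (defaults 0.05 and 1).
#' @return Character vector of `"up"`, `"down"`, `"not_de"`; `NA` inputs
#'   give `"not_de"`.
#' @export
deg_status <- function(log2fc, padj, padj_max = 0.05, lfc_min = 1) {
  status <- rep("not_de", length(log2fc))
  sig <- !is.na(padj) & !is.na(log2fc) & padj < padj_max
  status[sig & log2fc > lfc_min] <- "up"
  status[sig & log2fc < -lfc_min] <- "down"
  status
}

#' Overlay DEG calls onto network nodes
#'
#' Labels every node of a network `up`, `down`, `not_de` or `no_data` for
#' one (tissue, time) context, and summarises counts per functional module
#' (the node `process` attribute).
#'
#' @param net a `grn` object.
#' @param degs data frame with columns `gene_id`, `tissue`, `time_h`,
#'   `log2fc`, `padj` (a `phase` column is carried through if present).
#' @param tissue,time_h context selectors.
#' @param padj_max,lfc_min status thresholds, see [deg_status()].
#' @return Data frame with columns `node_id`, `status`, `log2fc`, `padj`,
#'   `process`; per-process status counts in `attr(, "module_summary")`.
#' @export
overlay_degs <- function(net, degs, tissue, time_h,
                         padj_max = 0.05, lfc_min = 1) {
  validate_grn(net)
  req <- c("gene_id", "tissue", "time_h", "log2fc", "padj")
  missing_cols <- setdiff(req, names(degs))
  if (length(missing_cols) > 0) {
    stop_config("DEG table missing columns: ",
                paste(missing_cols, collapse = ", "))
  }
  sel <- degs[degs$tissue == tissue & degs$time_h == time_h, , drop = FALSE]
  idx <- match(net$nodes$node_id, sel$gene_id)
  log2fc <- sel$log2fc[idx]
  padj <- sel$padj[idx]
  status <- deg_status(log2fc, padj, padj_max, lfc_min)
  status[is.na(idx)] <- "no_data"
  out <- data.frame(node_id = net$nodes$node_id, status = status,
                    log2fc = log2fc, padj = padj,
                    process = net$nodes$process, stringsAsFactors = FALSE)
  summ <- as.data.frame(table(process = out$process, status = out$status),
                        stringsAsFactors = FALSE)
  summ <- summ[summ$Freq > 0, ]
  rownames(summ) <- NULL
  attr(out, "module_summary") <- summ
  out
}

#' Gini index of tissue specificity for one gene
#'
#' The classical Gini inequality index over per-group mean TPM:
#' `G = sum_ij |m_i - m_j| / (2 g^2 mbar)` for `g` groups with means `m_i`
#' and grand mean `mbar`. Zero means equal expression in all groups; the
#' maximum `(g - 1) / g` is reached when a single group carries all
#' expression. Returns 0 by convention when every group mean is 0. The
#' index is invariant to rescaling all values by a positive constant.
#'
#' @param expr an `expr_set`.
#' @param gene_id gene to score.
#' @param group_by metadata column defining the groups (default
#'   `"tissue"`); at least 2 groups are required.
#' @return A value in `[0, 1)`.
#' @export
tissue_specificity_gini <- function(expr, gene_id, group_by = "tissue") {
  if (!gene_id %in% rownames(expr$values)) {
    stop_domain("gene not found: ", gene_id)
  }
  groups <- expr$samples[[group_by]]
  if (length(unique(groups)) < 2) stop_domain("need >= 2 groups")
  m <- tapply(expr$values[gene_id, ], groups, mean)
  g <- length(m)
  if (all(m == 0)) return(0)
  sum(abs(outer(m, m, "-"))) / (2 * g^2 * mean(m))
}

#' Cluster temporal expression profiles
#'
#' Averages replicates per (tissue, phase, time) column group, z-scores
#' each gene's mean profile, and partitions genes with k-means (Euclidean
#' distance, `nstart` restarts, seeded). Genes with constant profiles
#' cannot be z-scored and are excluded; their ids are reported.
#'
#' @param expr an `expr_set`.
#' @param k number of clusters (default 10).
#' @param seed RNG seed; fixed seed gives bit-reproducible assignments.
#' @param tissue optional tissue restriction.
#' @param nstart k-means restarts (default 10).
#' @return Data frame with columns `gene_id`, `cluster_id` (integers
#'   `0..k-1`); cluster centroid profiles in `attr(, "centroids")` and
#'   excluded genes in `attr(, "skipped")`.
#' @export
cluster_profiles <- function(expr, k = 10, seed = 1, tissue = NULL,
                             nstart = 10) {
  if (!is_count(k) || k < 2) stop_domain("k must be an integer >= 2")
  samples <- expr$samples
  values <- expr$values
  if (!is.null(tissue)) {
    keep <- samples$tissue == tissue
    if (!any(keep)) stop_domain("no samples for tissue ", tissue)
    samples <- samples[keep, , drop = FALSE]
    values <- values[, keep, drop = FALSE]
  }
  grp <- paste(samples$tissue, samples$phase, samples$time_h, sep = "|")
  ord <- order(samples$tissue, samples$time_h, samples$phase)
  grp_levels <- unique(grp[ord])
  prof <- t(apply(values, 1, function(v) {
    tapply(v, factor(grp, levels = grp_levels), mean)
  }))
  sds <- apply(prof, 1, stats::sd)
  skipped <- rownames(prof)[sds == 0 | is.na(sds)]
  prof <- prof[!(rownames(prof) %in% skipped), , drop = FALSE]
  if (nrow(prof) < k) {
    stop_domain("fewer usable genes (", nrow(prof), ") than clusters (", k, ")")
  }
  z <- t(scale(t(prof)))
  set.seed(seed)
  km <- stats::kmeans(z, centers = k, nstart = nstart, iter.max = 100)
  out <- data.frame(gene_id = rownames(z),
                    cluster_id = as.integer(km$cluster) - 1L,
                    stringsAsFactors = FALSE)
  attr(out, "centroids") <- km$centers
  attr(out, "skipped") <- skipped
  out
}
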