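# Marker and two-cluster differential expression: Wilcoxon rank-sum on
# log-normalized values, fold changes on de-logged cluster means with a
# pseudocount of 1, detection-percentage prefilter, Benjamini-Hochberg FDR
# over the tested set.

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact enumeration when both groups have at most \code{exact_max} values
#' and the pooled data are tie-free; otherwise the normal approximation with
#' mid-rank ties, tie-corrected variance and continuity correction.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @param exact \code{NULL} (auto), or force the branch.
#' @param exact_max Largest group size for the automatic exact branch
#'   (default 10).
#' @return The two-sided p-value.
#' @export
wilcoxon_test <- function(x, y, exact = NULL, exact_max = 10L) {
  if (length(x) == 0L || length(y) == 0L)
    sctf_parameter_error("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  if (is.null(exact))
    exact <- length(x) <= exact_max && length(y) <= exact_max && !ties
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact && !ties, correct = TRUE)$p.value
  )
}

# vectorized per-gene fold-change / detection table between two cell groups
fc_table <- function(nm, cells_a, cells_b) {
  va <- nm$values[cells_a, , drop = FALSE]
  vb <- nm$values[cells_b, , drop = FALSE]
  mean_a <- Matrix::colSums(expm1(va)) / length(cells_a) + 1
  mean_b <- Matrix::colSums(expm1(vb)) / length(cells_b) + 1
  log_fc <- log(mean_a) - log(mean_b)
  data.frame(gene_id = nm$genes$gene_id,
             log_fc = as.numeric(log_fc),
             fold_change = as.numeric(exp(log_fc)),
             pct_a = as.numeric(Matrix::colMeans(va > 0)),
             pct_b = as.numeric(Matrix::colMeans(vb > 0)),
             stringsAsFactors = FALSE)
}

#' Fold change and detection fractions for one gene between two groups
#'
#' The group mean is mean(expm1(normalized value)) + 1 — a pseudocount of 1
#' on the de-logged mean — so the ratio is always finite;
#' \code{log_fc = ln(mean_a) - ln(mean_b)}. Detection fractions are the
#' proportions of cells with a raw count > 0.
#'
#' @param nm A \code{NormalizedMatrix}.
#' @param group_a,group_b Disjoint, non-empty cell index vectors.
#' @param gene Gene column index or gene id.
#' @return List with \code{log_fc}, \code{fold_change}, \code{pct_a},
#'   \code{pct_b}.
#' @export
fold_change <- function(nm, group_a, group_b, gene) {
  if (length(group_a) == 0L || length(group_b) == 0L)
    sctf_parameter_error("both groups must be non-empty")
  if (length(intersect(group_a, group_b)))
    sctf_parameter_error("groups must be disjoint")
  if (is.character(gene)) gene <- match(gene, nm$genes$gene_id)
  if (is.na(gene)) sctf_data_error("gene not found")
  va <- nm$values[group_a, gene]
  vb <- nm$values[group_b, gene]
  mean_a <- mean(expm1(va)) + 1
  mean_b <- mean(expm1(vb)) + 1
  list(log_fc = log(mean_a) - log(mean_b),
       fold_change = mean_a / mean_b,
       pct_a = mean(nm$counts[group_a, gene] > 0),
       pct_b = mean(nm$counts[group_b, gene] > 0))
}

# shared testing engine: Wilcoxon over genes passing the pct prefilter,
# BH over the tested set
test_genes <- function(nm, cells_a, cells_b, min_pct) {
  fc <- fc_table(nm, cells_a, cells_b)
  tested <- fc$pct_a > min_pct | fc$pct_b > min_pct
  p <- rep(NA_real_, nrow(fc))
  idx <- which(tested)
  if (length(idx)) {
    va <- as.matrix(nm$values[cells_a, idx, drop = FALSE])
    vb <- as.matrix(nm$values[cells_b, idx, drop = FALSE])
    p[idx] <- vapply(seq_along(idx),
                     function(j) wilcoxon_test(va[, j], vb[, j]),
                     numeric(1))
  }
  fdr <- rep(NA_real_, nrow(fc))
  fdr[idx] <- stats::p.adjust(p[idx], method = "BH")
  data.frame(fc, tested = tested, p_value = p, fdr = fdr,
             direction = ifelse(fc$log_fc >= 0, "up", "down"),
             stringsAsFactors = FALSE)
}

#' Marker genes of one cluster against all other cells
#'
#' Genes are tested only if detected in more than \code{min_pct} of either
#' group; up-markers with fold change > \code{min_fc} and BH FDR (over the
#' tested set) < \code{max_fdr} are returned, sorted by ascending p-value
#' then descending fold change.
#'
#' @param nm A \code{NormalizedMatrix}.
#' @param clusters A \code{ClusterAssignment} with at least two clusters.
#' @param cluster_id The cluster whose markers are sought (0-based label).
#' @param min_pct Detection prefilter (default 0.25, strict).
#' @param min_fc Minimum fold change (default 1.5, strict).
#' @param max_fdr Maximum BH FDR (default 0.05, strict).
#' @return A data frame of marker records (gene_id, cluster, log_fc,
#'   fold_change, pct_in, pct_out, p_value, fdr, direction).
#' @export
find_markers <- function(nm, clusters, cluster_id, min_pct = 0.25,
                         min_fc = 1.5, max_fdr = 0.05) {
  cells_in <- which(clusters$labels == cluster_id)
  cells_out <- which(clusters$labels != cluster_id)
  if (length(cells_in) == 0L) sctf_parameter_error("cluster is empty")
  if (length(cells_out) == 0L)
    sctf_parameter_error("single-cluster assignment: no out-group to compare")
  tt <- test_genes(nm, cells_in, cells_out, min_pct)
  keep <- tt$tested & tt$fold_change > min_fc & tt$fdr < max_fdr
  out <- tt[keep, , drop = FALSE]
  out <- out[order(out$p_value, -out$fold_change), , drop = FALSE]
  data.frame(gene_id = out$gene_id, cluster = cluster_id,
             log_fc = out$log_fc, fold_change = out$fold_change,
             pct_in = out$pct_a, pct_out = out$pct_b,
             p_value = out$p_value, fdr = out$fdr,
             direction = out$direction,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Tiered differential expression between two clusters
#'
#' Tests genes between the low- and high-TF clusters and returns three
#' nested tiers: \code{tier_all} (fold change > \code{min_fc} in either
#' direction, FDR < \code{max_fdr}), \code{tier_up} (the subset higher in
#' \code{cluster_hi}), and \code{tier_strong} (the up-subset with fold
#' change > \code{strong_fc}). Fold changes are high-vs-low.
#'
#' @param nm A \code{NormalizedMatrix}.
#' @param clusters A \code{ClusterAssignment}.
#' @param cluster_lo,cluster_hi Distinct 0-based cluster labels.
#' @param min_pct Detection prefilter applied before testing (default 0.25).
#' @param min_fc,max_fdr,strong_fc Tier thresholds (defaults 1.5, 0.05, 2).
#' @return A \code{DEGTiers} list: \code{records} (all tested genes, with a
#'   \code{tier} column in \{none, all, up, strong\}), and gene-id vectors
#'   \code{tier_all}, \code{tier_up}, \code{tier_strong}.
#' @export
deg_between <- function(nm, clusters, cluster_lo, cluster_hi,
                        min_pct = 0.25, min_fc = 1.5, max_fdr = 0.05,
                        strong_fc = 2.0) {
  if (identical(cluster_lo, cluster_hi))
    sctf_parameter_error("cluster_lo and cluster_hi must differ")
  cells_hi <- which(clusters$labels == cluster_hi)
  cells_lo <- which(clusters$labels == cluster_lo)
  if (length(cells_hi) == 0L || length(cells_lo) == 0L)
    sctf_parameter_error("both clusters must be non-empty")
  tt <- test_genes(nm, cells_hi, cells_lo, min_pct)
  sig <- tt$tested & !is.na(tt$fdr) & tt$fdr < max_fdr
  in_all <- sig & (tt$fold_change > min_fc | tt$fold_change < 1 / min_fc)
  in_up <- in_all & tt$log_fc > 0
  in_strong <- in_up & tt$fold_change > strong_fc
  tier <- ifelse(in_strong, "strong",
                 ifelse(in_up, "up", ifelse(in_all, "all", "none")))
  records <- data.frame(gene_id = tt$gene_id,
                        cluster_pair = paste0(cluster_hi, "_vs_", cluster_lo),
                        log_fc = tt$log_fc, fold_change = tt$fold_change,
                        pct_in = tt$pct_a, pct_out = tt$pct_b,
                        p_value = tt$p_value, fdr = tt$fdr,
                        direction = tt$direction, tier = tier,
                        stringsAsFactors = FALSE)
  records <- records[tt$tested, , drop = FALSE]
  records <- records[order(records$p_value, -records$fold_change), , drop = FALSE]
  rownames(records) <- NULL
  structure(list(records = records,
                 tier_all = tt$gene_id[in_all],
                 tier_up = tt$gene_id[in_up],
                 tier_strong = tt$gene_id[in_strong],
                 cluster_lo = cluster_lo, cluster_hi = cluster_hi,
                 thresholds = list(min_pct = min_pct, min_fc = min_fc,
                                   max_fdr = max_fdr, strong_fc = strong_fc)),
            class = "DEGTiers")
}
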