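# The core inference: per-cluster mean expression profiles, extreme-cluster
# identification for the TF, the Pearson R^2 correlation screen across
# cluster means, and the overlap call combining the screen with the strong
# DEG tier. Correlation is computed at cluster resolution on purpose:
# per-cell correlation is drowned by dropout noise, and the cluster mean is
# the unit of analysis throughout.

#' Per-cluster mean expression profiles
#'
#' @param nm A \code{NormalizedMatrix}.
#' @param clusters A \code{ClusterAssignment} over the same cells.
#' @return A \code{ClusterProfile}: list with \code{means} (genes x clusters
#'   matrix of mean normalized expression, columns named by 0-based cluster
#'   label) and \code{sizes}.
#' @export
cluster_profiles <- function(nm, clusters) {
  if (length(clusters$labels) != nrow(nm$values))
    sctf_validation_error("cluster assignment does not match the matrix cells")
  labs <- sort(unique(clusters$labels))
  ind <- Matrix::sparseMatrix(i = seq_along(clusters$labels),
                              j = match(clusters$labels, labs) ,
                              x = 1, dims = c(length(clusters$labels), length(labs)))
  sizes <- Matrix::colSums(ind)
  means <- as.matrix(Matrix::crossprod(nm$values, ind))
  means <- sweep(means, 2, sizes, "/")
  rownames(means) <- nm$genes$gene_id
  colnames(means) <- as.character(labs)
  structure(list(means = means, sizes = as.integer(sizes)),
            class = "ClusterProfile")
}

#' Clusters with the lowest and highest TF expression
#'
#' Argmin and argmax of the TF's cluster-mean profile; ties broken by lowest
#' cluster label. A TF profile that is constant across clusters means the
#' transfection-induced expression contrast the design relies on is absent,
#' and raises a premise error.
#'
#' @param profile A \code{ClusterProfile}.
#' @param tf_gene TF gene id.
#' @return List with \code{lo} and \code{hi} (0-based cluster labels).
#' @export
extreme_clusters <- function(profile, tf_gene) {
  if (ncol(profile$means) < 2L)
    sctf_parameter_error("need at least 2 clusters")
  row <- match(tf_gene, rownames(profile$means))
  if (is.na(row))
    sctf_data_error(sprintf("TF gene %s not present in the profile", tf_gene))
  v <- profile$means[row, ]
  if (max(v) == min(v))
    sctf_premise_error(sprintf(
      "no TF contrast: %s has a constant cluster-mean profile", tf_gene))
  list(lo = as.integer(colnames(profile$means)[which.min(v)]),
       hi = as.integer(colnames(profile$means)[which.max(v)]))
}

#' Pearson correlation screen against the TF's cluster profile
#'
#' For each candidate gene, the Pearson correlation between its cluster-mean
#' vector and the TF's, over all clusters. A candidate passes when
#' r^2 > \code{r2_min} and, under the default positive-regulation reading,
#' r > 0. Candidates with zero variance across clusters are recorded with a
#' missing r (never coerced to 0) and fail as \code{degenerate}.
#'
#' @param profile A \code{ClusterProfile} with at least 3 clusters.
#' @param tf_gene TF gene id (excluded from candidates if present).
#' @param candidates Character vector of candidate gene ids.
#' @param r2_min Minimum squared correlation (default 0.7, strict).
#' @param require_positive Require r > 0 (default TRUE).
#' @return A data frame of \code{CorrelationRecord}s: gene_id, r, r_squared,
#'   n_clusters, pass, fail_reason in \{none, low_r2, negative_r, degenerate\}.
#' @export
correlation_screen <- function(profile, tf_gene, candidates,
                               r2_min = 0.7, require_positive = TRUE) {
  if (ncol(profile$means) < 3L)
    sctf_parameter_error("need at least 3 clusters for the correlation screen")
  row <- match(tf_gene, rownames(profile$means))
  if (is.na(row))
    sctf_data_error(sprintf("TF gene %s not present in the profile", tf_gene))
  tf <- profile$means[row, ]
  if (stats::sd(tf) == 0)
    sctf_premise_error(sprintf(
      "no TF contrast: %s has a constant cluster-mean profile", tf_gene))
  candidates <- setdiff(unique(candidates), tf_gene)
  missing <- setdiff(candidates, rownames(profile$means))
  if (length(missing))
    sctf_data_error(sprintf("%d candidate gene(s) not in the profile (e.g. %s)",
                            length(missing), missing[1]))
  P <- profile$means[candidates, , drop = FALSE]
  sds <- apply(P, 1, stats::sd)
  r <- rep(NA_real_, length(candidates))
  ok <- sds > 0
  if (any(ok))
    r[ok] <- as.numeric(stats::cor(t(P[ok, , drop = FALSE]), tf))
  r2 <- r^2
  pass <- !is.na(r) & r2 > r2_min & (!require_positive | r > 0)
  fail_reason <- ifelse(pass, "none",
                 ifelse(!ok, "degenerate",
                 ifelse(r2 > r2_min & require_positive & r <= 0,
                        "negative_r", "low_r2")))
  data.frame(gene_id = candidates, r = r, r_squared = r2,
             n_clusters = ncol(profile$means),
             pass = pass, fail_reason = fail_reason,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Default candidate pool by detection prevalence
#'
#' Genes detected (count > 0) in more than \code{min_cells_frac} of cells,
#' minus exclusions. The pipeline always places the TF in the exclusions.
#'
#' @param nm A \code{NormalizedMatrix}.
#' @param min_cells_frac Minimum detection prevalence (default 0.10, strict).
#' @param exclude Gene ids to exclude.
#' @return Character vector of gene ids.
#' @export
default_candidate_pool <- function(nm, min_cells_frac = 0.10,
                                   exclude = character(0)) {
  prev <- Matrix::colMeans(nm$counts > 0)
  pool <- setdiff(nm$genes$gene_id[prev > min_cells_frac], exclude)
  if (length(pool) == 0L)
    sctf_data_error("empty candidate pool")
  pool
}

#' Combine the correlation screen and the strong DEG tier into target calls
#'
#' \code{final_call} is the conjunction: a gene passes the correlation screen
#' AND sits in the strong (two-fold up) DEG tier. The TF itself is never
#' called. Every gene appearing in either input gets a row, so the evidence
#' behind every decision is visible.
#'
#' @param corr Correlation records from \code{\link{correlation_screen}}.
#' @param deg Either a \code{DEGTiers} object or a character vector of
#'   strong-tier gene ids.
#' @param tf_gene TF gene id.
#' @return A data frame of \code{TargetCall}s sorted by descending r_squared
#'   (missing last), ties by gene_id: gene_id, in_correlation_set,
#'   in_deg_strong_set, final_call, r, r_squared, log_fc, fold_change, fdr.
#' @export
call_targets <- function(corr, deg, tf_gene) {
  strong <- if (inherits(deg, "DEGTiers")) deg$tier_strong else as.character(deg)
  deg_records <- if (inherits(deg, "DEGTiers")) deg$records else NULL
  genes <- union(corr$gene_id[corr$pass], strong)
  genes <- sort(genes)
  i <- match(genes, corr$gene_id)
  in_corr <- !is.na(i) & corr$pass[ifelse(is.na(i), 1L, i)]
  in_strong <- genes %in% strong
  final <- in_corr & in_strong & genes != tf_gene
  out <- data.frame(gene_id = genes,
                    in_correlation_set = in_corr,
                    in_deg_strong_set = in_strong,
                    final_call = final,
                    r = ifelse(is.na(i), NA_real_, corr$r[ifelse(is.na(i), 1L, i)]),
                    r_squared = ifelse(is.na(i), NA_real_,
                                       corr$r_squared[ifelse(is.na(i), 1L, i)]),
                    stringsAsFactors = FALSE)
  if (!is.null(deg_records)) {
    j <- match(out$gene_id, deg_records$gene_id)
    out$log_fc <- deg_records$log_fc[j]
    out$fold_change <- deg_records$fold_change[j]
    out$fdr <- deg_records$fdr[j]
  } else {
    out$log_fc <- out$fold_change <- out$fdr <- NA_real_
  }
  ord <- order(-ifelse(is.na(out$r_squared), -Inf, out$r_squared), out$gene_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
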