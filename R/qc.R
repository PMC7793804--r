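# Cell-level quality control: Gaussian mean +/- k*SD band gates on total UMI
# and detected-gene counts (the band is estimated once on the full pre-filter
# population, on the raw metric scale) and an upper gate on the fraction of
# counts from mitochondrial genes.

#' Per-cell QC metrics
#'
#' @param m A \code{CountMatrix}.
#' @return A data frame with one row per cell: \code{barcode},
#'   \code{total_umi}, \code{n_genes_detected}, \code{mito_fraction}
#'   (0 for cells with no counts).
#' @export
compute_cell_metrics <- function(m) {
  counts <- m$counts
  total <- Matrix::rowSums(counts)
  ngene <- Matrix::rowSums(counts > 0)
  mito <- if (any(m$mito_mask))
    Matrix::rowSums(counts[, m$mito_mask, drop = FALSE]) else rep(0, nrow(counts))
  frac <- ifelse(total > 0, mito / total, 0)
  data.frame(barcode = m$barcodes,
             total_umi = as.numeric(total),
             n_genes_detected = as.integer(ngene),
             mito_fraction = as.numeric(frac),
             stringsAsFactors = FALSE)
}

#' Gaussian band keep-mask
#'
#' Keeps values inside the closed interval mean +/- \code{k_sd} sample
#' standard deviations, both estimated on the input vector itself. A zero
#' standard deviation degenerates the band to a point every value equals, so
#' everything is kept.
#'
#' @param values Numeric vector (one value per cell).
#' @param k_sd Band half-width in standard deviations (default 2).
#' @param log_scale Estimate the band on \code{log1p(values)} instead of the
#'   raw scale (off by default).
#' @return Logical keep-mask of the same length.
#' @export
gaussian_band_filter <- function(values, k_sd = 2.0, log_scale = FALSE) {
  if (length(values) < 2L)
    sctf_parameter_error("band filter needs at least 2 cells")
  v <- if (log_scale) log1p(values) else values
  mu <- mean(v)
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) return(rep(TRUE, length(v)))
  v >= mu - k_sd * s & v <= mu + k_sd * s
}

#' Apply the cell QC gates
#'
#' Cells must pass all three gates jointly: band filter on total UMI, band
#' filter on detected genes, and mitochondrial fraction \code{<= mito_max}
#' (strictly greater fails). Gates are estimated in a single pass on the full
#' input population. Genes left with zero counts across the retained cells
#' are dropped and reported.
#'
#' @param m A \code{CountMatrix}.
#' @param umi_k,gene_k Band half-widths for the UMI and gene gates.
#' @param mito_max Maximum allowed mitochondrial fraction (default 0.10).
#' @param log_scale Passed to \code{\link{gaussian_band_filter}}.
#' @return A list with \code{matrix} (filtered \code{CountMatrix}, cells in
#'   input order) and \code{report} (a \code{QCReport}: per-cell flags with
#'   failure reasons, realized band limits, dropped genes, counts).
#' @export
apply_qc <- function(m, umi_k = 2.0, gene_k = 2.0, mito_max = 0.10,
                     log_scale = FALSE) {
  metrics <- compute_cell_metrics(m)
  keep_umi <- gaussian_band_filter(metrics$total_umi, umi_k, log_scale)
  keep_gene <- gaussian_band_filter(metrics$n_genes_detected, gene_k, log_scale)
  keep_mito <- metrics$mito_fraction <= mito_max
  keep <- keep_umi & keep_gene & keep_mito

  reasons <- character(nrow(metrics))
  fail <- function(mask, tag) ifelse(mask, "", tag)
  rs <- cbind(fail(keep_umi, "total_umi"),
              fail(keep_gene, "n_genes_detected"),
              fail(keep_mito, "mito_fraction"))
  reasons <- apply(rs, 1, function(r) paste(r[nzchar(r)], collapse = ","))

  if (!any(keep))
    sctf_data_error("no cells pass QC (empty after QC)")

  filtered <- subset_count_matrix(m, cells = which(keep))
  gene_nz <- Matrix::colSums(filtered$counts) > 0
  dropped <- filtered$genes$gene_id[!gene_nz]
  if (any(!gene_nz)) filtered <- subset_count_matrix(filtered, genes = which(gene_nz))

  band <- function(v, k) {
    if (log_scale) v <- log1p(v)
    c(mean = mean(v), sd = stats::sd(v),
      lo = mean(v) - k * stats::sd(v), hi = mean(v) + k * stats::sd(v))
  }
  report <- structure(list(
    cells = data.frame(metrics,
                       pass = keep, reasons = reasons,
                       stringsAsFactors = FALSE),
    umi_band = band(metrics$total_umi, umi_k),
    gene_band = band(metrics$n_genes_detected, gene_k),
    thresholds = list(umi_k = umi_k, gene_k = gene_k, mito_max = mito_max,
                      log_scale = log_scale),
    n_cells_in = nrow(metrics),
    n_cells_retained = sum(keep),
    n_genes_in = nrow(m$genes),
    n_genes_retained = nrow(filtered$genes),
    genes_dropped = dropped
  ), class = "QCReport")

  list(matrix = filtered, report = report)
}

#' @export
print.QCReport <- function(x, ...) {
  cat(sprintf("QCReport: %d/%d cells retained, %d/%d genes retained (%d all-zero genes dropped)\n",
              x$n_cells_retained, x$n_cells_in,
              x$n_genes_retained, x$n_genes_in, length(x$genes_dropped)))
  cat(sprintf("  UMI band  [%.1f, %.1f]; gene band [%.1f, %.1f]; mito <= %.2f\n",
              x$umi_band["lo"], x$umi_band["hi"],
              x$gene_band["lo"], x$gene_band["hi"], x$thresholds$mito_max))
  invisible(x)
}
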