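# Depth normalization, variable-gene selection, and PCA feeding the
# clustering graph.

#' Depth-normalize and log-transform a count matrix
#'
#' Per-cell depth normalization: value = ln(1 + count * scale_factor /
#' cell_total). Zero counts stay exactly zero, so sparsity is preserved, and
#' for every cell sum(expm1(value)) equals \code{scale_factor}.
#'
#' @param m A QC-filtered \code{CountMatrix} (no zero-total cells).
#' @param scale_factor Positive target depth per cell (default 10,000, the
#'   conventional default of this normalization).
#' @return A \code{NormalizedMatrix}: list with \code{values} (sparse
#'   cells x genes), \code{counts} (the parent counts), \code{barcodes},
#'   \code{genes}, \code{scale_factor}.
#' @export
log_normalize <- function(m, scale_factor = 1e4) {
  if (!is.numeric(scale_factor) || scale_factor <= 0)
    sctf_parameter_error("scale_factor must be positive")
  totals <- Matrix::rowSums(m$counts)
  if (any(totals == 0))
    sctf_data_error("cells with zero total counts present; run apply_qc first")
  values <- m$counts
  # dgCMatrix @i holds 0-based row (cell) indices of the nonzero entries
  values@x <- log1p(values@x * scale_factor / totals[values@i + 1L])
  structure(list(values = values, counts = m$counts,
                 barcodes = m$barcodes, genes = m$genes,
                 scale_factor = scale_factor),
            class = "NormalizedMatrix")
}

#' Select highly variable genes
#'
#' The default \code{"vst"} statistic works on raw counts: a loess trend of
#' log10(variance) on log10(mean) is fitted across genes, each gene's counts
#' are standardized by its trend-predicted standard deviation with
#' standardized values clipped at sqrt(n_cells), and genes are ranked by the
#' variance of the clipped standardized counts. The alternative
#' \code{"dispersion"} statistic ranks genes by variance/mean of the
#' log-normalized values.
#'
#' @param m A \code{CountMatrix}.
#' @param n Number of genes to select (default 500).
#' @param method \code{"vst"} (default) or \code{"dispersion"}.
#' @param loess_span Span of the mean-variance trend fit (default 0.3).
#' @return A \code{VariableGeneSet}: list with \code{indices} (column indices
#'   into the matrix, decreasing statistic, ties broken by gene index),
#'   \code{gene_ids}, \code{stats} (per-gene mean, variance, standardized
#'   variance), \code{n_selected}, \code{method}.
#' @export
select_variable_genes <- function(m, n = 500, method = c("vst", "dispersion"),
                                  loess_span = 0.3) {
  method <- match.arg(method)
  counts <- m$counts
  ncell <- nrow(counts)
  mu <- Matrix::colMeans(counts)
  ex2 <- Matrix::colSums(counts^2) / ncell
  v <- (ex2 - mu^2) * ncell / (ncell - 1)
  v <- pmax(v, 0)

  if (method == "vst") {
    fit_ok <- mu > 0 & v > 0
    if (sum(fit_ok) < 2L)
      sctf_data_error("fewer than 2 genes with positive mean and variance")
    lx <- log10(mu[fit_ok]); ly <- log10(v[fit_ok])
    pred <- rep(NA_real_, length(mu))
    if (sum(fit_ok) >= 50) {
      # robust fit so a handful of genuinely variable genes cannot drag the
      # technical mean-variance trend toward themselves
      lo <- stats::loess(ly ~ lx, span = loess_span, degree = 2,
                         family = "symmetric")
      pred[fit_ok] <- stats::fitted(lo)
    } else {
      qf <- stats::lm(ly ~ stats::poly(lx, min(2, sum(fit_ok) - 1), raw = TRUE))
      pred[fit_ok] <- stats::fitted(qf)
    }
    sd_hat <- sqrt(10^pred)
    cmax <- sqrt(ncell)
    stat <- numeric(length(mu))
    p <- counts@p
    xs <- counts@x
    for (g in which(fit_ok)) {
      nz <- if (p[g + 1L] > p[g]) xs[(p[g] + 1L):p[g + 1L]] else numeric(0)
      z0 <- max(min((0 - mu[g]) / sd_hat[g], cmax), -cmax)
      z <- pmin(pmax((nz - mu[g]) / sd_hat[g], -cmax), cmax)
      stat[g] <- (sum(z^2) + (ncell - length(nz)) * z0^2 -
                    (sum(z) + (ncell - length(nz)) * z0)^2 / ncell) / (ncell - 1)
    }
  } else {
    nm <- log_normalize(m)
    nmu <- Matrix::colMeans(nm$values)
    nex2 <- Matrix::colSums(nm$values^2) / ncell
    nv <- pmax((nex2 - nmu^2) * ncell / (ncell - 1), 0)
    stat <- ifelse(nmu > 0, nv / nmu, 0)
  }

  pos <- which(v > 0)
  if (length(pos) < n) {
    warning(sprintf("only %d genes with positive variance; returning all of them",
                    length(pos)))
    n <- length(pos)
  }
  ord <- order(-stat, seq_along(stat))
  ord <- ord[ord %in% pos]
  idx <- ord[seq_len(n)]
  structure(list(indices = idx,
                 gene_ids = m$genes$gene_id[idx],
                 stats = data.frame(gene_id = m$genes$gene_id,
                                    mean = mu, variance = v,
                                    std_variance = stat,
                                    stringsAsFactors = FALSE),
                 n_selected = n, method = method),
            class = "VariableGeneSet")
}

#' Scale selected genes and compute a PCA embedding
#'
#' Each selected gene is centered and scaled to unit variance, values are
#' clipped to \code{[-clip, clip]} to bound outlier leverage, and the
#' principal components are obtained from the eigendecomposition of the
#' gene-gene covariance (exact, deterministic). Component signs are fixed by
#' making each component's largest-magnitude loading positive.
#'
#' @param nm A \code{NormalizedMatrix}.
#' @param genes A \code{VariableGeneSet}.
#' @param n_components Number of components (default 100); clamped to
#'   min(cells - 1, genes selected) with a warning.
#' @param clip Clipping bound in standard deviations (default 10).
#' @param seed Unused by the exact solver; accepted for interface stability.
#' @return A \code{PCAEmbedding}: list with \code{scores} (cells x
#'   components, barcodes as rownames), \code{loadings} (genes x components),
#'   \code{explained_variance} (non-increasing), \code{n_components}.
#' @export
scale_and_pca <- function(nm, genes, n_components = 100, clip = 10.0,
                          seed = NULL) {
  X <- as.matrix(nm$values[, genes$indices, drop = FALSE])
  mu <- colMeans(X)
  s <- apply(X, 2, stats::sd)
  const <- s == 0 | !is.finite(s)
  if (any(const)) {
    warning(sprintf("%d constant gene(s) among selected; scaled to 0", sum(const)))
    s[const] <- 1
  }
  X <- sweep(X, 2, mu, "-")
  X <- sweep(X, 2, s, "/")
  X[, const] <- 0
  X[X > clip] <- clip
  X[X < -clip] <- -clip

  kmax <- min(nrow(X) - 1L, ncol(X))
  if (n_components > kmax) {
    warning(sprintf("n_components reduced from %d to %d", n_components, kmax))
    n_components <- kmax
  }
  eig <- eigen(crossprod(X) / (nrow(X) - 1), symmetric = TRUE)
  k <- n_components
  V <- eig$vectors[, seq_len(k), drop = FALSE]
  ev <- pmax(eig$values[seq_len(k)], 0)
  # deterministic sign: largest-|loading| entry of each component positive
  for (j in seq_len(k)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  scores <- X %*% V
  rownames(scores) <- nm$barcodes
  rownames(V) <- genes$gene_ids
  colnames(scores) <- colnames(V) <- paste0("PC", seq_len(k))
  structure(list(scores = scores, loadings = V,
                 explained_variance = ev, n_components = k),
            class = "PCAEmbedding")
}
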