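#' Construct a validated cells x genes UMI count matrix
#'
#' The raw-input container of the pipeline: a sparse non-negative integer
#' matrix of unique-molecule counts with cell barcodes on rows and genes on
#' columns, plus a per-gene mitochondrial flag used by quality control.
#'
#' @param counts A matrix or sparse \code{Matrix} of non-negative integral UMI
#'   counts, cells x genes.
#' @param barcodes Character vector of unique cell identifiers, one per row.
#' @param genes A \code{data.frame} with columns \code{gene_id} (unique) and
#'   \code{gene_name}, one row per column of \code{counts}.
#' @param mito_mask Logical vector flagging mitochondrial genes; defaults to
#'   all-\code{FALSE}.
#' @return An object of class \code{CountMatrix}: a list with elements
#'   \code{counts} (a \code{dgCMatrix}), \code{barcodes}, \code{genes},
#'   \code{mito_mask}.
#' @export
CountMatrix <- function(counts, barcodes, genes, mito_mask = NULL) {
  if (!inherits(counts, "Matrix")) counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(mito_mask)) mito_mask <- rep(FALSE, ncol(counts))
  m <- structure(
    list(counts = counts,
         barcodes = as.character(barcodes),
         genes = as.data.frame(genes, stringsAsFactors = FALSE),
         mito_mask = as.logical(mito_mask)),
    class = "CountMatrix"
  )
  validate_count_matrix(m)
}

validate_count_matrix <- function(m) {
  counts <- m$counts
  if (nrow(counts) != length(m$barcodes) || ncol(counts) != nrow(m$genes))
    sctf_validation_error(sprintf(
      "count matrix is %d x %d but %d barcodes and %d genes were given",
      nrow(counts), ncol(counts), length(m$barcodes), nrow(m$genes)))
  if (!all(c("gene_id", "gene_name") %in% names(m$genes)))
    sctf_validation_error("gene table must have columns gene_id and gene_name")
  if (anyDuplicated(m$barcodes))
    sctf_validation_error("duplicate cell barcodes")
  if (anyDuplicated(m$genes$gene_id))
    sctf_validation_error("duplicate gene identifiers")
  if (length(m$mito_mask) != ncol(counts))
    sctf_validation_error("mito_mask length does not match the number of genes")
  x <- counts@x
  if (length(x) && (any(x < 0) || any(x != floor(x))))
    sctf_format_error("counts must be non-negative integers")
  dimnames(m$counts) <- list(m$barcodes, m$genes$gene_id)
  m
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d cells x %d genes (%d mitochondrial), %.1f%% nonzero\n",
              nrow(x$counts), ncol(x$counts), sum(x$mito_mask),
              100 * length(x$counts@x) / prod(dim(x$counts))))
  invisible(x)
}

#' Subset a CountMatrix by cells and/or genes
#'
#' @param m A \code{CountMatrix}.
#' @param cells,genes Index vectors (integer or logical) into cells / genes;
#'   \code{NULL} keeps everything. Order is preserved as given.
#' @return A \code{CountMatrix}.
#' @export
subset_count_matrix <- function(m, cells = NULL, genes = NULL) {
  if (is.null(cells)) cells <- seq_along(m$barcodes)
  if (is.null(genes)) genes <- seq_len(nrow(m$genes))
  CountMatrix(m$counts[cells, genes, drop = FALSE],
              m$barcodes[cells],
              m$genes[genes, , drop = FALSE],
              m$mito_mask[genes])
}
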