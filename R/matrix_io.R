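# File-format layer: 10x-style Matrix Market triplets, FASTA promoter sets,
# and TSV result tables. Gzipped and plain files are both accepted, sniffed
# by the gzip magic bytes rather than the file extension.

open_text <- function(path) {
  if (!file.exists(path)) sctf_io_error(sprintf("file not found: %s", path))
  magic <- readBin(path, "raw", n = 2L)
  if (length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b))
    gzfile(path, "rt")
  else
    file(path, "rt")
}

read_lines_any <- function(path) {
  con <- open_text(path)
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

#' Read a 10x-style triplet count matrix
#'
#' Reads a Matrix Market coordinate file plus one-record-per-line barcode and
#' feature tables (plain or gzipped). 10x pipelines write the matrix
#' genes x cells; the orientation is detected by matching the header
#' dimensions against the table line counts and the matrix is returned
#' cells x genes.
#'
#' @param matrix_path Path to the Matrix Market coordinate file.
#' @param barcodes_path Path to the barcode table (one barcode per line).
#' @param features_path Path to the feature table
#'   (\code{gene_id <TAB> gene_name [<TAB> type]}).
#' @param mito_prefixes Character vector of gene-id/name prefixes marking
#'   mitochondrial genes (the mitochondrial gene set is organism- and
#'   annotation-specific, so it is always user-supplied).
#' @param orientation \code{"auto"} (default), or an explicit
#'   \code{"genes_x_cells"} / \code{"cells_x_genes"} for the ambiguous square
#'   case.
#' @return A \code{CountMatrix}.
#' @export
read_10x_triplet <- function(matrix_path, barcodes_path, features_path,
                             mito_prefixes = c("MT-", "mt-"),
                             orientation = c("auto", "genes_x_cells", "cells_x_genes")) {
  orientation <- match.arg(orientation)
  con <- open_text(matrix_path)
  mat <- tryCatch(Matrix::readMM(con), error = function(e) {
    close(con)
    sctf_format_error(sprintf("not a readable Matrix Market file: %s (%s)",
                              matrix_path, conditionMessage(e)))
  })
  close(con)

  barcodes <- read_lines_any(barcodes_path)
  barcodes <- barcodes[nzchar(barcodes)]
  feat_lines <- read_lines_any(features_path)
  feat_lines <- feat_lines[nzchar(feat_lines)]
  feats <- do.call(rbind, strsplit(feat_lines, "\t", fixed = TRUE))
  if (is.null(feats)) feats <- matrix(character(0), 0, 2)
  if (ncol(feats) < 1) sctf_format_error("empty feature table")
  genes <- data.frame(
    gene_id = feats[, 1],
    gene_name = if (ncol(feats) >= 2) feats[, 2] else feats[, 1],
    stringsAsFactors = FALSE
  )

  nb <- length(barcodes); ng <- nrow(genes)
  dims <- dim(mat)
  if (orientation == "auto") {
    gx <- dims[1] == ng && dims[2] == nb
    cx <- dims[1] == nb && dims[2] == ng
    if (gx && cx)
      sctf_parameter_error(
        "square matrix with equal barcode and feature counts: pass orientation explicitly")
    if (gx) orientation <- "genes_x_cells"
    else if (cx) orientation <- "cells_x_genes"
    else sctf_format_error(sprintf(
      "matrix is %d x %d but there are %d barcodes and %d features",
      dims[1], dims[2], nb, ng))
  } else {
    want <- if (orientation == "genes_x_cells") c(ng, nb) else c(nb, ng)
    if (!all(dims == want))
      sctf_format_error(sprintf(
        "matrix is %d x %d, expected %d x %d for orientation %s",
        dims[1], dims[2], want[1], want[2], orientation))
  }
  if (orientation == "genes_x_cells") mat <- Matrix::t(mat)

  mito <- startsWith_any(genes$gene_id, mito_prefixes) |
    startsWith_any(genes$gene_name, mito_prefixes)
  CountMatrix(mat, barcodes, genes, mito)
}

startsWith_any <- function(x, prefixes) {
  out <- rep(FALSE, length(x))
  for (p in prefixes) out <- out | startsWith(x, p)
  out
}

#' Write a CountMatrix as a 10x-style triplet directory
#'
#' Emits \code{matrix.mtx} (genes x cells, per the 10x convention),
#' \code{barcodes.tsv} and \code{features.tsv} such that
#' \code{\link{read_10x_triplet}} inverts it exactly.
#'
#' @param m A \code{CountMatrix}.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a named character vector of the three paths.
#' @export
write_10x_triplet <- function(m, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    sctf_io_error(sprintf("cannot create directory: %s", out_dir))
  paths <- c(matrix = file.path(out_dir, "matrix.mtx"),
             barcodes = file.path(out_dir, "barcodes.tsv"),
             features = file.path(out_dir, "features.tsv"))
  Matrix::writeMM(Matrix::t(m$counts), paths["matrix"])
  writeLines(m$barcodes, paths["barcodes"])
  writeLines(paste(m$genes$gene_id, m$genes$gene_name,
                   "Gene Expression", sep = "\t"), paths["features"])
  invisible(paths)
}

#' Read promoter sequences from a FASTA file
#'
#' Sequences are uppercased; the sequence identifier is the first whitespace
#' token of the header. Returns a \code{PromoterSet} data frame with columns
#' \code{sequence_id} and \code{sequence}, in file order.
#'
#' @param path FASTA file (plain or gzipped; multi-line sequences allowed).
#' @return A \code{PromoterSet}.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) sctf_io_error(sprintf("file not found: %s", path))
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) {
    warning("FASTA file contains no sequences")
    return(PromoterSet(character(0), character(0)))
  }
  ids <- sub("\\s.*$", "", names(set))
  PromoterSet(ids, toupper(as.character(set)))
}

#' Construct a PromoterSet
#'
#' @param sequence_id Unique sequence identifiers.
#' @param sequence Nucleotide strings over the IUPAC alphabet.
#' @return A data frame of class \code{PromoterSet}.
#' @export
PromoterSet <- function(sequence_id, sequence) {
  sequence <- toupper(as.character(sequence))
  if (anyDuplicated(sequence_id))
    sctf_validation_error("duplicate sequence identifiers in FASTA input")
  if (length(sequence) && any(!nzchar(sequence)))
    sctf_validation_error("empty sequence in FASTA input")
  bad <- grepl("[^ACGTRYSWKMBDHVNU]", sequence)
  if (any(bad))
    sctf_validation_error(sprintf("non-IUPAC characters in sequence %s",
                                  sequence_id[which(bad)[1]]))
  structure(data.frame(sequence_id = as.character(sequence_id),
                       sequence = sequence, stringsAsFactors = FALSE),
            class = c("PromoterSet", "data.frame"))
}

#' Write a result table as TSV
#'
#' Tab-separated with a header row; floating-point columns are rendered with
#' 6 significant digits; row and column order are preserved as given.
#'
#' @param records A data frame.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_table <- function(records, path) {
  records <- as.data.frame(records)
  for (j in seq_along(records)) {
    if (is.double(records[[j]])) records[[j]] <- signif(records[[j]], 6)
  }
  ok <- tryCatch({
    utils::write.table(records, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "NA")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    sctf_io_error(sprintf("cannot write table to %s: %s", path,
                          conditionMessage(ok)))
  invisible(path)
}
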