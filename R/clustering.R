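# Shared-nearest-neighbor graph construction and modularity clustering.
# Community detection is delegated to igraph's multi-level (Louvain)
# modularity optimizer with the resolution parameter; node order and moves
# are made reproducible by seeding R's RNG.

#' Build a shared-nearest-neighbor graph in PC space
#'
#' k-nearest neighbors by Euclidean distance in the first \code{dims_use}
#' principal components (a cell's own index is excluded from its k-nearest
#' list; distance ties are broken by cell index). The edge weight between
#' cells i and j is the Jaccard overlap of their neighborhoods
#' \eqn{N(i) = \{i\} \cup kNN(i)} — the cell itself belongs to its own
#' neighborhood, so mutually identical cells get weight 1. Edges with weight
#' below \code{prune} are removed.
#'
#' @param e A \code{PCAEmbedding}.
#' @param dims_use Number of leading components to use (default 30).
#' @param k Neighborhood size (default 20); must be < number of cells.
#' @param prune Minimum Jaccard weight kept (default 1/15).
#' @return An \code{SNNGraph}: list with \code{adjacency} (sparse symmetric
#'   weight matrix, zero diagonal), \code{knn} (cells x k neighbor index
#'   matrix), \code{k}, \code{prune}.
#' @export
build_snn_graph <- function(e, dims_use = 30, k = 20, prune = 1 / 15) {
  X <- e$scores[, seq_len(min(dims_use, ncol(e$scores))), drop = FALSE]
  n <- nrow(X)
  if (k >= n) sctf_parameter_error("k must be smaller than the number of cells")
  sq <- rowSums(X^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(X)
  knn <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    o <- order(d2[i, ])          # ties broken by index (stable in order())
    o <- o[o != i]
    knn[i, ] <- o[seq_len(k)]
  }
  A <- Matrix::sparseMatrix(i = c(rep(seq_len(n), each = k), seq_len(n)),
                            j = c(as.vector(t(knn)), seq_len(n)),
                            x = 1, dims = c(n, n))
  S <- Matrix::tcrossprod(A)     # shared-neighborhood counts, |N(i)| = k + 1
  S <- methods::as(methods::as(S, "generalMatrix"), "CsparseMatrix")
  Matrix::diag(S) <- 0
  S <- Matrix::drop0(S)
  S@x <- S@x / (2 * (k + 1) - S@x)   # Jaccard: |I|/(|A|+|B|-|I|)
  S@x[S@x < prune] <- 0
  S <- Matrix::drop0(S)
  structure(list(adjacency = S, knn = knn, k = k, prune = prune,
                 barcodes = rownames(e$scores)),
            class = "SNNGraph")
}

#' Cluster cells by resolution-parameterized modularity optimization
#'
#' Runs multi-level (Louvain) modularity optimization on the SNN graph at the
#' given resolution, from \code{n_restarts} seeded node orders, and keeps the
#' partition with the highest resolution-modularity (single greedy runs can
#' stall in local optima, especially on small graphs). Labels are 0-based,
#' contiguous, and renumbered by decreasing cluster size (ties by lowest
#' original label). An edgeless graph yields one singleton cluster per cell,
#' with a warning.
#'
#' @param g An \code{SNNGraph}.
#' @param resolution Resolution parameter gamma of the modularity (default 1.4).
#' @param seed Integer seed making the optimization deterministic.
#' @param n_restarts Seeded restarts of the optimizer (default 10); the
#'   first restart wins ties.
#' @return A \code{ClusterAssignment}: list with \code{labels} (integer per
#'   cell), \code{n_clusters}, \code{sizes}, \code{resolution},
#'   \code{barcodes}.
#' @export
louvain_cluster <- function(g, resolution = 1.4, seed = 0L, n_restarts = 10L) {
  n <- nrow(g$adjacency)
  if (n == 0L) sctf_parameter_error("empty graph")
  if (Matrix::nnzero(g$adjacency) == 0L) {
    warning("SNN graph has no edges; every cell becomes its own cluster")
    labels <- seq_len(n) - 1L
  } else {
    ig <- igraph::graph_from_adjacency_matrix(g$adjacency, mode = "undirected",
                                              weighted = TRUE)
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    best_q <- -Inf
    labels <- NULL
    for (t in seq_len(n_restarts)) {
      set.seed(seed + t - 1L)
      cl <- igraph::cluster_louvain(ig, resolution = resolution)
      memb <- igraph::membership(cl)
      q <- igraph::modularity(ig, memb, weights = igraph::E(ig)$weight,
                              resolution = resolution)
      if (q > best_q + 1e-12) {
        best_q <- q
        labels <- as.integer(memb) - 1L
      }
    }
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  labels <- renumber_by_size(labels)
  sizes <- as.integer(table(labels))
  structure(list(labels = labels, n_clusters = length(sizes), sizes = sizes,
                 resolution = resolution, barcodes = g$barcodes),
            class = "ClusterAssignment")
}

# relabel so cluster 0 is the largest; pure renumbering, partition unchanged
renumber_by_size <- function(labels) {
  tab <- table(labels)
  ord <- order(-as.integer(tab), as.integer(names(tab)))
  map <- integer(length(tab))
  map[ord] <- seq_along(ord) - 1L
  map[match(labels, as.integer(names(tab)))]
}

#' @export
print.ClusterAssignment <- function(x, ...) {
  cat(sprintf("ClusterAssignment: %d cells in %d clusters (resolution %.2f); sizes %s\n",
              length(x$labels), x$n_clusters, x$resolution,
              paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' Two-dimensional embedding for visualization
#'
#' A deterministic neighborhood-preserving layout: the first two principal
#' components of the subspace used for the neighbor graph. For plotting only;
#' no downstream statistic reads it.
#'
#' @param e A \code{PCAEmbedding}.
#' @param dims_use Leading components considered (default 30).
#' @param seed Accepted for interface stability; the layout is deterministic.
#' @return A cells x 2 matrix.
#' @export
embed_2d <- function(e, dims_use = 30, seed = 0L) {
  if (nrow(e$scores) < 3L) sctf_parameter_error("need at least 3 cells")
  out <- e$scores[, seq_len(min(2L, ncol(e$scores))), drop = FALSE]
  if (ncol(out) < 2L) out <- cbind(out, 0)
  colnames(out) <- c("dim1", "dim2")
  out
}
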