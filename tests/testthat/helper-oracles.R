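# Independent brute-force oracles. Everything here recomputes quantities
# from first principles (loops, enumeration, closed forms) and must stay
# independent of the package's implementation paths.

# --- exhaustive Wilcoxon rank-sum: two-sided p by enumerating all
#     assignments of pooled mid-ranks to the first group
oracle_wilcoxon_exact <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  combs <- utils::combn(length(pooled), n1)
  sums <- colSums(matrix(r[combs], nrow = n1))
  mu <- n1 * (length(pooled) + 1) / 2
  obs <- sum(r[seq_len(n1)])
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

# --- all set partitions of n items (restricted growth strings)
oracle_partitions <- function(n) {
  res <- list()
  rec <- function(prefix, maxv) {
    if (length(prefix) == n) {
      res[[length(res) + 1L]] <<- prefix
      return(invisible())
    }
    for (v in 1:(maxv + 1L)) rec(c(prefix, v), max(maxv, v))
  }
  rec(integer(0), 0L)
  res
}

# --- resolution-parameterized modularity from the adjacency matrix
oracle_modularity <- function(A, memb, gamma) {
  m2 <- sum(A)
  if (m2 == 0) return(0)
  k <- rowSums(A)
  same <- outer(memb, memb, "==")
  sum((A - gamma * outer(k, k) / m2) * same) / m2
}

oracle_best_modularity <- function(A, gamma) {
  max(vapply(oracle_partitions(nrow(A)),
             function(p) oracle_modularity(A, p, gamma), numeric(1)))
}

# --- brute-force SNN: kNN by sorted distances (self excluded, ties by
#     index), Jaccard over neighborhoods including the cell itself
oracle_snn <- function(X, k, prune) {
  n <- nrow(X)
  nbr <- vector("list", n)
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(X) - X[i, ])^2))
    o <- order(d)
    o <- o[o != i]
    nbr[[i]] <- c(i, o[seq_len(k)])
  }
  W <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    w <- length(intersect(nbr[[i]], nbr[[j]])) /
      length(union(nbr[[i]], nbr[[j]]))
    if (w >= prune) W[i, j] <- w
  }
  W
}

# --- character-window motif count (forward strand)
oracle_motif_count <- function(s) {
  n <- nchar(s)
  if (n < 4) return(0L)
  w <- substring(s, 1:(n - 3), 4:n)
  sum(w == "CGTG" | w == "CGTA")
}

# --- Pearson correlation, closed-form sum formula
oracle_pearson <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

# --- small random count matrix for round-trip / oracle tests
make_counts <- function(n_cells, n_genes, seed = 1, mu = 1, size = 2,
                        n_mito = 0) {
  set.seed(seed)
  counts <- matrix(stats::rnbinom(n_cells * n_genes, mu = mu, size = size),
                   n_cells, n_genes)
  ids <- sprintf("G%04d", seq_len(n_genes))
  if (n_mito > 0) ids[seq_len(n_mito)] <- sprintf("MT-G%04d", seq_len(n_mito))
  CountMatrix(counts, sprintf("bc%04d", seq_len(n_cells)),
              data.frame(gene_id = ids, gene_name = ids,
                         stringsAsFactors = FALSE),
              startsWith(ids, "MT-"))
}

# NormalizedMatrix stand-in built directly from a dense matrix of
# log-normalized values (counts share the sparsity pattern)
make_nm <- function(values, counts = NULL, gene_ids = NULL) {
  values <- Matrix::Matrix(values, sparse = TRUE)
  if (is.null(counts)) counts <- values
  if (is.null(gene_ids)) gene_ids <- sprintf("G%04d", seq_len(ncol(values)))
  structure(list(values = values,
                 counts = Matrix::Matrix(counts, sparse = TRUE),
                 barcodes = sprintf("bc%04d", seq_len(nrow(values))),
                 genes = data.frame(gene_id = gene_ids, gene_name = gene_ids,
                                    stringsAsFactors = FALSE),
                 scale_factor = 1e4),
            class = "NormalizedMatrix")
}

make_profile <- function(means, sizes = NULL) {
  if (is.null(sizes)) sizes <- rep(10L, ncol(means))
  if (is.null(colnames(means)))
    colnames(means) <- as.character(seq_len(ncol(means)) - 1L)
  structure(list(means = means, sizes = sizes), class = "ClusterProfile")
}

make_clusters <- function(labels) {
  labels <- as.integer(labels)
  structure(list(labels = labels, n_clusters = length(unique(labels)),
                 sizes = as.integer(table(labels)), resolution = NA_real_,
                 barcodes = sprintf("bc%04d", seq_along(labels))),
            class = "ClusterAssignment")
}

random_dna <- function(n, len, seed) {
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}
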