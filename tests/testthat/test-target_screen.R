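test_that("cluster profiles equal brute-force per-cluster means", {
  set.seed(71)
  m <- make_counts(60, 12, seed = 71, mu = 4)
  nm <- log_normalize(m)
  labels <- sample(0:2, 60, replace = TRUE)
  prof <- cluster_profiles(nm, make_clusters(labels))
  vals <- as.matrix(nm$values)
  for (cl in 0:2) for (g in c(1, 6, 12))
    expect_equal(prof$means[g, as.character(cl)],
                 mean(vals[labels == cl, g]), tolerance = 1e-12)

  # one cluster holding all cells equals the genewise grand mean
  p1 <- cluster_profiles(nm, make_clusters(rep(0L, 60)))
  expect_equal(unname(p1$means[, 1]), unname(colMeans(vals)), tolerance = 1e-12)

  # singleton cluster column equals that cell's normalized vector
  labels2 <- c(1L, rep(0L, 59))
  p2 <- cluster_profiles(nm, make_clusters(labels2))
  expect_equal(unname(p2$means[, "1"]), unname(vals[1, ]), tolerance = 1e-12)
})

test_that("extreme clusters are the argmin/argmax with low-label tie-breaks", {
  prof <- make_profile(rbind(TF = c(0.1, 5.0, 2.0)))
  expect_equal(extreme_clusters(prof, "TF"), list(lo = 0L, hi = 1L))
  prof2 <- make_profile(rbind(TF = c(3, 3, 1)))
  expect_equal(extreme_clusters(prof2, "TF"), list(lo = 2L, hi = 0L))
  prof3 <- make_profile(rbind(TF = c(2, 2, 2)))
  expect_error(extreme_clusters(prof3, "TF"), class = "sctf_premise_error")
  expect_error(extreme_clusters(prof, "absent"), class = "sctf_data_error")
})

test_that("extreme clusters are invariant under consistent relabeling", {
  prof <- make_profile(rbind(TF = c(0.5, 4, 1, 2)))
  perm <- c(3, 1, 4, 2)   # permute the columns, keep labels attached
  means2 <- prof$means[, perm, drop = FALSE]
  colnames(means2) <- colnames(prof$means)[perm]
  ex1 <- extreme_clusters(prof, "TF")
  ex2 <- extreme_clusters(make_profile(means2, prof$sizes[perm]), "TF")
  expect_equal(ex1, ex2)
})

test_that("correlation screen matches the closed-form Pearson formula", {
  tf <- c(1, 2, 3, 4)
  cand <- c(1.1, 1.9, 3.2, 3.8)
  prof <- make_profile(rbind(TF = tf, A = cand))
  rec <- correlation_screen(prof, "TF", "A", r2_min = 0.7)
  expect_equal(rec$r, oracle_pearson(cand, tf), tolerance = 1e-12)
  expect_equal(rec$r_squared, rec$r^2, tolerance = 1e-15)
  expect_true(rec$pass)
})

test_that("proportional, anticorrelated and degenerate candidates are classified", {
  tf <- c(1, 3, 2, 5)
  prof <- make_profile(rbind(
    TF = tf,
    prop = 0.2 + 2.5 * tf,            # exact positive proportionality
    anti = 10 - 2 * tf,               # perfect anticorrelation
    flat = rep(4, 4)))                # zero variance
  rec <- correlation_screen(prof, "TF", c("prop", "anti", "flat"))
  expect_equal(rec$r[rec$gene_id == "prop"], 1, tolerance = 1e-12)
  expect_true(rec$pass[rec$gene_id == "prop"])
  expect_equal(rec$r[rec$gene_id == "anti"], -1, tolerance = 1e-12)
  expect_false(rec$pass[rec$gene_id == "anti"])
  expect_equal(rec$fail_reason[rec$gene_id == "anti"], "negative_r")
  expect_true(is.na(rec$r[rec$gene_id == "flat"]))
  expect_equal(rec$fail_reason[rec$gene_id == "flat"], "degenerate")
  # sign-blind mode admits the anticorrelated gene
  rec2 <- correlation_screen(prof, "TF", "anti", require_positive = FALSE)
  expect_true(rec2$pass)
})

test_that("the screen is invariant under positive affine transforms", {
  set.seed(72)
  tf <- runif(6, 0, 5)
  cand <- 2 * tf + rnorm(6, sd = 0.3)
  prof1 <- make_profile(rbind(TF = tf, A = cand))
  prof2 <- make_profile(rbind(TF = tf, A = 7 + 0.01 * cand))
  r1 <- correlation_screen(prof1, "TF", "A")
  r2 <- correlation_screen(prof2, "TF", "A")
  expect_equal(r1$r, r2$r, tolerance = 1e-12)
})

test_that("a constant TF profile is a premise error in the screen", {
  prof <- make_profile(rbind(TF = c(1, 1, 1), A = c(1, 2, 3)))
  expect_error(correlation_screen(prof, "TF", "A"),
               class = "sctf_premise_error")
})

test_that("prevalence pool matches brute-force detection fractions", {
  m <- make_counts(200, 30, seed = 73, mu = 0.3)
  nm <- log_normalize(apply_qc(m, umi_k = 10, gene_k = 10)$matrix)
  pool <- default_candidate_pool(nm, min_cells_frac = 0.10, exclude = "G0001")
  dense <- as.matrix(nm$counts)
  brute <- nm$genes$gene_id[colMeans(dense > 0) > 0.10]
  expect_setequal(pool, setdiff(brute, "G0001"))
  # always-detected gene is in; 1-in-1000 gene is out
  counts <- cbind(rep(3, 100), c(1, rep(0, 99)))
  m2 <- CountMatrix(counts, sprintf("c%03d", 1:100),
                    data.frame(gene_id = c("ubiq", "rare"),
                               gene_name = c("ubiq", "rare")))
  nm2 <- log_normalize(m2)
  pool2 <- default_candidate_pool(nm2)
  expect_true("ubiq" %in% pool2)
  expect_false("rare" %in% pool2)
})

test_that("target calls are the conjunction of screen pass and strong tier", {
  corr <- data.frame(gene_id = c("A", "B", "C"), r = c(0.9, 0.95, 0.99),
                     r_squared = c(0.81, 0.9025, 0.9801), n_clusters = 5,
                     pass = TRUE, fail_reason = "none",
                     stringsAsFactors = FALSE)
  calls <- call_targets(corr, c("B", "C", "D"), tf_gene = "TF")
  expect_setequal(calls$gene_id[calls$final_call], c("B", "C"))
  expect_true(all(c("A", "D") %in% calls$gene_id))
  expect_false(any(calls$final_call[calls$gene_id %in% c("A", "D")]))
  # disjoint sets: zero calls, non-empty evidence
  calls2 <- call_targets(corr, c("X", "Y"), tf_gene = "TF")
  expect_equal(sum(calls2$final_call), 0L)
  expect_gt(nrow(calls2), 0L)
  # the TF is never called even if it sits in the strong tier
  calls3 <- call_targets(corr, c("TF", "B"), tf_gene = "TF")
  expect_false(calls3$final_call[calls3$gene_id == "TF"])
})

test_that("adding a gene to neither input set never changes existing calls", {
  corr <- data.frame(gene_id = c("A", "B"), r = c(0.9, 0.85),
                     r_squared = c(0.81, 0.7225), n_clusters = 4,
                     pass = c(TRUE, TRUE), fail_reason = "none",
                     stringsAsFactors = FALSE)
  base <- call_targets(corr, "A", tf_gene = "TF")
  corr2 <- rbind(corr, data.frame(gene_id = "Z", r = 0.1, r_squared = 0.01,
                                  n_clusters = 4, pass = FALSE,
                                  fail_reason = "low_r2"))
  ext <- call_targets(corr2, "A", tf_gene = "TF")
  expect_identical(base[base$gene_id %in% c("A", "B"), ],
                   ext[ext$gene_id %in% c("A", "B"), ])
})

test_that("transfected cells concentrate in the high-TF cluster", {
  sim <- simulate_toe(sim_config(n_cells = 800, n_genes = 400, n_targets = 10,
                                 seed = 17))
  qc <- apply_qc(sim$matrix)
  nm <- log_normalize(qc$matrix)
  hvg <- select_variable_genes(qc$matrix, n = 200)
  pca <- scale_and_pca(nm, hvg, n_components = 30)
  snn <- build_snn_graph(pca, dims_use = 20, k = 15)
  cl <- louvain_cluster(snn, 1.4, seed = 1)
  prof <- cluster_profiles(nm, cl)
  ex <- extreme_clusters(prof, "Os02g0822400")
  truth_tr <- sim$truth$cells$transfected[match(qc$matrix$barcodes,
                                                sim$truth$cells$barcode)]
  hi_cells <- cl$labels == ex$hi
  expect_gt(mean(truth_tr[hi_cells]), 0.8)
})
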