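test_that("exact Wilcoxon branch reproduces the enumeration p-value", {
  expect_equal(wilcoxon_test(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(oracle_wilcoxon_exact(c(1, 2, 3), c(4, 5, 6)), 0.1)
  # identical samples: maximal p
  expect_equal(wilcoxon_test(c(1, 2, 3), c(1, 2, 3)), 1.0)
  # a few tie-free small cases against enumeration
  set.seed(61)
  for (i in 1:10) {
    x <- sample(1:100, 6); y <- sample(101:200, 5)
    y <- y - sample(0:80, 1)
    if (anyDuplicated(c(x, y))) next
    expect_equal(wilcoxon_test(x, y), oracle_wilcoxon_exact(x, y),
                 tolerance = 1e-12)
  }
})

test_that("normal approximation tracks exhaustive enumeration on 8 vs 8 samples", {
  set.seed(62)
  for (i in 1:20) {
    x <- rnorm(8); y <- rnorm(8, mean = runif(1, -1, 1))
    p_approx <- wilcoxon_test(x, y, exact = FALSE)
    p_exact <- oracle_wilcoxon_exact(x, y)
    expect_lt(abs(p_approx - p_exact), 0.02)
  }
})

test_that("empty groups are rejected", {
  expect_error(wilcoxon_test(numeric(0), 1:3), class = "sctf_parameter_error")
})

test_that("fold change follows the pseudocount-on-de-logged-mean convention", {
  # gene silent in both groups
  nm <- make_nm(matrix(0, 6, 2))
  fc <- fold_change(nm, 1:3, 4:6, 1)
  expect_equal(fc$fold_change, 1.0)
  expect_equal(fc$log_fc, 0.0)

  # de-logged means 9 vs 4 -> (9+1)/(4+1) = 2
  v <- matrix(0, 4, 1)
  v[1:2, 1] <- log(10)   # expm1 = 9
  v[3:4, 1] <- log(5)    # expm1 = 4
  nm2 <- make_nm(v)
  fc2 <- fold_change(nm2, 1:2, 3:4, 1)
  expect_equal(fc2$fold_change, 2.0, tolerance = 1e-12)

  # random fixture against an independent loop
  set.seed(63)
  counts <- matrix(rnbinom(40 * 8, mu = 5, size = 2), 40, 8)
  m <- CountMatrix(counts, sprintf("c%02d", 1:40),
                   data.frame(gene_id = paste0("g", 1:8),
                              gene_name = paste0("g", 1:8)))
  nm3 <- log_normalize(m)
  a <- 1:20; b <- 21:40
  vals <- as.matrix(nm3$values)
  for (g in c(1, 4, 8)) {
    fcg <- fold_change(nm3, a, b, g)
    ma <- mean(expm1(vals[a, g])) + 1
    mb <- mean(expm1(vals[b, g])) + 1
    expect_equal(fcg$fold_change, ma / mb, tolerance = 1e-12)
    expect_equal(fcg$log_fc, log(ma) - log(mb), tolerance = 1e-12)
    expect_equal(fcg$pct_a, mean(counts[a, g] > 0))
  }
})

test_that("swapping the groups negates log_fc exactly", {
  set.seed(64)
  nm <- make_nm(matrix(abs(rnorm(30 * 3)), 30, 3))
  f1 <- fold_change(nm, 1:15, 16:30, 2)
  f2 <- fold_change(nm, 16:30, 1:15, 2)
  expect_equal(f1$log_fc, -f2$log_fc, tolerance = 1e-12)
})

test_that("planted markers are recovered with no false positives", {
  hits <- 0
  for (s in 1:20) {
    set.seed(700 + s)
    n <- 300; labels <- rep(c(0L, 1L), each = n / 2)
    null_counts <- matrix(rnbinom(n * 200, mu = 2, size = 5), n, 200)
    marker_mu <- ifelse(labels == 1L, 8, 2)   # 4-fold up in cluster 1
    markers <- sapply(1:5, function(i) rnbinom(n, mu = marker_mu, size = 5))
    counts <- cbind(markers, null_counts)
    ids <- c(paste0("mk", 1:5), sprintf("null%03d", 1:200))
    m <- CountMatrix(counts, sprintf("c%03d", 1:n),
                     data.frame(gene_id = ids, gene_name = ids))
    nm <- log_normalize(m)
    res <- find_markers(nm, make_clusters(labels), 1L)
    ok <- all(paste0("mk", 1:5) %in% res$gene_id) &&
      !any(startsWith(res$gene_id, "null"))
    hits <- hits + ok
  }
  expect_gte(hits, 18)
})

test_that("genes below the detection prefilter are never tested", {
  set.seed(65)
  n <- 100
  counts <- matrix(rnbinom(n * 10, mu = 3, size = 3), n, 10)
  counts[, 1] <- 0
  counts[sample(n, 5), 1] <- 1   # detected in 5% of cells: below 25% everywhere
  ids <- paste0("g", 1:10)
  m <- CountMatrix(counts, sprintf("c%03d", 1:n),
                   data.frame(gene_id = ids, gene_name = ids))
  nm <- log_normalize(m)
  deg <- deg_between(nm, make_clusters(rep(c(0L, 1L), each = 50)), 0L, 1L)
  expect_false("g1" %in% deg$records$gene_id)
})

test_that("single-cluster marker calling is rejected", {
  nm <- make_nm(matrix(1, 10, 3))
  expect_error(find_markers(nm, make_clusters(rep(0L, 10)), 0L),
               class = "sctf_parameter_error")
  expect_error(deg_between(nm, make_clusters(rep(c(0L, 1L), 5)), 1L, 1L),
               class = "sctf_parameter_error")
})

test_that("DEG tiers are nested and identically distributed clusters yield none", {
  empties <- 0
  for (s in 1:20) {
    set.seed(800 + s)
    n <- 400
    counts <- matrix(rnbinom(n * 100, mu = 3, size = 3), n, 100)
    ids <- sprintf("g%03d", 1:100)
    m <- CountMatrix(counts, sprintf("c%03d", 1:n),
                     data.frame(gene_id = ids, gene_name = ids))
    nm <- log_normalize(m)
    deg <- deg_between(nm, make_clusters(rep(c(0L, 1L), each = n / 2)), 0L, 1L)
    expect_true(all(deg$tier_strong %in% deg$tier_up))
    expect_true(all(deg$tier_up %in% deg$tier_all))
    empties <- empties + (length(deg$tier_all) == 0L)
  }
  expect_gte(empties, 18)
})

test_that("effect sizes straddling two-fold land in the right tiers", {
  set.seed(66)
  n <- 400
  # a large flat background keeps per-cell totals nearly equal between the
  # groups, so depth normalization barely attenuates the planted ratios
  base <- matrix(rnbinom(n * 200, mu = 20, size = 20), n, 200)
  hi <- rep(c(FALSE, TRUE), each = n / 2)
  strong <- sapply(1:3, function(i) rnbinom(n, mu = ifelse(hi, 50, 20), size = 20))
  weak <- sapply(1:3, function(i) rnbinom(n, mu = ifelse(hi, 34, 20), size = 20))
  counts <- cbind(strong, weak, base)
  ids <- c(paste0("strong", 1:3), paste0("weak", 1:3), sprintf("base%03d", 1:200))
  m <- CountMatrix(counts, sprintf("c%03d", 1:n),
                   data.frame(gene_id = ids, gene_name = ids))
  nm <- log_normalize(m)
  deg <- deg_between(nm, make_clusters(as.integer(hi)), 0L, 1L)
  expect_true(all(paste0("strong", 1:3) %in% deg$tier_strong))
  expect_true(all(paste0("weak", 1:3) %in% deg$tier_up))
  expect_false(any(paste0("weak", 1:3) %in% deg$tier_strong))
})

test_that("BH adjustment respects fdr in [p, 1] and p-rank monotonicity", {
  set.seed(67)
  n <- 200
  counts <- matrix(rnbinom(n * 60, mu = 4, size = 3), n, 60)
  counts[1:(n / 2), 1:5] <- counts[1:(n / 2), 1:5] + rpois(n / 2 * 5, 6)
  ids <- sprintf("g%02d", 1:60)
  m <- CountMatrix(counts, sprintf("c%03d", 1:n),
                   data.frame(gene_id = ids, gene_name = ids))
  nm <- log_normalize(m)
  deg <- deg_between(nm, make_clusters(rep(c(0L, 1L), each = n / 2)), 1L, 0L,
                     max_fdr = 1)
  rec <- deg$records
  expect_true(all(rec$fdr >= rec$p_value - 1e-12))
  expect_true(all(rec$fdr <= 1))
  o <- order(rec$p_value)
  expect_true(all(diff(rec$fdr[o]) >= -1e-12))
})
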