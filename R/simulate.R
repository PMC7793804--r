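# Synthetic transient-overexpression (TOE) scRNA-seq generator with known
# ground truth. The generative premise mirrors the experiment being modeled:
# a subset of cells takes up the TF plasmid with a heterogeneous dose, the
# TF's expression tracks the dose, true targets respond linearly to the
# dose, everything else is stationary negative-binomial noise with per-cell
# library-size variation, plus a small damaged-cell fraction with inflated
# mitochondrial content to exercise QC.

#' Simulation configuration
#'
#' Defaults describe the emulated study conditions: 3,000 cells by 2,000
#' genes, 20 planted targets, a 60% transfection rate (harvest before the
#' ~65% peak, when per-cell doses are most heterogeneous), log-normal
#' per-cell dose and depth, gamma-distributed gene base means and shared NB
#' dispersion.
#'
#' @param n_cells,n_genes Matrix dimensions (defaults 3000 x 2000).
#' @param n_targets Number of planted dose-responsive targets (default 20).
#' @param n_mito_genes Number of mitochondrial genes (default 10).
#' @param transfection_rate Probability a cell is transfected (default 0.60).
#' @param tf_dose_sd Log-normal sigma of per-cell plasmid dose among
#'   transfected cells (default 0.75).
#' @param tf_base_mean Mean TF counts in untransfected cells, near 0
#'   (default 0.05).
#' @param tf_scale Mean TF counts per unit dose (default 20).
#' @param beta Per-target linear dose-response slope; scalar or length
#'   \code{n_targets} (default 1.5).
#' @param base_mean_shape,base_mean_rate Gamma hyperparameters of gene base
#'   means (defaults 0.5, 0.5: mean 1 count/cell, right-skewed).
#' @param dispersion NB dispersion (inverse size; variance =
#'   mu + dispersion * mu^2); 0 gives Poisson counts (default 0.3).
#' @param libsize_sigma Log-normal sd of the per-cell depth factor
#'   (default 0.35).
#' @param n_celltype_blobs,blob_effect Optional background heterogeneity:
#'   number of cell blobs (0 = off, the default, matching the low
#'   heterogeneity of differentiated leaf cells) and the fold applied to
#'   each blob's private 5% gene subset.
#' @param damaged_frac Fraction of cells with inflated mitochondrial counts
#'   (default 0.02).
#' @param min_target_base Minimum base mean for a gene to be eligible as a
#'   planted target (default 0.2): targets are drawn from detectably
#'   expressed genes, as an expression-based screen can only ever see those.
#' @param tf_gene_id,tf_gene_name Identifiers of the TF gene.
#' @param seed Integer seed; one seeded generator drives every draw.
#' @return A validated \code{SimConfig} list.
#' @export
sim_config <- function(n_cells = 3000L, n_genes = 2000L, n_targets = 20L,
                       n_mito_genes = 10L, transfection_rate = 0.60,
                       tf_dose_sd = 0.75, tf_base_mean = 0.05, tf_scale = 20,
                       beta = 1.5, base_mean_shape = 0.5, base_mean_rate = 0.5,
                       dispersion = 0.3, libsize_sigma = 0.35,
                       n_celltype_blobs = 0L, blob_effect = 2.0,
                       damaged_frac = 0.02, min_target_base = 0.2,
                       tf_gene_id = "Os02g0822400", tf_gene_name = "OsNAC78",
                       seed = 1L) {
  cfg <- list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
              n_targets = as.integer(n_targets),
              n_mito_genes = as.integer(n_mito_genes),
              transfection_rate = transfection_rate, tf_dose_sd = tf_dose_sd,
              tf_base_mean = tf_base_mean, tf_scale = tf_scale, beta = beta,
              base_mean_shape = base_mean_shape, base_mean_rate = base_mean_rate,
              dispersion = dispersion, libsize_sigma = libsize_sigma,
              n_celltype_blobs = as.integer(n_celltype_blobs),
              blob_effect = blob_effect, damaged_frac = damaged_frac,
              min_target_base = min_target_base,
              tf_gene_id = tf_gene_id, tf_gene_name = tf_gene_name,
              seed = as.integer(seed))
  with(cfg, {
    if (n_cells < 2L || n_genes < 2L) sctf_parameter_error("need >= 2 cells and genes")
    if (transfection_rate < 0 || transfection_rate > 1)
      sctf_parameter_error("transfection_rate must be in [0, 1]")
    if (n_targets < 0L || n_targets > n_genes - 1L - n_mito_genes)
      sctf_parameter_error("n_targets out of range")
    if (tf_base_mean < 0 || tf_scale < 0 || tf_dose_sd < 0 || libsize_sigma < 0)
      sctf_parameter_error("negative rate or scale parameter")
    if (base_mean_shape <= 0 || base_mean_rate <= 0)
      sctf_parameter_error("gamma hyperparameters must be positive")
    if (dispersion < 0) sctf_parameter_error("dispersion must be >= 0")
    if (!length(beta) %in% c(1L, n_targets))
      sctf_parameter_error("beta must be scalar or one value per target")
    if (damaged_frac < 0 || damaged_frac > 1)
      sctf_parameter_error("damaged_frac must be in [0, 1]")
  })
  structure(cfg, class = "SimConfig")
}

#' Simulate a transient-overexpression experiment
#'
#' Generative model, in order: (1) per-cell transfection ~
#' Bernoulli(\code{transfection_rate}) and dose D ~ LogNormal(0,
#' \code{tf_dose_sd}) for transfected cells, 0 otherwise; (2) per-cell depth
#' factor L ~ LogNormal(0, \code{libsize_sigma}); (3) gene base means b ~
#' Gamma(shape, rate), optional blob structure multiplying blob-private gene
#' subsets; (4) expected counts — TF: L (tf_base_mean + tf_scale D);
#' target g: L b_g (1 + beta_g D); others: L b_g; (5) counts ~ NB(mean mu,
#' dispersion); (6) a \code{damaged_frac} fraction of cells get
#' mitochondrial counts resampled so their mitochondrial fraction exceeds
#' 10%. The same seed always yields the identical dataset.
#'
#' @param cfg A \code{SimConfig}.
#' @return List with \code{matrix} (a \code{CountMatrix}) and \code{truth}
#'   (a \code{SimTruth}: per-cell and per-gene truth tables plus the config).
#' @export
simulate_toe <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  n <- cfg$n_cells; g <- cfg$n_genes

  transfected <- stats::runif(n) < cfg$transfection_rate
  dose <- ifelse(transfected,
                 stats::rlnorm(n, meanlog = 0, sdlog = cfg$tf_dose_sd), 0)
  libsize <- stats::rlnorm(n, meanlog = 0, sdlog = cfg$libsize_sigma)

  # gene axis: [1] TF, [2 .. g - n_mito] ordinary, tail mitochondrial
  n_mito <- cfg$n_mito_genes
  ordinary <- 2:(g - n_mito)
  mito_idx <- if (n_mito > 0) (g - n_mito + 1L):g else integer(0)
  gene_id <- sprintf("G%05d", seq_len(g))
  gene_id[mito_idx] <- sprintf("MT-G%05d", mito_idx)
  gene_name <- gene_id
  gene_id[1] <- cfg$tf_gene_id; gene_name[1] <- cfg$tf_gene_name

  base <- stats::rgamma(g, shape = cfg$base_mean_shape, rate = cfg$base_mean_rate)
  base[1] <- NA  # the TF's mean is dose-driven, not gamma-drawn

  eligible <- ordinary[base[ordinary] >= cfg$min_target_base]
  if (length(eligible) < cfg$n_targets)
    sctf_parameter_error(sprintf(
      "only %d genes eligible as targets (base mean >= %g); lower min_target_base",
      length(eligible), cfg$min_target_base))
  targets <- sort(sample(eligible, cfg$n_targets))
  beta_g <- numeric(g)
  beta_g[targets] <- rep(cfg$beta, length.out = cfg$n_targets)

  blob <- rep(0L, n)
  mu <- outer(libsize, ifelse(is.na(base), 0, base))
  if (cfg$n_celltype_blobs >= 2L) {
    blob <- sample.int(cfg$n_celltype_blobs, n, replace = TRUE)
    n_private <- max(1L, round(0.05 * length(ordinary)))
    for (b in seq_len(cfg$n_celltype_blobs)) {
      genes_b <- sample(ordinary, n_private)
      mu[blob == b, genes_b] <- mu[blob == b, genes_b] * cfg$blob_effect
    }
  }
  mu[, 1] <- libsize * (cfg$tf_base_mean + cfg$tf_scale * dose)
  if (length(targets))
    mu[, targets] <- mu[, targets] * (1 + outer(dose, beta_g[targets]))
  if (any(!is.finite(mu)))
    sctf_parameter_error("configuration implies non-finite expected counts")

  counts <- if (cfg$dispersion > 0)
    stats::rnbinom(n * g, mu = mu, size = 1 / cfg$dispersion)
  else
    stats::rpois(n * g, lambda = mu)
  counts <- matrix(as.numeric(counts), n, g)

  damaged <- stats::runif(n) < cfg$damaged_frac
  if (any(damaged) && n_mito > 0) {
    for (i in which(damaged)) {
      other <- sum(counts[i, -mito_idx])
      frac <- stats::runif(1, 0.15, 0.35)
      mtot <- max(1L, round(frac / (1 - frac) * max(other, 1)))
      counts[i, mito_idx] <- as.numeric(
        stats::rmultinom(1, mtot, prob = base[mito_idx] + 1e-9))
    }
  }

  m <- CountMatrix(counts,
                   barcodes = sprintf("cell%05d", seq_len(n)),
                   genes = data.frame(gene_id = gene_id, gene_name = gene_name,
                                      stringsAsFactors = FALSE),
                   mito_mask = seq_len(g) %in% mito_idx)
  truth <- structure(list(
    cells = data.frame(barcode = m$barcodes, transfected = transfected,
                       dose = dose, libsize = libsize, damaged = damaged,
                       blob = blob, stringsAsFactors = FALSE),
    genes = data.frame(gene_id = gene_id, gene_name = gene_name,
                       is_tf = seq_len(g) == 1L,
                       is_target = seq_len(g) %in% targets,
                       is_mito = seq_len(g) %in% mito_idx,
                       beta = beta_g,
                       base_mean = ifelse(is.na(base), 0, base),
                       stringsAsFactors = FALSE),
    config = cfg
  ), class = "SimTruth")
  list(matrix = m, truth = truth)
}

#' Score target calls against simulation truth
#'
#' @param calls A \code{TargetCall} data frame from \code{\link{call_targets}}.
#' @param truth A \code{SimTruth}.
#' @return List with \code{recall} (called true targets / planted targets),
#'   \code{precision} (called true targets / calls; defined as 1 and flagged
#'   when there are no calls), \code{precision_defined}, \code{n_calls},
#'   \code{n_targets}, and a per-gene \code{confusion} data frame.
#' @export
truth_eval <- function(calls, truth) {
  stopifnot(inherits(truth, "SimTruth"))
  if (!all(calls$gene_id %in% truth$genes$gene_id))
    sctf_validation_error("target calls refer to genes absent from the truth axis")
  called <- calls$gene_id[calls$final_call]
  targets <- truth$genes$gene_id[truth$genes$is_target]
  tp <- intersect(called, targets)
  confusion <- data.frame(
    gene_id = truth$genes$gene_id,
    is_target = truth$genes$is_target,
    called = truth$genes$gene_id %in% called,
    stringsAsFactors = FALSE)
  confusion$label <- with(confusion,
    ifelse(is_target & called, "TP",
    ifelse(!is_target & called, "FP",
    ifelse(is_target & !called, "FN", "TN"))))
  list(recall = if (length(targets)) length(tp) / length(targets) else NA_real_,
       precision = if (length(called)) length(tp) / length(called) else 1.0,
       precision_defined = length(called) > 0,
       n_calls = length(called), n_targets = length(targets),
       confusion = confusion)
}
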