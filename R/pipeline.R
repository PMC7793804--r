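# End-to-end orchestration: read -> QC -> normalize -> HVG -> PCA -> SNN ->
# cluster -> profiles -> extreme clusters -> DEG tiers -> correlation screen
# -> target calls, with a stage-by-stage manifest and deterministic seeding.

#' Pipeline configuration
#'
#' Collects every stage parameter with its default. One global seed fans out
#' to per-stage seeds by a fixed derivation (\code{seed + 101} for PCA,
#' \code{seed + 202} for clustering, \code{seed + 303} for the 2-D layout),
#' so each stage is individually reproducible.
#'
#' @param tf_gene Gene id of the over-expressed TF (required downstream).
#' @param umi_k,gene_k,mito_max,qc_log_scale QC gate parameters.
#' @param scale_factor Depth-normalization target (default 10,000).
#' @param hvg_n,hvg_method Variable-gene selection (defaults 500, "vst").
#' @param pca_n_components,dims_use,pca_clip PCA parameters (100 components
#'   computed; the leading \code{dims_use} = 30 feed the neighbor graph).
#' @param snn_k,snn_prune SNN graph parameters (defaults 20, 1/15).
#' @param resolution Modularity resolution (default 1.4).
#' @param min_pct,min_fc,max_fdr,strong_fc DEG thresholds (defaults 0.25,
#'   1.5, 0.05, 2).
#' @param r2_min,require_positive Correlation-screen thresholds (defaults
#'   0.7, TRUE).
#' @param pool_mode Candidate pool: \code{"prevalence"} (genes detected in >
#'   \code{pool_min_cells_frac} of cells) or \code{"markers"} (union of all
#'   cluster up-markers).
#' @param pool_min_cells_frac Prevalence threshold (default 0.10).
#' @param seed Global integer seed.
#' @return A \code{RunConfig} list.
#' @export
run_config <- function(tf_gene,
                       umi_k = 2.0, gene_k = 2.0, mito_max = 0.10,
                       qc_log_scale = FALSE,
                       scale_factor = 1e4,
                       hvg_n = 500L, hvg_method = "vst",
                       pca_n_components = 100L, dims_use = 30L, pca_clip = 10.0,
                       snn_k = 20L, snn_prune = 1 / 15,
                       resolution = 1.4,
                       min_pct = 0.25, min_fc = 1.5, max_fdr = 0.05,
                       strong_fc = 2.0,
                       r2_min = 0.7, require_positive = TRUE,
                       pool_mode = c("prevalence", "markers"),
                       pool_min_cells_frac = 0.10,
                       seed = 1L) {
  if (missing(tf_gene) || !is.character(tf_gene) || length(tf_gene) != 1L)
    sctf_config_error("tf_gene must be a single gene id")
  pool_mode <- match.arg(pool_mode)
  structure(list(
    tf_gene = tf_gene, umi_k = umi_k, gene_k = gene_k, mito_max = mito_max,
    qc_log_scale = qc_log_scale, scale_factor = scale_factor,
    hvg_n = as.integer(hvg_n), hvg_method = hvg_method,
    pca_n_components = as.integer(pca_n_components),
    dims_use = as.integer(dims_use), pca_clip = pca_clip,
    snn_k = as.integer(snn_k), snn_prune = snn_prune,
    resolution = resolution, min_pct = min_pct, min_fc = min_fc,
    max_fdr = max_fdr, strong_fc = strong_fc, r2_min = r2_min,
    require_positive = require_positive, pool_mode = pool_mode,
    pool_min_cells_frac = pool_min_cells_frac, seed = as.integer(seed)
  ), class = "RunConfig")
}

derive_seed <- function(seed, stage) {
  offs <- c(pca = 101L, cluster = 202L, embed = 303L)
  seed + offs[[stage]]
}

#' Run the full target-prediction pipeline
#'
#' Executes every stage on a \code{CountMatrix} and returns all intermediate
#' results plus a manifest with one entry per stage recording the realized
#' parameters, dimensions and warnings. If \code{out_dir} is given, result
#' tables (TSV), the manifest and the resolved configuration (JSON) are
#' written there.
#'
#' @param m A \code{CountMatrix}.
#' @param config A \code{RunConfig}.
#' @param out_dir Optional output directory.
#' @return A \code{PipelineResult} list: \code{qc}, \code{normalized},
#'   \code{hvg}, \code{pca}, \code{snn}, \code{clusters}, \code{profiles},
#'   \code{extremes}, \code{deg}, \code{correlation}, \code{calls},
#'   \code{manifest}, \code{config}.
#' @export
run_pipeline <- function(m, config, out_dir = NULL) {
  stopifnot(inherits(m, "CountMatrix"), inherits(config, "RunConfig"))
  manifest <- list()
  note <- function(stage, ...) {
    manifest[[stage]] <<- c(list(stage = stage), list(...))
  }

  qc <- apply_qc(m, umi_k = config$umi_k, gene_k = config$gene_k,
                 mito_max = config$mito_max, log_scale = config$qc_log_scale)
  note("qc", n_cells = qc$report$n_cells_retained,
       n_genes = qc$report$n_genes_retained,
       umi_band = unname(qc$report$umi_band[c("lo", "hi")]),
       gene_band = unname(qc$report$gene_band[c("lo", "hi")]),
       mito_max = config$mito_max)

  if (!config$tf_gene %in% qc$matrix$genes$gene_id)
    sctf_premise_error(sprintf(
      "TF gene %s absent after QC: no TF expression to contrast", config$tf_gene))

  nm <- log_normalize(qc$matrix, scale_factor = config$scale_factor)
  note("normalize", scale_factor = config$scale_factor)

  hvg <- select_variable_genes(qc$matrix, n = config$hvg_n,
                               method = config$hvg_method)
  note("hvg", n_selected = hvg$n_selected, method = hvg$method)

  pca <- scale_and_pca(nm, hvg, n_components = config$pca_n_components,
                       clip = config$pca_clip,
                       seed = derive_seed(config$seed, "pca"))
  note("pca", n_components = pca$n_components, dims_use = config$dims_use,
       clip = config$pca_clip)

  snn <- build_snn_graph(pca, dims_use = config$dims_use, k = config$snn_k,
                         prune = config$snn_prune)
  note("snn", k = config$snn_k, prune = config$snn_prune,
       n_edges = length(snn$adjacency@x) / 2)

  clusters <- louvain_cluster(snn, resolution = config$resolution,
                              seed = derive_seed(config$seed, "cluster"))
  note("cluster", resolution = config$resolution,
       n_clusters = clusters$n_clusters, sizes = clusters$sizes)

  profiles <- cluster_profiles(nm, clusters)
  extremes <- extreme_clusters(profiles, config$tf_gene)
  note("extreme_clusters", lo = extremes$lo, hi = extremes$hi)

  deg <- deg_between(nm, clusters, cluster_lo = extremes$lo,
                     cluster_hi = extremes$hi, min_pct = config$min_pct,
                     min_fc = config$min_fc, max_fdr = config$max_fdr,
                     strong_fc = config$strong_fc)
  note("deg", tier_all = length(deg$tier_all), tier_up = length(deg$tier_up),
       tier_strong = length(deg$tier_strong))

  pool <- if (config$pool_mode == "prevalence") {
    default_candidate_pool(nm, min_cells_frac = config$pool_min_cells_frac,
                           exclude = config$tf_gene)
  } else {
    labs <- sort(unique(clusters$labels))
    mk <- lapply(labs, function(cl)
      find_markers(nm, clusters, cl, min_pct = config$min_pct,
                   min_fc = config$min_fc, max_fdr = config$max_fdr)$gene_id)
    pool <- setdiff(unique(unlist(mk)), config$tf_gene)
    if (length(pool) == 0L) sctf_data_error("empty candidate pool (markers mode)")
    pool
  }
  note("candidate_pool", mode = config$pool_mode, n_candidates = length(pool))

  corr <- correlation_screen(profiles, config$tf_gene, pool,
                             r2_min = config$r2_min,
                             require_positive = config$require_positive)
  note("correlation", n_pass = sum(corr$pass), r2_min = config$r2_min)

  calls <- call_targets(corr, deg, config$tf_gene)
  note("calls", n_final = sum(calls$final_call))

  result <- structure(list(qc = qc, normalized = nm, hvg = hvg, pca = pca,
                           snn = snn, clusters = clusters, profiles = profiles,
                           extremes = extremes, deg = deg, correlation = corr,
                           calls = calls, manifest = unname(manifest),
                           config = config),
                      class = "PipelineResult")
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    sctf_io_error(sprintf("cannot create directory: %s", out_dir))
  write_table(result$qc$report$cells, file.path(out_dir, "qc_report.tsv"))
  write_table(data.frame(barcode = result$clusters$barcodes,
                         cluster = result$clusters$labels,
                         stringsAsFactors = FALSE),
              file.path(out_dir, "clusters.tsv"))
  prof <- data.frame(gene_id = rownames(result$profiles$means),
                     result$profiles$means, check.names = FALSE,
                     stringsAsFactors = FALSE)
  write_table(prof, file.path(out_dir, "cluster_profiles.tsv"))
  write_table(result$deg$records, file.path(out_dir, "deg_tiers.tsv"))
  write_table(result$correlation, file.path(out_dir, "correlation.tsv"))
  write_table(result$calls, file.path(out_dir, "target_calls.tsv"))
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(unclass(result$config),
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.PipelineResult <- function(x, ...) {
  cat(sprintf(
    "PipelineResult: %d cells, %d clusters (lo=%d, hi=%d); DEG tiers %d/%d/%d; %d correlated; %d final calls\n",
    length(x$clusters$labels), x$clusters$n_clusters,
    x$extremes$lo, x$extremes$hi,
    length(x$deg$tier_all), length(x$deg$tier_up), length(x$deg$tier_strong),
    sum(x$correlation$pass), sum(x$calls$final_call)))
  invisible(x)
}
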