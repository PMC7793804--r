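Package: sctftarget
Title: Transcription Factor Target Prediction from Single-Cell Transient
    Overexpression RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts candidate target genes of a transcription factor (TF)
    from droplet single-cell RNA-seq of cells transiently over-expressing the
    TF. Per-cell plasmid dose heterogeneity creates a natural expression
    gradient; the pipeline performs cell quality control (Gaussian mean +/- 2
    SD gates on UMI and gene counts, mitochondrial-fraction gate), depth
    normalization, variable-gene selection, PCA, shared-nearest-neighbor graph
    clustering by modularity optimization, and then combines a cluster-mean
    Pearson correlation screen against the TF with tiered differential
    expression between the lowest- and highest-TF clusters to call targets.
    Includes a NAC-family CGT[GA] promoter core-motif scanner and a
    negative-binomial simulator of transient-overexpression experiments with
    planted ground-truth targets for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    igraph,
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster,
    optparse,
    yaml
Config/testthat/edition: 3
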