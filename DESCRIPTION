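Package: peakbench
Title: Benchmarking Framework for ChIP-Seq Peak Sets and Coverage Tracks
Version: 0.1.0
Authors@R:
    person("peakbench", "developers", email = "peakbench@example.org",
           role = c("aut", "cre"))
Description: Window-based evaluation of ChIP-seq peak calls against reference
    datasets: peaks are mapped to fixed non-overlapping genomic windows to
    compute ROC and precision-recall curves with AUC and a scored-recall
    validity flag, Jaccard-index similarity matrices with average-linkage
    clusterograms, maxgap overlap accounting and replicate-consensus merging,
    FDR-quantile peak recovery, saturation-of-recall at subsampled depths,
    matched random control regions, binned replicate correlation, metagene and
    peak-centered coverage profiles with standard errors, and a fully seeded
    synthetic ChIP-seq generator (genome, genes, point-source and broad
    enrichment domains, fragments, and a Poisson surrogate peak caller with
    Benjamini-Hochberg q-values) so the entire pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
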