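# Shared end-to-end fixture: a small simulated benchmark (3 replicate peak
# sets + genome) and a JSON config pointing at it.

make_bench_inputs <- function(dir, seed = 21) {
  cfg <- sim_config(chrom_sizes = chrom_sizes(c(b1 = 3e5, b2 = 2e5)),
                    n_genes = 80, n_fragments = 4e4, seed = seed)
  gg <- simulate_genome_and_genes(cfg)
  truth <- simulate_truth(cfg, gg$genes)
  write_chrom_sizes(gg$chrom_sizes, file.path(dir, "genome.sizes"))
  for (r in 1:3) {
    reads <- simulate_fragments(truth, cfg, r)
    pk <- call_peaks_poisson(reads, gg$chrom_sizes, q_cutoff = 0.5)
    write_peaks(pk, file.path(dir, sprintf("rep%d.narrowPeak", r)))
  }
  list(cfg = cfg, dir = dir)
}

write_bench_config <- function(dir, path, extra_analysis = list()) {
  cfg <- list(
    genome = file.path(dir, "genome.sizes"),
    datasets = list(
      list(label = "ref1", peaks = file.path(dir, "rep1.narrowPeak"),
           dialect = "narrowPeak", role = "reference-replicate"),
      list(label = "ref2", peaks = file.path(dir, "rep2.narrowPeak"),
           dialect = "narrowPeak", role = "reference-replicate"),
      list(label = "cand", peaks = file.path(dir, "rep3.narrowPeak"),
           dialect = "narrowPeak", role = "candidate")),
    analysis = c(list(window_size = 1000, maxgap = 200), extra_analysis))
  jsonlite::write_json(cfg, path, auto_unbox = TRUE)
  path
}
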