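test_that("find_overlaps applies the maxgap partner rule", {
  A <- peaks("chr1", 100, 200)
  B <- peaks("chr1", 150, 250)
  ov <- find_overlaps(A, B, 0)
  expect_equal(ov$nA_hit, 1)
  expect_equal(ov$components[["both"]], 1)
  expect_equal(ov$pctA, 1.0)

  B <- peaks("chr1", 250, 300)
  ov <- find_overlaps(A, B, 100)  # gap 50 <= 100
  expect_equal(ov$nA_hit, 1)

  B <- peaks("chr1", 350, 400)
  ov <- find_overlaps(A, B, 100)  # gap 150 > 100
  expect_equal(ov$nA_hit, 0)
  expect_equal(ov$components[["onlyA"]], 1)
  expect_equal(ov$components[["onlyB"]], 1)
  expect_error(find_overlaps(A, B, -1), "maxgap")
})

test_that("find_overlaps at maxgap 0 matches the O(n^2) oracle", {
  withr::local_seed(37)
  cs <- test_sizes()
  for (i in 1:5) {
    A <- rand_peaks(200, cs)
    B <- rand_peaks(300, cs)
    oracle <- brute_partner_pairs(A, B, 0)
    ov <- find_overlaps(A, B, 0)
    expect_equal(ov$nA_hit, length(unique(oracle[, 1])))
    expect_equal(ov$nB_hit, length(unique(oracle[, 2])))
  }
})

test_that("hit counts and both-components are monotone in maxgap", {
  withr::local_seed(41)
  cs <- test_sizes()
  for (i in 1:5) {
    A <- rand_peaks(80, cs)
    B <- rand_peaks(80, cs)
    # component counts are NOT monotone (both-components can merge into
    # one), so monotonicity is asserted on partner hit counts only
    prev_hitA <- -1; prev_hitB <- -1
    for (mg in c(0, 100, 200, 4000)) {
      ov <- find_overlaps(A, B, mg)
      expect_gte(ov$nA_hit, prev_hitA)
      expect_gte(ov$nB_hit, prev_hitB)
      prev_hitA <- ov$nA_hit; prev_hitB <- ov$nB_hit
    }
  }
})

test_that("merge_replicates keeps cross-replicate unions with best q", {
  r1 <- peaks("chr1", c(100, 1000), c(200, 1100), q = c(3, 5))
  r2 <- peaks("chr1", 150, 250, q = 5)
  cons <- merge_replicates(r1, r2)
  expect_equal(nrow(cons), 1)             # lone rep1 peak dropped
  expect_equal(cons$start, 100)
  expect_equal(cons$end, 250)             # coordinate union
  expect_equal(cons$q, 5)                 # best member significance

  # FDR cutoff needs q
  r3 <- peaks("chr1", 100, 200)
  expect_error(merge_replicates(r3, r3, fdr_cutoff = 0.05), "q values")

  # cutoff drops sub-threshold members before matching
  r1 <- peaks("chr1", 100, 200, q = 1)    # fails -log10(0.05)
  r2 <- peaks("chr1", 150, 250, q = 5)
  expect_equal(nrow(merge_replicates(r1, r2, fdr_cutoff = 0.05)), 0)

  # self-merged: no two output peaks within maxgap of each other
  withr::local_seed(43)
  cs <- test_sizes()
  a <- rand_peaks(150, cs); a$q <- runif(150, 2, 10)
  b <- rand_peaks(150, cs); b$q <- runif(150, 2, 10)
  cons <- merge_replicates(a, b, fdr_cutoff = 0.05, maxgap = 100)
  if (nrow(cons) > 1) {
    self <- brute_partner_pairs(cons, cons, 100)
    expect_true(all(self[, 1] == self[, 2]))
  }
})

test_that("fdr_quantile_recovery partitions and scores the hand case", {
  # 20 candidates: the 10 most significant overlap the reference
  ref <- peaks("chr1", seq(0, 9) * 1000, seq(0, 9) * 1000 + 500)
  cand <- peaks("chr1", c(seq(0, 9) * 1000, seq(50, 59) * 1000),
                c(seq(0, 9) * 1000 + 400, seq(50, 59) * 1000 + 400),
                q = c(seq(20, 11), seq(10, 1)))
  qr <- fdr_quantile_recovery(cand, ref, maxgap = 0, n_quantiles = 10)
  expect_equal(qr$n, rep(2, 10))
  expect_equal(qr$fraction, c(rep(1, 5), rep(0, 5)))

  # all candidates overlapping -> all fractions 1
  qr <- fdr_quantile_recovery(cand[1:10, ], ref, maxgap = 0,
                              n_quantiles = 5)
  expect_equal(qr$fraction, rep(1, 5))

  # remainder goes to the lowest-FDR blocks
  qr <- fdr_quantile_recovery(cand[1:7, ], ref, n_quantiles = 3)
  expect_equal(qr$n, c(3, 2, 2))

  expect_error(fdr_quantile_recovery(cand, empty_peaks()), "empty")
  expect_error(fdr_quantile_recovery(peaks("chr1", 0, 10), ref), "q value")
})

test_that("quantile recovery decreases with FDR on enrichment-led q", {
  # candidates at true regions carry q correlated with enrichment; decoys get
  # low q; reference = the true regions
  run_once <- function(seed) {
    withr::local_seed(seed)
    n_true <- 60; n_decoy <- 60
    true_start <- seq_len(n_true) * 2000
    e <- rlnorm(n_true, log(8), 0.5)
    cand_true <- peaks("chr1", true_start, true_start + 500,
                       q = pmax(3 * log2(e) + rnorm(n_true, 0, 1), 0))
    decoy_start <- 5e5 + seq_len(n_decoy) * 2000
    cand_decoy <- peaks("chr1", decoy_start, decoy_start + 500,
                        q = pmax(rnorm(n_decoy, 1, 0.5), 0))
    cand <- peaks(c(cand_true$chrom, cand_decoy$chrom),
                  c(cand_true$start, cand_decoy$start),
                  c(cand_true$end, cand_decoy$end),
                  q = c(cand_true$q, cand_decoy$q))
    ref <- peaks("chr1", true_start, true_start + 500)
    qr <- fdr_quantile_recovery(cand, ref, maxgap = 0, n_quantiles = 10)
    qr$fraction[1] > qr$fraction[10]
  }
  wins <- sum(vapply(1:40, run_once, logical(1)))
  expect_gte(wins, 38)  # >= 95% of seeded runs
})

test_that("saturation_recall is 1 for the full set and 0 for empty", {
  full <- peaks("chr1", c(100, 1000, 2000), c(200, 1100, 2100))
  sub <- full[1:2, ]
  sat <- saturation_recall(full, list(d100 = full, d50 = sub,
                                      d0 = empty_peaks()))
  expect_equal(sat$fraction, c(1, 2 / 3, 0))
  # nested sets give a non-decreasing curve
  expect_true(all(diff(rev(sat$fraction)) >= 0))
  expect_error(saturation_recall(empty_peaks(), list(a = full)), "empty")
})

test_that("partition_unique_common accounts for every peak exactly once", {
  A <- peaks("chr1", c(100, 5000, 9000), c(200, 5100, 9100))
  B <- peaks("chr1", c(150, 20000, 30000), c(250, 20100, 30100))
  part <- partition_unique_common(A, B, 0)
  expect_equal(nrow(part$A_common), 1)
  expect_equal(nrow(part$A_only), 2)
  expect_equal(nrow(part$B_common), 1)
  expect_equal(nrow(part$B_only), 2)
  expect_equal(nrow(part$A_only) + nrow(part$A_common), nrow(A))

  # disjoint chromosomes -> all unique; identical sets -> all common
  C <- peaks("chr2", 100, 200)
  expect_equal(nrow(partition_unique_common(A, C, 0)$A_common), 0)
  expect_equal(nrow(partition_unique_common(A, A, 0)$A_only), 0)
})

test_that("random_matched_regions preserves lengths and avoids exclusions", {
  cs <- chrom_sizes(c(chr1 = 100000))
  tmpl <- peaks("chr1", c(100, 5000), c(600, 7000))
  r1 <- random_matched_regions(tmpl, cs, seed = 9)
  expect_equal(r1$end - r1$start, tmpl$end - tmpl$start)
  expect_identical(r1, random_matched_regions(tmpl, cs, seed = 9))

  # exclusions covering half the chromosome are never intersected
  excl <- data.frame(chrom = "chr1", start = 0, end = 50000)
  withr::local_seed(1)
  many <- peaks("chr1", seq(0, 49) * 100, seq(0, 49) * 100 + 80)
  rr <- random_matched_regions(many, cs, exclusions = excl, seed = 13)
  expect_true(all(gap(rr, excl) > 0))

  expect_error(random_matched_regions(peaks("chr1", 0, 100000), cs,
                                      seed = 1), "longer than")
})

test_that("region_read_coverage matches brute-force counting", {
  regions <- data.frame(chrom = "chr1", start = c(0, 1000),
                        end = c(500, 1500))
  expect_equal(region_read_coverage(read_set(), regions)$counts, c(0, 0))
  rs <- read_set("chr1", 100, 200)
  expect_equal(region_read_coverage(rs, regions)$counts, c(1, 0))

  withr::local_seed(47)
  cs <- test_sizes()
  frs <- rand_peaks(1000, cs, max_len = 300)
  rs <- read_set(frs$chrom, frs$start, frs$end)
  regs <- rand_peaks(50, cs, max_len = 2000)
  got <- region_read_coverage(rs, regs)$counts
  oracle <- vapply(seq_len(nrow(regs)), function(i) {
    sum(rs$fragments$chrom == regs$chrom[i] &
          rs$fragments$start < regs$end[i] &
          rs$fragments$end > regs$start[i])
  }, numeric(1))
  expect_equal(got, oracle)
})

test_that("annotate_peaks assigns promoter, gene body and intergenic", {
  gn <- genes(c("chr1", "chr1"), c(10000, 50000), c(20000, 60000),
              c("gA", "gB"), c("+", "-"))
  # summit 500 bp upstream of gA's TSS -> promoter
  pk <- peaks("chr1", 9000, 10000, summit = 500)
  ann <- annotate_peaks(pk, gn)
  expect_equal(ann$category, "Promoter")
  expect_equal(ann$nearest_gene, "gA")
  expect_equal(ann$distance, -500)

  # mid-gene, 5 kb from TSS -> gene body
  ann <- annotate_peaks(peaks("chr1", 14000, 16000, summit = 1000), gn)
  expect_equal(ann$category, "GeneBody")

  # far from any gene -> distal intergenic
  ann <- annotate_peaks(peaks("chr1", 80000, 80200), gn)
  expect_equal(ann$category, "DistalIntergenic")

  # minus-strand promoter: TSS at end = 60000, anchor slightly inside
  ann <- annotate_peaks(peaks("chr1", 59500, 60500), gn)
  expect_equal(ann$category, "Promoter")
  expect_equal(ann$nearest_gene, "gB")

  expect_error(annotate_peaks(pk, gn[0, ]), "empty gene set")
})
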