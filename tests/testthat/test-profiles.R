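const_track <- function(value, cs) {
  coverage_track(lapply(setNames(as.numeric(cs), names(cs)),
                        function(l) S4Vectors::Rle(value, l)), cs)
}

test_that("bin_track averages per-base coverage, partial bin included", {
  cs <- chrom_sizes(c(chr1 = 20))
  f <- withr::local_tempfile()
  writeLines("chr1\t0\t10\t2", f)
  tr <- read_bedgraph(f, cs)
  bt <- bin_track(tr, 20, cs)
  expect_equal(bt$value, 1.0)   # weighted mean of 2 and 0

  # constant track -> every bin the constant; partial final bin too
  cs <- chrom_sizes(c(chr1 = 4500))
  bt <- bin_track(const_track(3.5, cs), 2000, cs)
  expect_equal(bt$value, rep(3.5, 3))
  expect_equal(bt$end[3] - bt$start[3], 500)
  expect_error(bin_track(const_track(1, cs), 0, cs), "bin_size")
})

test_that("bin_track conserves the genome-wide mean exactly", {
  withr::local_seed(53)
  cs <- test_sizes()
  frs <- rand_peaks(400, cs, 300)
  tr <- coverage_from_fragments(read_set(frs$chrom, frs$start, frs$end), cs)
  bt <- bin_track(tr, 977, cs)  # deliberately awkward bin size
  lens <- bt$end - bt$start
  expect_equal(sum(bt$value * lens) / sum(lens),
               track_total(tr) / genome_length(cs))
})

test_that("pearson_bins matches closed forms and rejects degeneracy", {
  cs <- chrom_sizes(c(chr1 = 4000))
  f <- withr::local_tempfile()
  writeLines("chr1\t0\t2000\t1", f)
  a <- bin_track(read_bedgraph(f, cs), 2000, cs)     # (1, 0)
  writeLines("chr1\t2000\t4000\t1", f)
  b <- bin_track(read_bedgraph(f, cs), 2000, cs)     # (0, 1)
  expect_equal(pearson_bins(a, b), -1)

  withr::local_seed(59)
  cs <- test_sizes()
  frs <- rand_peaks(500, cs, 300)
  tr <- bin_track(coverage_from_fragments(
    read_set(frs$chrom, frs$start, frs$end), cs), 500, cs)
  expect_equal(pearson_bins(tr, tr), 1)

  # affine rescaling leaves r unchanged
  tr2 <- tr; tr2$value <- 3 * tr2$value + 2
  expect_equal(pearson_bins(tr, tr2), 1)

  flat <- bin_track(const_track(1, cs), 500, cs)
  expect_error(pearson_bins(tr, flat), "zero variance")
  expect_error(pearson_bins(tr, bin_track(const_track(1, cs), 250, cs)),
               "identically binned")
})

test_that("pearson_bins of a track against its shuffle is near zero", {
  withr::local_seed(7)
  cs <- chrom_sizes(c(c1 = 2.5e6))
  frs <- rand_peaks(5000, cs, 300)
  a <- bin_track(coverage_from_fragments(
    read_set(frs$chrom, frs$start, frs$end), cs), 500, cs)  # 5000 bins
  b <- a
  b$value <- sample(b$value)
  expect_lt(abs(pearson_bins(a, b)), 0.05)
})

test_that("metagene of a constant track is flat with zero SEM", {
  cs <- chrom_sizes(c(chr1 = 100000))
  gn <- genes(rep("chr1", 3), c(10000, 40000, 70000),
              c(15000, 44000, 76000), paste0("g", 1:3), c("+", "-", "+"))
  mg <- metagene(const_track(2.5, cs), gn)
  expect_equal(ncol(mg$matrix), 2 * 50 + 100)
  expect_equal(unname(mg$summary$mean), rep(2.5, 200))
  expect_equal(unname(mg$summary$sem), rep(0, 200))
})

test_that("metagene separates body from flank signal and is strand-aware", {
  cs <- chrom_sizes(c(chr1 = 100000))
  gn <- genes("chr1", 40000, 50000, "g1", "+")
  f <- withr::local_tempfile()
  writeLines("chr1\t40000\t50000\t4", f)  # elevated only inside the body
  tr <- read_bedgraph(f, cs)
  mg <- metagene(tr, gn)
  body_cols <- grep("^body_", mg$columns)
  flank_cols <- grep("^flank", mg$columns)
  expect_true(min(mg$matrix[1, body_cols]) >
                max(mg$matrix[1, flank_cols]))

  # mirror test: reflecting genome and strand reverses the row elementwise
  L <- 100000
  gn_m <- genes("chr1", L - 50000, L - 40000, "g1", "-")
  writeLines(c("chr1\t50000\t52000\t7", "chr1\t40000\t50000\t4"), f)
  tr <- read_bedgraph(f, cs)
  writeLines(c(paste("chr1", L - 52000, L - 50000, 7, sep = "\t"),
               paste("chr1", L - 50000, L - 40000, 4, sep = "\t")), f)
  tr_m <- read_bedgraph(f, cs)
  mg_p <- metagene(tr, gn)
  mg_m <- metagene(tr_m, gn_m)
  expect_equal(mg_m$matrix[1, ], mg_p$matrix[1, ],
               ignore_attr = TRUE)

  # short genes are flagged and excluded, never padded
  gn2 <- genes(c("chr1", "chr1"), c(40000, 60000), c(50000, 60050),
               c("a", "b"), c("+", "+"))
  mg2 <- metagene(tr, gn2)
  expect_identical(mg2$flagged, c(FALSE, TRUE))
  expect_error(metagene(tr, gn2[2, ]), "no retained genes")
})

test_that("log2fc_profile matches the closed form and is shape-strict", {
  cs <- chrom_sizes(c(chr1 = 100000))
  gn <- genes("chr1", 40000, 50000, "g1", "+")
  sig <- metagene(const_track(0.9, cs), gn)
  ctl <- metagene(const_track(0, cs), gn)
  fc <- log2fc_profile(sig, ctl, pseudocount = 0.1)
  expect_equal(unname(fc$matrix[1, 1]), log2(1.0 / 0.1), tolerance = 1e-12)

  same <- log2fc_profile(sig, sig)
  expect_true(all(same$matrix == 0))

  # ratio invariance in the psi -> 0 limit
  s2 <- metagene(const_track(1.8, cs), gn)
  c2 <- metagene(const_track(0.6, cs), gn)
  s1 <- metagene(const_track(0.9, cs), gn)
  c1 <- metagene(const_track(0.3, cs), gn)
  fc1 <- log2fc_profile(s1, c1, pseudocount = 1e-9)
  fc2 <- log2fc_profile(s2, c2, pseudocount = 1e-9)
  expect_equal(fc1$matrix, fc2$matrix, tolerance = 1e-6)

  bad <- metagene(const_track(1, cs), gn, body_bins = 50)
  expect_error(log2fc_profile(sig, bad), "shape mismatch")
})

test_that("peak_centered bins, flags edges and sorts by the sort track", {
  cs <- chrom_sizes(c(chr1 = 100000))
  pk <- peaks("chr1", c(20000, 60000), c(20400, 60400), name = c("lo", "hi"),
              summit = c(200, 200))
  f <- withr::local_tempfile()
  writeLines(c("chr1\t19000\t21000\t1", "chr1\t59000\t61000\t5"), f)
  tr <- read_bedgraph(f, cs)
  pm <- peak_centered(tr, pk, half_width = 1000, bin = 10)
  expect_equal(ncol(pm$matrix), 200)
  expect_identical(rownames(pm$matrix), c("lo", "hi"))  # input order kept

  srt <- peak_centered(tr, pk, half_width = 1000, bin = 10, sort_by = tr)
  expect_identical(rownames(srt$matrix), c("hi", "lo"))
  # sorting is a permutation: row means unchanged as a set
  expect_equal(sort(rowMeans(srt$matrix)), sort(rowMeans(pm$matrix)))

  # edge peak is flagged
  edge <- peaks("chr1", 0, 400, name = "edge", summit = 100)
  pe <- peak_centered(tr, edge, half_width = 1000, bin = 10)
  expect_true(pe$flagged[1])

  # constant track: all rows identical and the sort is stable
  cm <- peak_centered(const_track(2, cs), pk, sort_by = const_track(2, cs))
  expect_identical(rownames(cm$matrix), c("lo", "hi"))
  expect_true(all(cm$matrix == 2))
  expect_error(peak_centered(tr, pk, half_width = 5, bin = 10), "half_width")
})
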