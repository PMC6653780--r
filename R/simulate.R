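#' Simulation configuration
#'
#' The stated world for synthetic ChIP-seq data: a small multi-chromosome
#' genome, lognormal gene lengths, point-source (H3K4Me3-like promoter
#' regions) or broad (H3K9Me3/H3K27Me3-like domain) enrichment with lognormal
#' per-region enrichment factors `e >= 1`, lognormal replicate-to-replicate
#' noise on `e`, uniform Poisson background fragments and a truncated-normal
#' fragment length.
#'
#' @param chrom_sizes genome; default three chromosomes totalling 1 Mb.
#' @param n_genes number of genes to place.
#' @param gene_meanlog,gene_sdlog lognormal gene-length parameters (bp).
#' @param mark_type `"point"` (promoter regions at TSS +/- 500) or `"broad"`
#'   (long domains).
#' @param frac_marked fraction of genes carrying the point mark.
#' @param n_domains,domain_range broad mode: number of domains and their
#'   length range in bp.
#' @param enrich_meanlog,enrich_sdlog lognormal enrichment-factor parameters
#'   (natural-log scale); draws are clipped to `>= 1`.
#' @param rep_noise_sd lognormal sd (tau) multiplying each region's `e` per
#'   replicate.
#' @param n_fragments fragments per replicate.
#' @param frag_mean,frag_sd,frag_min fragment-length Normal(200, 20) with a
#'   50 bp floor.
#' @param seed mandatory integer master seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(chrom_sizes = peakbench::chrom_sizes(
                         c(chrS1 = 5e5, chrS2 = 3e5, chrS3 = 2e5)),
                       n_genes = 200,
                       gene_meanlog = log(2000), gene_sdlog = 0.5,
                       mark_type = c("point", "broad"),
                       frac_marked = 0.2,
                       n_domains = 30, domain_range = c(5000, 20000),
                       enrich_meanlog = log(8), enrich_sdlog = 0.5,
                       rep_noise_sd = 0.2,
                       n_fragments = 1e5,
                       frag_mean = 200, frag_sd = 20, frag_min = 50,
                       seed) {
  mark_type <- match.arg(mark_type)
  if (missing(seed)) stop("sim_config: seed is mandatory")
  stopifnot(n_genes >= 0, n_fragments >= 0, frac_marked >= 0,
            frac_marked <= 1, rep_noise_sd >= 0, n_domains >= 0,
            frag_min >= 1)
  structure(list(chrom_sizes = chrom_sizes, n_genes = n_genes,
                 gene_meanlog = gene_meanlog, gene_sdlog = gene_sdlog,
                 mark_type = mark_type, frac_marked = frac_marked,
                 n_domains = n_domains, domain_range = domain_range,
                 enrich_meanlog = enrich_meanlog,
                 enrich_sdlog = enrich_sdlog,
                 rep_noise_sd = rep_noise_sd, n_fragments = n_fragments,
                 frag_mean = frag_mean, frag_sd = frag_sd,
                 frag_min = frag_min, seed = as.integer(seed)),
            class = "sim_config")
}

## uniform genome position -> (chrom, pos); u in [0, genome_length)
position_on_genome <- function(u, chrom_sizes) {
  len <- as.numeric(chrom_sizes)
  cum <- cumsum(len)
  ci <- findInterval(u, c(0, cum), rightmost.closed = FALSE)
  list(chrom = names(chrom_sizes)[ci], pos = u - c(0, cum)[ci])
}

#' Simulate a genome's gene models
#'
#' Places `n_genes` non-overlapping genes uniformly on the configured genome
#' by rejection sampling (lengths lognormal, floored at 200 bp and capped at
#' half the smallest chromosome), strands Bernoulli(1/2).  Deterministic
#' given the config seed.
#'
#' @param cfg a [sim_config()].
#' @return list with `chrom_sizes` and `genes`.
#' @export
simulate_genome_and_genes <- function(cfg) {
  old <- local_seed(derive_seed(cfg$seed, 11))
  on.exit(restore_seed(old))
  sizes <- cfg$chrom_sizes
  if (cfg$n_genes == 0) {
    return(list(chrom_sizes = sizes,
                genes = genes(character(0), numeric(0), numeric(0),
                              character(0), character(0))))
  }
  lens <- pmin(pmax(round(rlnorm(cfg$n_genes, cfg$gene_meanlog,
                                 cfg$gene_sdlog)), 200),
               floor(min(as.numeric(sizes)) / 2))
  if (sum(lens) >= genome_length(sizes)) {
    stop("simulate_genome_and_genes: total gene length exceeds genome")
  }
  placed <- place_nonoverlapping(lens, sizes,
                                 max_tries = 200 * cfg$n_genes,
                                 what = "genes")
  strand <- ifelse(runif(cfg$n_genes) < 0.5, "+", "-")
  o <- order(match(placed$chrom, names(sizes)), placed$start)
  list(chrom_sizes = sizes,
       genes = genes(placed$chrom[o], placed$start[o], placed$end[o],
                     sprintf("gene%04d", seq_len(cfg$n_genes)), strand[o],
                     sizes))
}

## uniform rejection placement of non-overlapping intervals of given lengths
place_nonoverlapping <- function(lens, sizes, max_tries, what) {
  chrom <- character(length(lens)); start <- numeric(length(lens))
  got <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                    stringsAsFactors = FALSE)
  tries <- 0
  G <- genome_length(sizes)
  for (i in order(-lens)) {   # biggest first: placement succeeds more often
    repeat {
      tries <- tries + 1
      if (tries > max_tries) {
        stop("place_nonoverlapping: could not place all ", what,
             " after ", max_tries, " tries; reduce their number or size")
      }
      at <- position_on_genome(floor(runif(1, 0, G)), sizes)
      s <- at$pos; ch <- at$chrom
      if (s + lens[i] > unclass(sizes)[[ch]]) next
      cand <- list(chrom = ch, start = s, end = s + lens[i])
      if (nrow(got) == 0 || all(gap(cand, got) > 0)) break
    }
    chrom[i] <- ch; start[i] <- s
    got <- rbind(got, data.frame(chrom = ch, start = s, end = s + lens[i],
                                 stringsAsFactors = FALSE))
  }
  data.frame(chrom = chrom, start = start, end = start + lens,
             stringsAsFactors = FALSE)
}

#' Simulate ground-truth enrichment regions
#'
#' Point mode plants promoter regions (TSS +/- 500 bp, clipped to the
#' chromosome) on a random `frac_marked` subset of genes; broad mode places
#' `n_domains` non-overlapping domains with lengths uniform in
#' `domain_range`.  Each region draws an enrichment factor
#' `e ~ lognormal(enrich_meanlog, enrich_sdlog)` clipped to `>= 1`.  Point
#' regions that collide (adjacent genes) are dropped to keep the
#' non-overlap invariant.
#'
#' @param cfg a [sim_config()].
#' @param gn the simulated `genes` (point mode).
#' @return an object of class `synthetic_truth`: list with `mark_type` and
#'   `regions` (data.frame `chrom`, `start`, `end`, `enrichment`).
#' @export
simulate_truth <- function(cfg, gn = NULL) {
  old <- local_seed(derive_seed(cfg$seed, 23))
  on.exit(restore_seed(old))
  sizes <- cfg$chrom_sizes
  if (cfg$mark_type == "point") {
    if (is.null(gn)) stop("simulate_truth: point mode needs genes")
    k <- round(cfg$frac_marked * nrow(gn))
    pick <- sort(sample.int(nrow(gn), k))
    tss <- tss_position(gn)[pick]
    reg <- data.frame(chrom = gn$chrom[pick],
                      start = pmax(tss - 500, 0),
                      end = pmin(tss + 500, unclass(sizes)[gn$chrom[pick]]),
                      stringsAsFactors = FALSE)
  } else {
    lens <- floor(runif(cfg$n_domains, cfg$domain_range[1],
                        cfg$domain_range[2] + 1))
    reg <- if (cfg$n_domains == 0) {
      data.frame(chrom = character(), start = numeric(), end = numeric(),
                 stringsAsFactors = FALSE)
    } else {
      place_nonoverlapping(lens, sizes, max_tries = 500 * cfg$n_domains,
                           what = "broad domains")
    }
  }
  if (nrow(reg)) {
    reg$enrichment <- pmax(rlnorm(nrow(reg), cfg$enrich_meanlog,
                                  cfg$enrich_sdlog), 1)
    o <- order(match(reg$chrom, names(sizes)), reg$start)
    reg <- reg[o, , drop = FALSE]
    # drop point regions overlapping an earlier one (adjacent genes)
    keep <- rep(TRUE, nrow(reg))
    if (nrow(reg) > 1) {
      run_end <- reg$end[1]; run_chrom <- reg$chrom[1]
      for (i in 2:nrow(reg)) {
        if (reg$chrom[i] == run_chrom && reg$start[i] < run_end) {
          keep[i] <- FALSE
        } else {
          run_end <- reg$end[i]; run_chrom <- reg$chrom[i]
        }
      }
    }
    reg <- reg[keep, , drop = FALSE]
    rownames(reg) <- NULL
  } else {
    reg$enrichment <- numeric(0)
  }
  structure(list(mark_type = cfg$mark_type, regions = reg,
                 chrom_sizes = sizes), class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("synthetic_truth (", x$mark_type, "): ", nrow(x$regions),
      " region(s), mean enrichment ",
      format(mean(x$regions$enrichment), digits = 3), "\n", sep = "")
  invisible(x)
}

#' Simulate sequenced fragments for one replicate
#'
#' Per replicate, each region's enrichment is jittered as
#' `e' = e * lognormal(0, rep_noise_sd)`.  Each fragment picks its source with
#' probability proportional to weight — background weight = genome length,
#' region i weight = `length_i * (e'_i - 1)` (so `e = 1` is exactly "no
#' enrichment") — places its midpoint uniformly in the source, draws its
#' length from the truncated Normal, and is clipped to the chromosome.
#' Deterministic given `(seed, replicate_index)`.
#'
#' @param truth a [simulate_truth()] result.
#' @param cfg the [sim_config()].
#' @param replicate_index 1, 2, ... — different indices give independent
#'   replicates under the same master seed.
#' @return a [read_set()], sorted by coordinate.
#' @export
simulate_fragments <- function(truth, cfg, replicate_index = 1) {
  old <- local_seed(derive_seed(cfg$seed, 37, replicate_index))
  on.exit(restore_seed(old))
  sizes <- cfg$chrom_sizes
  n <- cfg$n_fragments
  if (n < 1) return(read_set())
  reg <- truth$regions
  e_rep <- if (nrow(reg)) {
    reg$enrichment * rlnorm(nrow(reg), 0, cfg$rep_noise_sd)
  } else numeric(0)
  w <- c(genome_length(sizes),
         if (nrow(reg)) (reg$end - reg$start) * pmax(e_rep - 1, 0))
  src <- sample.int(length(w), n, replace = TRUE, prob = w)
  mid <- numeric(n); chrom <- character(n)
  bg <- src == 1L
  if (any(bg)) {
    at <- position_on_genome(floor(runif(sum(bg), 0, genome_length(sizes))),
                             sizes)
    chrom[bg] <- at$chrom; mid[bg] <- at$pos
  }
  if (any(!bg)) {
    ri <- src[!bg] - 1L
    chrom[!bg] <- reg$chrom[ri]
    mid[!bg] <- floor(runif(sum(!bg), reg$start[ri], reg$end[ri]))
  }
  len <- pmax(round(rnorm(n, cfg$frag_mean, cfg$frag_sd)), cfg$frag_min)
  start <- pmax(mid - floor(len / 2), 0)
  end <- pmin(start + len, unclass(sizes)[chrom])
  start <- pmin(start, end - 1)   # keep >= 1 bp after clipping
  o <- order(match(chrom, names(sizes)), start, end)
  read_set(chrom[o], start[o], end[o], sizes)
}

#' Bernoulli subsampling of fragments
#'
#' Each fragment is kept independently with probability `fraction` — the
#' depth-series generator for saturation analysis.
#'
#' @param reads a [read_set()].
#' @param fraction keep probability in `[0, 1]`.
#' @param seed integer seed.
#' @return a [read_set()].
#' @export
subsample_fragments <- function(reads, fraction, seed) {
  if (fraction < 0 || fraction > 1) {
    stop("subsample_fragments: fraction must be in [0, 1]")
  }
  old <- local_seed(derive_seed(seed, 53))
  on.exit(restore_seed(old))
  keep <- runif(reads$total) < fraction
  f <- reads$fragments[keep, , drop = FALSE]
  read_set(f$chrom, f$start, f$end)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up adjusted p-values: `q_(i) = min_{j >= i} m * p_(j) / j`, capped at
#' 1.
#'
#' @param p raw p-values.
#' @return q-values in the input order.
#' @export
bh_qvalues <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  q <- pmin(rev(cummin(rev(p[o] * m / seq_len(m)))), 1)
  out <- numeric(m)
  out[o] <- q
  out
}

#' Surrogate Poisson window peak caller
#'
#' A deliberately simple stand-in for an external peak caller, used to
#' produce realistically ranked p/q peaks for testing downstream stages.
#' Fragment midpoints are counted in tiled windows; the background rate is
#' the uniform expectation `lambda = total * window / genome_length`; the
#' per-window p-value is the Poisson upper tail `P(X >= k)`; q-values are
#' Benjamini-Hochberg over all tiled windows.
#'
#' With `q_cutoff` given, significant windows within `merge_gap` windows of
#' each other merge into peaks carrying the best member p/q and the summit at
#' the centre of the highest-count window.  With `q_cutoff = NULL` (the
#' "no FDR cutoff" ROC mode) every window with at least one fragment becomes
#' its own scored peak and no merging is done — merging would collapse the
#' p-value ranking the threshold sweep needs, and dropping zero-count windows
#' is what lets a shallow dataset leave reference windows unscored.
#'
#' @param reads a [read_set()] with `total >= 1`.
#' @param chrom_sizes governing [chrom_sizes()].
#' @param window window width in bp (default 200).
#' @param q_cutoff FDR threshold on the natural scale, or `NULL`.
#' @param merge_gap merge distance in windows (default 1).
#' @return a [peaks()] data.frame sorted by coordinate, with `p`, `q`
#'   (-log10) and `summit` set; `signal` is the fold enrichment over lambda.
#' @export
call_peaks_poisson <- function(reads, chrom_sizes, window = 200,
                               q_cutoff = NULL, merge_gap = 1) {
  if (window < 1) stop("call_peaks_poisson: window must be >= 1")
  if (reads$total < 1) stop("call_peaks_poisson: no fragments")
  f <- reads$fragments
  mid <- floor((f$start + f$end) / 2)
  win <- tile_genome(chrom_sizes, window)
  idx <- match(paste0(f$chrom, ":", floor(mid / window)), win$id)
  counts <- tabulate(idx, nbins = nrow(win))
  lambda <- reads$total * window / genome_length(chrom_sizes)
  p_raw <- ppois(counts - 1, lambda, lower.tail = FALSE)
  p_raw <- pmax(p_raw, 1e-300)
  q_raw <- pmax(bh_qvalues(p_raw), 1e-300)
  plog <- -log10(p_raw); qlog <- -log10(q_raw)

  if (is.null(q_cutoff)) {
    keep <- which(counts >= 1)
    if (length(keep) == 0) return(empty_peaks())
    return(peaks(win$chrom[keep], win$start[keep], win$end[keep],
                 name = sprintf("w_%s", win$id[keep]),
                 score = pmin(round(10 * qlog[keep]), 1000),
                 strand = ".", signal = counts[keep] / lambda,
                 p = plog[keep], q = qlog[keep],
                 summit = floor((win$end[keep] - win$start[keep]) / 2)))
  }

  sig <- which(q_raw <= q_cutoff)
  if (length(sig) == 0) return(empty_peaks())
  sw <- win[sig, , drop = FALSE]
  # windows within merge_gap windows merge: allowed bp gap between
  # consecutive significant windows is merge_gap * window
  memb <- gap_clusters(sw, maxgap = merge_gap * window)
  out <- lapply(split(seq_len(nrow(sw)), memb), function(ii) {
    k <- counts[sig[ii]]
    best_w <- ii[which.max(k)]
    s <- min(sw$start[ii]); e <- max(sw$end[ii])
    data.frame(chrom = sw$chrom[ii[1]], start = s, end = e,
               p = max(plog[sig[ii]]), q = max(qlog[sig[ii]]),
               signal = max(k) / lambda,
               summit = floor((sw$start[best_w] + sw$end[best_w]) / 2) - s,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(match(out$chrom, names(chrom_sizes)), out$start), ,
             drop = FALSE]
  peaks(out$chrom, out$start, out$end,
        name = sprintf("peak_%d", seq_len(nrow(out))),
        score = pmin(round(10 * out$q), 1000), strand = ".",
        signal = out$signal, p = out$p, q = out$q, summit = out$summit)
}
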