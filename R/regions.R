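#' Random regions matched to a template peak set
#'
#' For each template peak, draws one region on the same chromosome with the
#' same length, start uniform over the valid range, rejecting candidates that
#' overlap (gap 0: intersect or abut) any exclusion interval.  After
#' `max_tries` rejections the last candidate is accepted with a warning.
#' Fully reproducible given `seed`.
#'
#' @param template [peaks()] (or any data.frame with chrom/start/end).
#' @param chrom_sizes governing [chrom_sizes()].
#' @param exclusions data.frame with chrom/start/end to avoid, or `NULL`.
#' @param seed integer seed.
#' @param max_tries rejection-sampling budget per region.
#' @return data.frame with `chrom`, `start`, `end` (one row per template row,
#'   same order, same lengths).
#' @export
random_matched_regions <- function(template, chrom_sizes, exclusions = NULL,
                                   seed, max_tries = 1000) {
  len <- template$end - template$start
  lim <- unclass(chrom_sizes)[template$chrom]
  if (any(is.na(lim))) stop("random_matched_regions: unknown chromosome")
  if (any(len >= lim)) {
    stop("random_matched_regions: template longer than its chromosome")
  }
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  n <- nrow(template)
  start <- numeric(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      s <- floor(runif(1, 0, lim[[i]] - len[[i]] + 1))
      if (is.null(exclusions) || nrow(exclusions) == 0) { ok <- TRUE }
      else {
        g <- gap(list(chrom = template$chrom[[i]], start = s,
                      end = s + len[[i]]), exclusions)
        ok <- all(g > 0)
      }
      if (ok) break
    }
    if (!ok) {
      warning("random_matched_regions: region ", i, " still overlaps ",
              "exclusions after ", max_tries, " tries; accepting it")
    }
    start[i] <- s
  }
  data.frame(chrom = template$chrom, start = start, end = start + len,
             stringsAsFactors = FALSE)
}

#' Fragment counts over regions
#'
#' Counts fragments overlapping (>= 1 bp) each region, with a quartile
#' summary for boxplot-style reporting of raw-read coverage over peak
#' classes.
#'
#' @param reads a [read_set()].
#' @param regions data.frame with chrom/start/end.
#' @return list with `counts` (integer per region) and `summary` (named:
#'   `q1`, `median`, `q3`).
#' @export
region_read_coverage <- function(reads, regions) {
  counts <- integer(nrow(regions))
  if (reads$total > 0 && nrow(regions) > 0) {
    pairs <- overlap_pairs(regions, reads$fragments, maxgap = -1)
    tab <- table(pairs[, 1])
    counts[as.integer(names(tab))] <- as.integer(tab)
  }
  qs <- if (length(counts)) stats::quantile(counts, c(0.25, 0.5, 0.75))
        else c(NA_real_, NA_real_, NA_real_)
  list(counts = counts,
       summary = c(q1 = unname(qs[1]), median = unname(qs[2]),
                   q3 = unname(qs[3])))
}

#' Annotate peaks by nearest gene
#'
#' The anchor is the peak summit when present, else the interval midpoint.
#' A peak is `Promoter` when its anchor falls in the strand-aware window
#' `[TSS - promoter_up, TSS + promoter_down)` of any gene, else `GeneBody`
#' when the anchor lies inside a gene span, else `DistalIntergenic`.  The
#' nearest gene minimises the absolute anchor-to-TSS distance (ties broken by
#' the lexicographically smaller gene id); the reported distance is signed,
#' positive downstream of the TSS in the gene's orientation.
#'
#' @param pk [peaks()] data.frame.
#' @param gn `genes` data.frame (non-empty).
#' @param promoter_up,promoter_down promoter window in bp around the TSS.
#' @return data.frame with `name`, `category`, `nearest_gene`, `distance`.
#' @export
annotate_peaks <- function(pk, gn, promoter_up = 1000, promoter_down = 1000) {
  if (nrow(gn) == 0) stop("annotate_peaks: empty gene set")
  anchor <- ifelse(pk$summit >= 0, pk$start + pk$summit,
                   floor((pk$start + pk$end) / 2))
  tss <- tss_position(gn)
  n <- nrow(pk)
  category <- character(n); nearest <- character(n); dist_out <- numeric(n)
  for (i in seq_len(n)) {
    same <- which(gn$chrom == pk$chrom[i])
    if (length(same) == 0) {
      # gene-free chromosome: nearest gene undefined on this chromosome;
      # fall back to genome-wide nearest by TSS coordinate distance = Inf
      category[i] <- "DistalIntergenic"
      nearest[i] <- NA_character_; dist_out[i] <- Inf
      next
    }
    a <- anchor[i]
    sgn <- ifelse(gn$strand[same] == "+", 1, -1)
    d_signed <- (a - tss[same]) * sgn
    d_abs <- abs(a - tss[same])
    o <- order(d_abs, gn$id[same])
    best <- same[o[1]]
    nearest[i] <- gn$id[best]
    dist_out[i] <- d_signed[o[1]]
    in_prom <- d_signed >= -promoter_up & d_signed < promoter_down
    in_body <- a >= gn$start[same] & a < gn$end[same]
    category[i] <- if (any(in_prom)) "Promoter"
                   else if (any(in_body)) "GeneBody"
                   else "DistalIntergenic"
  }
  data.frame(name = pk$name, category = category, nearest_gene = nearest,
             distance = dist_out, stringsAsFactors = FALSE)
}
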