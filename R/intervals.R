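## Shared interval helpers.  Every interval in the package is 0-based
## half-open [start, end); IRanges (1-based closed) is used internally for
## overlap queries, converting at this boundary only.

#' Genomic interval gap
#'
#' Distance in bp between two 0-based half-open intervals.  `Inf` if they lie
#' on different chromosomes; 0 if they intersect or abut; otherwise the number
#' of bases strictly between them.  Abutting intervals (`[x,y)`, `[y,z)`) have
#' gap 0, so they count as overlapping at any maxgap >= 0.
#'
#' Arguments are recycled, so `gap()` is vectorised over pairs.
#'
#' @param a,b intervals: lists or data.frames with `chrom`, `start`, `end`.
#' @return numeric vector of gaps (bp, possibly `Inf`).
#' @examples
#' gap(list(chrom = "chr1", start = 100, end = 200),
#'     list(chrom = "chr1", start = 250, end = 300))  # 50
#' @export
gap <- function(a, b) {
  d <- pmax(a$start, b$start) - pmin(a$end, b$end)
  d <- pmax(d, 0)
  d[a$chrom != b$chrom] <- Inf
  as.numeric(d)
}

## 0-based half-open -> IRanges (1-based closed)
as_iranges0 <- function(start, end) {
  IRanges::IRanges(start = as.integer(start) + 1L, end = as.integer(end))
}

## All pairs (i, j) with gap(x[i], y[j]) <= maxgap; x, y are data.frames with
## chrom/start/end.  Returns a 2-column integer matrix (query, subject).
## maxgap = -1 requests strict (>= 1 bp) intersection, as in IRanges.
overlap_pairs <- function(x, y, maxgap = 0) {
  stopifnot(maxgap >= -1)
  out_q <- integer(0); out_s <- integer(0)
  for (ch in intersect(unique(x$chrom), unique(y$chrom))) {
    qi <- which(x$chrom == ch)
    si <- which(y$chrom == ch)
    hits <- IRanges::findOverlaps(as_iranges0(x$start[qi], x$end[qi]),
                                  as_iranges0(y$start[si], y$end[si]),
                                  maxgap = maxgap)
    out_q <- c(out_q, qi[S4Vectors::queryHits(hits)])
    out_s <- c(out_s, si[S4Vectors::subjectHits(hits)])
  }
  cbind(query = out_q, subject = out_s)
}

## Cluster intervals whose transitive gap-<=maxgap closure connects them.
## Returns an integer membership vector (cluster ids in coordinate order).
gap_clusters <- function(x, maxgap = 0) {
  n <- nrow(x)
  memb <- integer(n)
  cl <- 0L
  for (ch in unique(x$chrom)) {
    idx <- which(x$chrom == ch)
    idx <- idx[order(x$start[idx], x$end[idx])]
    run_end <- -Inf
    for (i in idx) {
      if (x$start[i] > run_end + maxgap) cl <- cl + 1L
      memb[i] <- cl
      run_end <- max(run_end, x$end[i])
    }
  }
  memb
}
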