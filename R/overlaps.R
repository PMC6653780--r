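#' Maxgap overlap accounting between two peak sets
#'
#' Two peaks are partners iff their [gap()] is at most `maxgap` (the
#' ChIPpeakAnno-style rule; typical values are 100/200 bp for point/broad
#' fly marks and 4000 bp for broad human marks).
#' Merged entities are the connected components of the partner graph built
#' with the same gap rule over the pooled peaks (within-set edges included),
#' classified by set membership.  Because the exact denominator behind a
#' single printed overlap percentage is ambiguous, all three are reported:
#' `pctA`/`pctB` (fraction of each set with a partner) and `pct_venn`
#' (components containing both sets over all components).
#'
#' @param A,B [peaks()] data.frames.
#' @param maxgap maximum allowed gap in bp (>= 0).
#' @return an object of class `overlap_report`: list with `maxgap`, `nA`,
#'   `nB`, `nA_hit`, `nB_hit`, `components` (named counts `both`, `onlyA`,
#'   `onlyB`), `pctA`, `pctB`, `pct_venn`.
#' @export
find_overlaps <- function(A, B, maxgap = 0) {
  if (maxgap < 0) stop("find_overlaps: maxgap must be >= 0")
  pairs <- overlap_pairs(A, B, maxgap)
  nA_hit <- length(unique(pairs[, 1]))
  nB_hit <- length(unique(pairs[, 2]))
  pooled <- data.frame(chrom = c(A$chrom, B$chrom),
                       start = c(A$start, B$start),
                       end = c(A$end, B$end), stringsAsFactors = FALSE)
  from_A <- c(rep(TRUE, nrow(A)), rep(FALSE, nrow(B)))
  comp <- if (nrow(pooled)) gap_clusters(pooled, maxgap) else integer(0)
  hasA <- tapply(from_A, comp, any)
  hasB <- tapply(!from_A, comp, any)
  components <- c(both = sum(hasA & hasB), onlyA = sum(hasA & !hasB),
                  onlyB = sum(!hasA & hasB))
  n_comp <- sum(components)
  structure(list(maxgap = maxgap, nA = nrow(A), nB = nrow(B),
                 nA_hit = nA_hit, nB_hit = nB_hit, components = components,
                 pctA = if (nrow(A)) nA_hit / nrow(A) else 0,
                 pctB = if (nrow(B)) nB_hit / nrow(B) else 0,
                 pct_venn = if (n_comp) components[["both"]] / n_comp else 0),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("overlap_report (maxgap ", x$maxgap, " bp): ",
      x$nA_hit, "/", x$nA, " of A and ", x$nB_hit, "/", x$nB,
      " of B have partners\n  components: both=", x$components[["both"]],
      " onlyA=", x$components[["onlyA"]], " onlyB=", x$components[["onlyB"]],
      "\n  pctA=", format(x$pctA, digits = 4),
      " pctB=", format(x$pctB, digits = 4),
      " pct_venn=", format(x$pct_venn, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Replicate-consensus peaks
#'
#' Keeps peaks passing the FDR cutoff that have a partner in the other
#' replicate (gap <= `maxgap`), and collapses each cross-replicate connected
#' component into one consensus peak spanning the coordinate union of its
#' members, carrying the best (maximum -log10) p and q among them.  This is
#' the "present in both replicates" reference-set rule.
#'
#' @param rep1,rep2 [peaks()] data.frames.
#' @param fdr_cutoff FDR threshold on the natural scale, or `NULL` for no
#'   filtering; when given, both replicates must carry q values.
#' @param maxgap partner rule distance in bp (default 0: intersect or abut).
#' @return a [peaks()] data.frame of consensus peaks (summit -1).
#' @export
merge_replicates <- function(rep1, rep2, fdr_cutoff = NULL, maxgap = 0) {
  sel <- function(pk) {
    if (is.null(fdr_cutoff)) return(pk)
    if (nrow(pk) && all(pk$q == -1)) {
      stop("merge_replicates: fdr_cutoff given but no q values present")
    }
    pk[pk$q >= -log10(fdr_cutoff), , drop = FALSE]
  }
  r1 <- sel(rep1); r2 <- sel(rep2)
  pairs <- overlap_pairs(r1, r2, maxgap)
  keep1 <- sort(unique(pairs[, 1])); keep2 <- sort(unique(pairs[, 2]))
  if (length(keep1) == 0) return(empty_peaks())
  pooled <- data.frame(
    chrom = c(r1$chrom[keep1], r2$chrom[keep2]),
    start = c(r1$start[keep1], r2$start[keep2]),
    end = c(r1$end[keep1], r2$end[keep2]),
    p = c(r1$p[keep1], r2$p[keep2]), q = c(r1$q[keep1], r2$q[keep2]),
    signal = c(r1$signal[keep1], r2$signal[keep2]),
    stringsAsFactors = FALSE)
  comp <- gap_clusters(pooled, maxgap)
  agg <- function(v, f) as.numeric(tapply(v, comp, f))
  out <- data.frame(chrom = as.character(tapply(pooled$chrom, comp,
                                                function(z) z[[1]])),
                    start = agg(pooled$start, min), end = agg(pooled$end, max),
                    p = agg(pooled$p, max), q = agg(pooled$q, max),
                    signal = agg(pooled$signal, max),
                    stringsAsFactors = FALSE)
  out <- out[order(match(out$chrom, unique(pooled$chrom)), out$start), ,
             drop = FALSE]
  peaks(out$chrom, out$start, out$end,
        name = paste0("consensus_", seq_len(nrow(out))),
        score = 0, strand = ".", signal = out$signal, p = out$p, q = out$q,
        summit = -1)
}

#' FDR-quantile recovery of candidate peaks
#'
#' Candidates are sorted by increasing FDR (decreasing -log10 q, coordinate
#' tie-break), split into `n_quantiles` near-equal blocks (remainders going to
#' the lowest-FDR blocks), and each block's recovery is the fraction of its
#' peaks with at least one reference partner at `maxgap`.  Quantile 1 holds
#' the most significant peaks.
#'
#' @param candidates [peaks()] with q values.
#' @param reference non-empty [peaks()] reference set.
#' @param maxgap partner distance in bp.
#' @param n_quantiles number of blocks (default 10).
#' @return an object of class `quantile_recovery`: data.frame with
#'   `quantile`, `n`, `recovered`, `fraction`.
#' @export
fdr_quantile_recovery <- function(candidates, reference, maxgap = 0,
                                  n_quantiles = 10) {
  if (n_quantiles < 1) stop("fdr_quantile_recovery: n_quantiles must be >= 1")
  if (nrow(reference) == 0) stop("fdr_quantile_recovery: empty reference")
  if (nrow(candidates) == 0 || any(candidates$q == -1)) {
    stop("fdr_quantile_recovery: all candidates must carry q values")
  }
  o <- order(-candidates$q, candidates$chrom, candidates$start,
             candidates$end)
  cand <- candidates[o, , drop = FALSE]
  n <- nrow(cand)
  base <- n %/% n_quantiles
  extra <- n %% n_quantiles
  sizes <- rep(base, n_quantiles) + (seq_len(n_quantiles) <= extra)
  block <- rep(seq_len(n_quantiles), sizes)
  hit <- logical(n)
  pairs <- overlap_pairs(cand, reference, maxgap)
  hit[unique(pairs[, 1])] <- TRUE
  df <- data.frame(quantile = seq_len(n_quantiles), n = sizes,
                   recovered = as.numeric(tapply(hit, factor(block,
                     levels = seq_len(n_quantiles)), sum, default = 0)))
  df$recovered[is.na(df$recovered)] <- 0
  df$fraction <- ifelse(df$n > 0, df$recovered / df$n, NA_real_)
  class(df) <- c("quantile_recovery", "data.frame")
  df
}

#' Saturation of peak recall across sequencing depths
#'
#' For each subsampled depth, the fraction of full-depth peaks with at least
#' one partner (gap <= `maxgap`) in that depth's peak set.
#'
#' @param full [peaks()] called at full depth (non-empty).
#' @param per_depth named list of [peaks()] (names = depth labels).
#' @param maxgap partner distance in bp.
#' @return an object of class `saturation_curve`: data.frame with `depth`,
#'   `recovered`, `fraction`.
#' @export
saturation_recall <- function(full, per_depth, maxgap = 0) {
  if (nrow(full) == 0) stop("saturation_recall: empty full-depth peak set")
  if (anyDuplicated(names(per_depth))) {
    stop("saturation_recall: duplicate depth labels")
  }
  rec <- vapply(per_depth, function(pk) {
    length(unique(overlap_pairs(full, pk, maxgap)[, 1]))
  }, numeric(1))
  df <- data.frame(depth = names(per_depth), recovered = as.numeric(rec),
                   fraction = as.numeric(rec) / nrow(full),
                   stringsAsFactors = FALSE)
  class(df) <- c("saturation_curve", "data.frame")
  df
}

#' Partition two peak sets into unique and common peaks
#'
#' A peak is common if it has a partner (gap <= `maxgap`) in the other set;
#' unique otherwise.  Membership is reported per input set, so
#' `nrow(A_only) + nrow(A_common) == nrow(A)` exactly.
#'
#' @param A,B [peaks()] data.frames.
#' @param maxgap partner distance in bp.
#' @return list with `A_only`, `A_common`, `B_only`, `B_common` peak tables.
#' @export
partition_unique_common <- function(A, B, maxgap = 0) {
  pairs <- overlap_pairs(A, B, maxgap)
  inA <- seq_len(nrow(A)) %in% pairs[, 1]
  inB <- seq_len(nrow(B)) %in% pairs[, 2]
  list(A_only = A[!inA, , drop = FALSE], A_common = A[inA, , drop = FALSE],
       B_only = B[!inB, , drop = FALSE], B_common = B[inB, , drop = FALSE])
}
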