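#' Bin a coverage track
#'
#' Mean per-base coverage over consecutive fixed-width bins tiling each
#' chromosome; the final partial bin is averaged over its true length, so the
#' length-weighted mean of the bin values equals the genome-wide mean exactly.
#'
#' @param cov a [coverage_track()].
#' @param bin_size bin width in bp (typical settings: 2000 for human, 500
#'   for fly genomes).
#' @param chrom_sizes governing [chrom_sizes()].
#' @return an object of class `binned_track`: data.frame with `chrom`, `bin`,
#'   `start`, `end`, `value`; attribute `bin_size`.
#' @export
bin_track <- function(cov, bin_size, chrom_sizes = cov$chrom_sizes) {
  if (bin_size < 1) stop("bin_track: bin_size must be >= 1")
  out <- lapply(names(chrom_sizes), function(ch) {
    len <- unclass(chrom_sizes)[[ch]]
    n <- ceiling(len / bin_size)
    s <- (seq_len(n) - 1) * bin_size
    e <- pmin(s + bin_size, len)
    v <- IRanges::viewMeans(IRanges::Views(cov$values[[ch]],
                                           start = s + 1L, end = e))
    data.frame(chrom = ch, bin = seq_len(n) - 1, start = s, end = e,
               value = as.numeric(v), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  attr(out, "bin_size") <- bin_size
  class(out) <- c("binned_track", "data.frame")
  out
}

#' Pearson correlation between two binned tracks
#'
#' Standard Pearson correlation over all bins, zeros included (no bin
#' filtering by default).  Set `drop_joint_zero_bins = TRUE` for a
#' sensitivity analysis that removes bins where both tracks are zero.
#'
#' @param a,b [bin_track()] results with identical binning.
#' @param drop_joint_zero_bins drop bins that are zero in both tracks.
#' @return the correlation coefficient.
#' @export
pearson_bins <- function(a, b, drop_joint_zero_bins = FALSE) {
  if (!isTRUE(attr(a, "bin_size") == attr(b, "bin_size")) ||
      nrow(a) != nrow(b) || !all(a$chrom == b$chrom) || !all(a$bin == b$bin)) {
    stop("pearson_bins: tracks are not identically binned")
  }
  x <- a$value; y <- b$value
  if (drop_joint_zero_bins) {
    keep <- x != 0 | y != 0
    x <- x[keep]; y <- y[keep]
  }
  if (length(x) < 2) stop("pearson_bins: need >= 2 bins")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("pearson_bins: zero variance in one of the tracks")
  }
  stats::cor(x, y)
}

## mean per-base values of one region split into equal bins; boundaries
## floor(i * L / nbins) guarantee non-empty bins when L >= nbins
region_bin_means <- function(vals, nbins) {
  L <- length(vals)
  b <- floor(seq_len(nbins + 1) - 1) * L / nbins
  b <- floor(b)
  cs <- c(0, cumsum(vals))
  (cs[b[-1] + 1] - cs[b[-(nbins + 1)] + 1]) / diff(b)
}

## fixed-width bins over [start, end) on a chromosome, zero outside
fixed_bin_means <- function(cov, chrom, start, end, bin) {
  n <- (end - start) / bin
  vals <- track_values(cov, chrom, max(start, 0), min(end,
                       unclass(cov$chrom_sizes)[[chrom]]))
  # callers must pre-flag out-of-chromosome rows; here start/end are in range
  region_bin_means(vals, n)
}

#' Metagene profile (TSS to TES with flanks)
#'
#' For each gene: `flank/flank_bin` fixed-width bins upstream of the TSS,
#' `body_bins` equal-width bins over the gene body `[TSS, TES)`, and the same
#' fixed-width bins downstream of the TES.  Minus-strand rows are reversed so
#' column 1 is always the 5' end.  Genes shorter than `body_bins` bp, or whose
#' flanks extend past a chromosome end, are flagged and excluded from the
#' summary (never zero-padded).
#'
#' @param cov a [coverage_track()] (typically RPM-normalized).
#' @param gn a `genes` data.frame.
#' @param flank flank width in bp on each side (default 1000).
#' @param body_bins number of gene-body bins.
#' @param flank_bin width of each flank bin in bp.
#' @return list of class `profile_matrix`: `matrix` (rows = genes, columns =
#'   bins), `flagged` (logical per input gene), `columns` (provenance
#'   labels), and `summary` (data.frame `column`, `mean`, `sem` over
#'   unflagged rows).
#' @export
metagene <- function(cov, gn, flank = 1000, body_bins = 100,
                     flank_bin = 20) {
  if (flank %% flank_bin != 0) {
    stop("metagene: flank must be a multiple of flank_bin")
  }
  nf <- flank / flank_bin
  sizes <- unclass(cov$chrom_sizes)
  L <- gn$end - gn$start
  flagged <- unname(L < body_bins | gn$start - flank < 0 |
                      gn$end + flank > sizes[gn$chrom])
  if (all(flagged)) stop("metagene: no retained genes")
  ncol_total <- 2 * nf + body_bins
  mat <- matrix(NA_real_, nrow(gn), ncol_total)
  for (i in which(!flagged)) {
    ch <- gn$chrom[i]
    left <- fixed_bin_means(cov, ch, gn$start[i] - flank, gn$start[i],
                            flank_bin)
    body <- region_bin_means(track_values(cov, ch, gn$start[i], gn$end[i]),
                             body_bins)
    right <- fixed_bin_means(cov, ch, gn$end[i], gn$end[i] + flank,
                             flank_bin)
    row <- c(left, body, right)
    if (gn$strand[i] == "-") row <- rev(row)
    mat[i, ] <- row
  }
  rownames(mat) <- gn$id
  columns <- c(paste0("flank5_", seq_len(nf)),
               paste0("body_", seq_len(body_bins)),
               paste0("flank3_", seq_len(nf)))
  colnames(mat) <- columns
  structure(list(matrix = mat, flagged = flagged, columns = columns,
                 summary = profile_summary(mat[!flagged, , drop = FALSE])),
            class = "profile_matrix")
}

## per-column mean and SEM (sd / sqrt(n)); SEM is 0 for a single row
profile_summary <- function(mat) {
  n <- nrow(mat)
  sem <- if (n > 1) apply(mat, 2, stats::sd) / sqrt(n) else rep(0, ncol(mat))
  data.frame(column = colnames(mat), mean = colMeans(mat), sem = sem,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-bin log2 fold change of signal over control
#'
#' Computed per region per bin as `log2((s + psi) / (c + psi))`, then
#' summarised column-wise with mean and SEM — which is what gives the
#' figure-style error band (as opposed to a ratio of averaged profiles).
#'
#' @param signal,control `profile_matrix` objects over the same regions and
#'   columns (RPM-normalized inputs).
#' @param pseudocount psi, in the track's units (default 0.1 RPM).
#' @return a `profile_matrix` of log2 fold changes; rows flagged in either
#'   input stay flagged.
#' @export
log2fc_profile <- function(signal, control, pseudocount = 0.1) {
  ms <- signal$matrix; mc <- control$matrix
  if (!all(dim(ms) == dim(mc))) stop("log2fc_profile: shape mismatch")
  flagged <- signal$flagged | control$flagged
  mat <- log2((ms + pseudocount) / (mc + pseudocount))
  structure(list(matrix = mat, flagged = flagged, columns = signal$columns,
                 summary = profile_summary(mat[!flagged, , drop = FALSE])),
            class = "profile_matrix")
}

#' Peak-centered coverage matrix
#'
#' Rows are peaks, columns fixed-width bins over `[anchor - half_width,
#' anchor + half_width)` where the anchor is the summit when present, else the
#' midpoint.  Rows whose span crosses a chromosome edge are flagged.  With
#' `sort_by` given, rows are ordered by decreasing mean of that track over the
#' row's span (coordinate tie-break) — e.g. profile one dataset sorted by the
#' affinities of another; otherwise input order is kept.
#'
#' @param cov [coverage_track()] to profile.
#' @param pk [peaks()] data.frame.
#' @param half_width half window in bp (default 1000, the figures' -1 kb to
#'   +1 kb).
#' @param bin bin width in bp.
#' @param sort_by optional [coverage_track()] driving the row order.
#' @return a `profile_matrix`; row labels are peak names.
#' @export
peak_centered <- function(cov, pk, half_width = 1000, bin = 10,
                          sort_by = NULL) {
  if (half_width < bin) stop("peak_centered: half_width must be >= bin")
  if ((2 * half_width) %% bin != 0) {
    stop("peak_centered: 2*half_width must be a multiple of bin")
  }
  sizes <- unclass(cov$chrom_sizes)
  anchor <- ifelse(pk$summit >= 0, pk$start + pk$summit,
                   floor((pk$start + pk$end) / 2))
  s <- anchor - half_width; e <- anchor + half_width
  flagged <- unname(s < 0 | e > sizes[pk$chrom])
  nb <- 2 * half_width / bin
  mat <- matrix(NA_real_, nrow(pk), nb)
  for (i in which(!flagged)) {
    mat[i, ] <- fixed_bin_means(cov, pk$chrom[i], s[i], e[i], bin)
  }
  rownames(mat) <- pk$name
  colnames(mat) <- paste0("offset_", seq_len(nb) * bin - half_width - bin)
  ord <- seq_len(nrow(pk))
  if (!is.null(sort_by)) {
    key <- vapply(seq_len(nrow(pk)), function(i) {
      if (flagged[i]) return(-Inf)
      mean(track_values(sort_by, pk$chrom[i], s[i], e[i]))
    }, numeric(1))
    ord <- order(-key, pk$chrom, pk$start)
  }
  mat <- mat[ord, , drop = FALSE]
  flagged <- flagged[ord]
  structure(list(matrix = mat, flagged = flagged, columns = colnames(mat),
                 summary = profile_summary(mat[!flagged, , drop = FALSE])),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat("profile_matrix: ", nrow(x$matrix), " region(s) x ", ncol(x$matrix),
      " bin(s); ", sum(x$flagged), " flagged\n", sep = "")
  invisible(x)
}
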