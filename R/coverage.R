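#' Coverage tracks
#'
#' A `coverage_track` stores per-base signal as one run-length-encoded step
#' function per chromosome ([S4Vectors::Rle]), tiling each chromosome exactly,
#' plus a normalization tag (`"raw"` or `"rpm"`).  The step-function
#' representation lets megabase synthetic genomes and real chromosomes share
#' one code path.
#'
#' @param values named list of numeric [S4Vectors::Rle] objects, one per
#'   chromosome, each of length equal to the chromosome.
#' @param chrom_sizes the governing [chrom_sizes()].
#' @param norm `"raw"` or `"rpm"`.
#' @return an object of class `coverage_track`.
#' @export
coverage_track <- function(values, chrom_sizes, norm = c("raw", "rpm")) {
  norm <- match.arg(norm)
  for (ch in names(chrom_sizes)) {
    if (is.null(values[[ch]])) {
      values[[ch]] <- S4Vectors::Rle(0, unclass(chrom_sizes)[[ch]])
    }
    if (length(values[[ch]]) != unclass(chrom_sizes)[[ch]]) {
      stop("coverage_track: ", ch, " steps do not tile the chromosome")
    }
    if (min(S4Vectors::runValue(values[[ch]]), 0) < 0) {
      stop("coverage_track: negative coverage on ", ch)
    }
  }
  structure(list(values = values[names(chrom_sizes)],
                 chrom_sizes = chrom_sizes, norm = norm),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track (", x$norm, "): ", length(x$values),
      " chromosome(s), genome mean ",
      format(track_total(x) / genome_length(x$chrom_sizes), digits = 4),
      "\n", sep = "")
  invisible(x)
}

## per-base values over [start, end), 0-based half-open
track_values <- function(track, chrom, start, end) {
  rle <- track$values[[chrom]]
  if (is.null(rle)) return(rep(0, end - start))
  as.numeric(IRanges::Views(rle, start = start + 1L, end = end)[[1]])
}

## genome-wide sum of per-base values
track_total <- function(track) {
  sum(vapply(track$values, function(r) {
    sum(as.numeric(S4Vectors::runValue(r)) * S4Vectors::runLength(r))
  }, numeric(1)))
}

#' Read a bedGraph file into a coverage track
#'
#' Records must be sorted and non-overlapping within each chromosome; gaps are
#' filled with 0 so the resulting step function tiles every chromosome.
#'
#' @param path 4-column bedGraph (chrom, start, end, value).
#' @param chrom_sizes governing [chrom_sizes()].
#' @return a [coverage_track()] tagged `raw`.
#' @export
read_bedgraph <- function(path, chrom_sizes) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = c("character", "numeric", "numeric",
                                         "numeric"),
                          col.names = c("chrom", "start", "end", "value"))
  if (any(df$value < 0)) {
    stop("read_bedgraph: negative coverage value at record ",
         which(df$value < 0)[1])
  }
  if (any(df$start < 0) || any(df$start >= df$end)) {
    stop("read_bedgraph: malformed coordinates at record ",
         which(df$start < 0 | df$start >= df$end)[1])
  }
  check_bounds(df$chrom, df$start, df$end, chrom_sizes, "read_bedgraph")
  values <- list()
  for (ch in unique(df$chrom)) {
    d <- df[df$chrom == ch, ]
    d <- d[order(d$start), ]
    if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)])) {
      stop("read_bedgraph: overlapping records on ", ch)
    }
    len <- unclass(chrom_sizes)[[ch]]
    # interleave zero gaps with declared steps
    starts <- d$start; ends <- d$end
    gap_starts <- c(0, ends); gap_ends <- c(starts, len)
    keep <- gap_ends > gap_starts
    seg_start <- c(starts, gap_starts[keep])
    seg_len <- c(ends - starts, gap_ends[keep] - gap_starts[keep])
    seg_val <- c(d$value, rep(0, sum(keep)))
    o <- order(seg_start)
    values[[ch]] <- S4Vectors::Rle(seg_val[o], seg_len[o])
  }
  coverage_track(values, chrom_sizes, "raw")
}

#' Write a coverage track as bedGraph
#'
#' Zero-valued runs are omitted (the conventional sparse bedGraph form);
#' [read_bedgraph()] fills them back in, so the round trip is exact.
#'
#' @param track a [coverage_track()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_bedgraph <- function(track, path) {
  out <- character(0)
  for (ch in names(track$values)) {
    r <- track$values[[ch]]
    v <- as.numeric(S4Vectors::runValue(r))
    l <- S4Vectors::runLength(r)
    e <- cumsum(as.numeric(l)); s <- e - l
    nz <- v != 0
    if (any(nz)) {
      out <- c(out, paste(ch, s[nz], e[nz],
                          vapply(v[nz], as.character, character(1)),
                          sep = "\t"))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Per-base coverage from fragment intervals
#'
#' The value at each base is the number of fragments covering it; with
#' `normalize = "rpm"` values are scaled by `1e6 / total fragments` (reads per
#' million).
#'
#' @param reads a [read_set()].
#' @param chrom_sizes governing [chrom_sizes()].
#' @param normalize `"raw"` or `"rpm"`.
#' @return a [coverage_track()].
#' @export
coverage_from_fragments <- function(reads, chrom_sizes,
                                    normalize = c("raw", "rpm")) {
  normalize <- match.arg(normalize)
  if (normalize == "rpm" && reads$total == 0) {
    stop("coverage_from_fragments: rpm normalization needs >= 1 fragment")
  }
  f <- reads$fragments
  if (nrow(f)) check_bounds(f$chrom, f$start, f$end, chrom_sizes)
  scale <- if (normalize == "rpm") 1e6 / reads$total else 1
  values <- list()
  for (ch in names(chrom_sizes)) {
    len <- unclass(chrom_sizes)[[ch]]
    idx <- which(f$chrom == ch)
    if (length(idx) == 0) {
      values[[ch]] <- S4Vectors::Rle(0, len)
    } else {
      cov <- IRanges::coverage(as_iranges0(f$start[idx], f$end[idx]),
                               width = len)
      values[[ch]] <- if (scale == 1) S4Vectors::Rle(as.numeric(
        S4Vectors::runValue(cov)), S4Vectors::runLength(cov))
      else S4Vectors::Rle(as.numeric(S4Vectors::runValue(cov)) * scale,
                          S4Vectors::runLength(cov))
    }
  }
  coverage_track(values, chrom_sizes, normalize)
}

#' Per-base coverage of fragment midpoints
#'
#' Companion to [coverage_from_fragments()] counting only each fragment's
#' midpoint base, for matching pipelines that pile up read centres rather than
#' whole fragments.
#'
#' @inheritParams coverage_from_fragments
#' @return a [coverage_track()].
#' @export
coverage_from_midpoints <- function(reads, chrom_sizes,
                                    normalize = c("raw", "rpm")) {
  f <- reads$fragments
  mid <- floor((f$start + f$end) / 2)
  coverage_from_fragments(read_set(f$chrom, mid, mid + 1), chrom_sizes,
                          normalize)
}
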