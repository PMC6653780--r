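## Fixed non-overlapping genomic windows.  A window id is "chrom:index" with
## index = floor(position / window_size); the final partial window of each
## chromosome is included (end clipped to the chromosome length).

#' Tile a genome into fixed non-overlapping windows
#'
#' @param chrom_sizes a [chrom_sizes()].
#' @param window_size window width in bp (the final window of each chromosome
#'   may be shorter).
#' @return data.frame with `chrom`, `index`, `start`, `end`, `id`; the total
#'   window count is `nrow()`.
#' @export
tile_genome <- function(chrom_sizes, window_size) {
  if (window_size < 1) stop("tile_genome: window_size must be >= 1")
  out <- lapply(names(chrom_sizes), function(ch) {
    len <- unclass(chrom_sizes)[[ch]]
    n <- ceiling(len / window_size)
    idx <- seq_len(n) - 1
    data.frame(chrom = ch, index = idx, start = idx * window_size,
               end = pmin((idx + 1) * window_size, len),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$id <- paste0(out$chrom, ":", out$index)
  out
}

## number of tiled windows without materialising them
n_windows <- function(chrom_sizes, window_size) {
  sum(ceiling(as.numeric(chrom_sizes) / window_size))
}

#' Construct a window set
#'
#' The identity of the genome windows hit by a peak set.  Ids are
#' `"chrom:index"` strings; duplicates are removed and order normalised so two
#' window sets compare by content.
#'
#' @param ids character vector of window ids.
#' @param window_size window width in bp.
#' @param chrom_sizes the governing [chrom_sizes()].
#' @return an object of class `window_set`.
#' @export
window_set <- function(ids, window_size, chrom_sizes) {
  structure(list(ids = sort(unique(as.character(ids))),
                 window_size = window_size, chrom_sizes = chrom_sizes),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat("window_set:", length(x$ids), "window(s) of", x$window_size, "bp\n")
  invisible(x)
}

## window ids overlapped by each peak; returns per-peak expansion
expand_peak_windows <- function(pk, window_size, chrom_sizes) {
  check_bounds(pk$chrom, pk$start, pk$end, chrom_sizes, "peaks")
  i0 <- floor(pk$start / window_size)
  i1 <- floor((pk$end - 1) / window_size)
  n <- i1 - i0 + 1
  row <- rep(seq_len(nrow(pk)), n)
  idx <- sequence(n) - 1 + rep(i0, n)
  list(row = row, id = paste0(pk$chrom[row], ":", idx))
}

#' Map peaks to the windows they hit
#'
#' A window belongs to the set iff at least one retained peak overlaps at
#' least 1 bp of it.  With `fdr_cutoff` given, retained peaks are those with
#' `q >= -log10(fdr_cutoff)` (peaks defined at an FDR cutoff, e.g. 5%).
#'
#' @param pk a [peaks()] data.frame.
#' @param window_size window width in bp.
#' @param chrom_sizes governing [chrom_sizes()].
#' @param fdr_cutoff FDR threshold on the natural scale (e.g. `0.05`), or
#'   `NULL` to keep all peaks.
#' @return a [window_set()].
#' @export
peaks_to_windows <- function(pk, window_size, chrom_sizes,
                             fdr_cutoff = NULL) {
  if (!is.null(fdr_cutoff)) {
    if (nrow(pk) && all(pk$q == -1)) {
      stop("peaks_to_windows: fdr_cutoff given but no peak carries a q value")
    }
    pk <- pk[pk$q >= -log10(fdr_cutoff), , drop = FALSE]
  }
  if (nrow(pk) == 0) return(window_set(character(0), window_size, chrom_sizes))
  ex <- expand_peak_windows(pk, window_size, chrom_sizes)
  window_set(ex$id, window_size, chrom_sizes)
}

#' Score windows by their best overlapping peak
#'
#' Each window hit by at least one peak gets the maximum -log10 p over the
#' peaks overlapping it (a window is as significant as its best peak);
#' windows with no peak are absent from the map.  Used for the
#' "changing p-value threshold" ROC sweep.
#'
#' @param pk a [peaks()] data.frame; every peak must carry a p value.
#' @param window_size window width in bp.
#' @param chrom_sizes governing [chrom_sizes()].
#' @param score_column `"p"` (default) or `"q"`: which -log10 column drives
#'   the sweep.
#' @return an object of class `scored_windows`: list with `scores` (named
#'   numeric, names = window ids), `window_size`, `chrom_sizes`.
#' @export
score_windows <- function(pk, window_size, chrom_sizes,
                          score_column = c("p", "q")) {
  score_column <- match.arg(score_column)
  if (nrow(pk) && any(pk[[score_column]] == -1)) {
    stop("score_windows: peak(s) without a ", score_column, " value")
  }
  if (nrow(pk) == 0) {
    return(scored_windows(setNames(numeric(0), character(0)), window_size,
                          chrom_sizes))
  }
  ex <- expand_peak_windows(pk, window_size, chrom_sizes)
  s <- pk[[score_column]][ex$row]
  agg <- tapply(s, ex$id, max)
  scored_windows(setNames(as.numeric(agg), names(agg)), window_size,
                 chrom_sizes)
}

#' Construct a scored-window map
#'
#' @param scores named numeric vector (names = window ids, values = -log10
#'   significance of the best overlapping peak; all `>= 0`).
#' @param window_size window width in bp.
#' @param chrom_sizes governing [chrom_sizes()].
#' @return an object of class `scored_windows`.
#' @export
scored_windows <- function(scores, window_size, chrom_sizes) {
  if (length(scores) && (is.null(names(scores)) || any(scores < 0))) {
    stop("scored_windows: scores must be named and >= 0")
  }
  o <- order(names(scores))
  structure(list(scores = scores[o], window_size = window_size,
                 chrom_sizes = chrom_sizes),
            class = "scored_windows")
}
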