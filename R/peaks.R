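#' Construct a peak table
#'
#' Peaks are stored as a data.frame with the narrowPeak field set: `chrom`,
#' `start`, `end` (0-based half-open), `name`, `score`, `strand`, `signal`,
#' `p` (-log10 p-value), `q` (-log10 q-value / FDR) and `summit` (offset from
#' `start`).  The value -1 is the missing sentinel for `p`, `q` and `summit`,
#' matching the ENCODE convention.
#'
#' @param chrom,start,end interval coordinates (recycled to common length).
#' @param name,score,strand,signal,p,q,summit narrowPeak columns; defaults are
#'   the missing sentinels.
#' @param chrom_sizes optional [chrom_sizes()]; when given, coordinates are
#'   validated against it.
#' @return a data.frame of class `peaks`.
#' @export
peaks <- function(chrom, start, end, name = ".", score = 0, strand = ".",
                  signal = 0, p = -1, q = -1, summit = -1,
                  chrom_sizes = NULL) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), name = as.character(name),
                   score = as.numeric(score), strand = as.character(strand),
                   signal = as.numeric(signal), p = as.numeric(p),
                   q = as.numeric(q), summit = as.numeric(summit),
                   stringsAsFactors = FALSE)
  validate_peaks(df, chrom_sizes)
}

validate_peaks <- function(df, chrom_sizes = NULL) {
  if (nrow(df)) {
    if (any(df$start < 0) || any(df$start >= df$end)) {
      stop("peaks: require 0 <= start < end (row ",
           which(df$start < 0 | df$start >= df$end)[1], ")")
    }
    if (!all(df$strand %in% c("+", "-", "."))) stop("peaks: bad strand value")
    w <- df$end - df$start
    bad <- df$summit != -1 & (df$summit < 0 | df$summit >= w)
    if (any(bad)) stop("peaks: summit outside peak (row ", which(bad)[1], ")")
    if (any(df$p < -1) || any(df$q < -1)) {
      stop("peaks: p and q must be -1 (missing) or >= 0")
    }
    if (!is.null(chrom_sizes)) {
      check_bounds(df$chrom, df$start, df$end, chrom_sizes, "peaks")
    }
  }
  class(df) <- c("peaks", "data.frame")
  df
}

empty_peaks <- function() {
  validate_peaks(data.frame(chrom = character(), start = numeric(),
                            end = numeric(), name = character(),
                            score = numeric(), strand = character(),
                            signal = numeric(), p = numeric(), q = numeric(),
                            summit = numeric(), stringsAsFactors = FALSE))
}

#' Read peak calls (BED6 / narrowPeak / broadPeak)
#'
#' Tab-delimited ENCODE dialects: `bed6` (6 columns; signal/p/q/summit take
#' their missing defaults), `narrowPeak` (BED6+4: signal, -log10 p, -log10 q,
#' summit) and `broadPeak` (BED6+3: no summit).
#'
#' @param path input file.
#' @param dialect one of `"bed6"`, `"narrowPeak"`, `"broadPeak"`.
#' @param chrom_sizes optional [chrom_sizes()] used to validate coordinates.
#' @return a [peaks()] data.frame.
#' @export
read_peaks <- function(path, dialect = c("narrowPeak", "broadPeak", "bed6"),
                       chrom_sizes = NULL) {
  dialect <- match.arg(dialect)
  ncol_want <- switch(dialect, bed6 = 6L, broadPeak = 9L, narrowPeak = 10L)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_peaks())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(fields)
  if (any(nc != ncol_want)) {
    stop("read_peaks: line ", which(nc != ncol_want)[1], " has ",
         nc[nc != ncol_want][1], " columns, dialect '", dialect,
         "' requires ", ncol_want)
  }
  m <- do.call(rbind, fields)
  num <- function(j) as.numeric(m[, j])
  df <- peaks(chrom = m[, 1], start = num(2), end = num(3), name = m[, 4],
              score = num(5), strand = m[, 6],
              signal = if (ncol_want >= 9) num(7) else 0,
              p      = if (ncol_want >= 9) num(8) else -1,
              q      = if (ncol_want >= 9) num(9) else -1,
              summit = if (ncol_want == 10) num(10) else -1,
              chrom_sizes = chrom_sizes)
  df
}

#' Write peak calls
#'
#' Inverse of [read_peaks()]: the round trip through a file reproduces every
#' field at printed precision.
#'
#' @param x a [peaks()] data.frame.
#' @param path output file.
#' @param dialect output dialect (see [read_peaks()]).
#' @return invisibly, `path`.
#' @export
write_peaks <- function(x, path,
                        dialect = c("narrowPeak", "broadPeak", "bed6")) {
  dialect <- match.arg(dialect)
  fmt <- function(v) vapply(v, function(z) as.character(z), character(1))
  cols <- list(x$chrom, fmt(x$start), fmt(x$end), x$name, fmt(x$score),
               x$strand)
  if (dialect != "bed6") cols <- c(cols, list(fmt(x$signal), fmt(x$p),
                                              fmt(x$q)))
  if (dialect == "narrowPeak") cols <- c(cols, list(fmt(x$summit)))
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Read gene models from BED6
#'
#' @param path BED6 file: chrom, start, end, id, score (ignored), strand.
#'   Strand must be `+` or `-`; ids must be unique.
#' @param chrom_sizes optional [chrom_sizes()] for coordinate validation.
#' @return a data.frame of class `genes` with columns `chrom`, `start`,
#'   `end`, `id`, `strand`.
#' @export
read_genes <- function(path, chrom_sizes = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = c("character", "numeric", "numeric",
                                         "character", "character",
                                         "character"),
                          col.names = c("chrom", "start", "end", "id",
                                        "score", "strand"))
  genes(df$chrom, df$start, df$end, df$id, df$strand, chrom_sizes)
}

#' Construct a gene-model table
#'
#' @param chrom,start,end gene span (0-based half-open).
#' @param id unique gene identifiers.
#' @param strand `"+"` or `"-"` (strict).
#' @param chrom_sizes optional [chrom_sizes()] for validation.
#' @return a data.frame of class `genes`.
#' @export
genes <- function(chrom, start, end, id, strand, chrom_sizes = NULL) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), id = as.character(id),
                   strand = as.character(strand), stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (!all(df$strand %in% c("+", "-"))) {
      stop("genes: strand must be strictly '+' or '-'")
    }
    if (anyDuplicated(df$id)) stop("genes: duplicate gene id(s)")
    if (any(df$start < 0) || any(df$start >= df$end)) {
      stop("genes: require 0 <= start < end")
    }
    if (!is.null(chrom_sizes)) {
      check_bounds(df$chrom, df$start, df$end, chrom_sizes, "genes")
    }
  }
  class(df) <- c("genes", "data.frame")
  df
}

#' Write gene models as BED6
#' @param x a `genes` data.frame.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_genes <- function(x, path) {
  writeLines(paste(x$chrom, x$start, x$end, x$id, 0, x$strand, sep = "\t"),
             path)
  invisible(path)
}

## Strand-aware TSS position (the 5' boundary in half-open coordinates).
tss_position <- function(genes) {
  ifelse(genes$strand == "+", genes$start, genes$end)
}
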