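#' Construct a fragment set
#'
#' Sequenced fragments as plain 0-based half-open intervals (strand is not
#' tracked: counting and coverage are strand-blind here).
#'
#' @param chrom,start,end fragment coordinates.
#' @param chrom_sizes optional [chrom_sizes()] for validation.
#' @return an object of class `read_set`: a list with `fragments` (data.frame
#'   `chrom`, `start`, `end`) and `total` (fragment count).
#' @export
read_set <- function(chrom = character(), start = numeric(),
                     end = numeric(), chrom_sizes = NULL) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (any(df$start < 0) || any(df$start >= df$end)) {
      stop("read_set: require 0 <= start < end (row ",
           which(df$start < 0 | df$start >= df$end)[1], ")")
    }
    if (!is.null(chrom_sizes)) {
      check_bounds(df$chrom, df$start, df$end, chrom_sizes, "read_set")
    }
  }
  structure(list(fragments = df, total = nrow(df)), class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat("read_set:", x$total, "fragment(s)\n")
  invisible(x)
}

#' Read fragment intervals (BED / tagAlign)
#'
#' Any tab-delimited BED-like file with >= 3 columns; only chrom/start/end are
#' used, extra columns (name, score, strand) are ignored.
#'
#' @param path input file.  An empty file yields an empty, valid `read_set`.
#' @param chrom_sizes optional [chrom_sizes()] for validation.
#' @return a [read_set()].
#' @export
read_fragments <- function(path, chrom_sizes = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(read_set())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(fields)
  if (any(nc < 3L)) {
    stop("read_fragments: line ", which(nc < 3L)[1], " has fewer than 3 columns")
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  if (anyNA(start) || anyNA(end)) {
    stop("read_fragments: non-numeric coordinate at line ",
         which(is.na(start) | is.na(end))[1])
  }
  read_set(chrom, start, end, chrom_sizes)
}

#' Write fragment intervals as BED3
#' @param x a [read_set()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_fragments <- function(x, path) {
  f <- x$fragments
  writeLines(paste(f$chrom, f$start, f$end, sep = "\t"), path)
  invisible(path)
}
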