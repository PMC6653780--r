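#' Construct a chromosome-size table
#'
#' An ordered map from chromosome name to length in bp.  Iteration order is
#' preserved (it determines window ids downstream), names must be unique and
#' lengths positive integers.
#'
#' @param sizes named numeric vector of chromosome lengths in bp.
#' @return an object of class `chrom_sizes` (a named integer-valued numeric
#'   vector).
#' @examples
#' chrom_sizes(c(chr1 = 1e6, chr2 = 5e5))
#' @export
chrom_sizes <- function(sizes) {
  nm <- names(sizes)
  if (is.null(nm) || any(!nzchar(nm))) {
    stop("chrom_sizes: all entries must be named")
  }
  if (anyDuplicated(nm)) {
    stop("chrom_sizes: duplicate chromosome name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  sizes <- as.numeric(sizes)
  if (any(!is.finite(sizes)) || any(sizes < 1) || any(sizes != floor(sizes))) {
    stop("chrom_sizes: lengths must be positive integers")
  }
  structure(setNames(sizes, nm), class = "chrom_sizes")
}

#' Read a UCSC chrom.sizes file
#'
#' Two whitespace-delimited columns: chromosome name, length in bp.  File order
#' is preserved.
#'
#' @param path path to the chrom.sizes file.
#' @return a [chrom_sizes()] object.
#' @export
read_chrom_sizes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("read_chrom_sizes: empty file: ", path)
  nm <- character(length(lines))
  len <- numeric(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[[i]]), "[ \t]+")[[1]]
    if (length(f) != 2L) {
      stop("read_chrom_sizes: malformed line ", i, " (expected 2 fields): ",
           lines[[i]])
    }
    v <- suppressWarnings(as.numeric(f[[2]]))
    if (is.na(v)) stop("read_chrom_sizes: non-numeric length at line ", i)
    nm[i] <- f[[1]]
    len[i] <- v
  }
  if (anyDuplicated(nm)) {
    stop("read_chrom_sizes: duplicate chromosome name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  if (any(len < 1) || any(len != floor(len))) {
    stop("read_chrom_sizes: lengths must be positive integers (line ",
         which(len < 1 | len != floor(len))[1], ")")
  }
  chrom_sizes(setNames(len, nm))
}

#' Write a chrom.sizes file
#'
#' @param sizes a [chrom_sizes()] object.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_chrom_sizes <- function(sizes, path) {
  writeLines(paste(names(sizes), format(unclass(sizes), scientific = FALSE,
                                        trim = TRUE), sep = "\t"), path)
  invisible(path)
}

#' @export
print.chrom_sizes <- function(x, ...) {
  cat("chrom_sizes:", length(x), "chromosome(s),",
      format(sum(x), big.mark = ","), "bp total\n")
  print(setNames(as.numeric(x), names(x)))
  invisible(x)
}

## total genome length
genome_length <- function(chrom_sizes) sum(as.numeric(chrom_sizes))

## check intervals (vectors chrom/start/end) against a chrom_sizes table
check_bounds <- function(chrom, start, end, sizes, what = "interval") {
  bad <- !(chrom %in% names(sizes))
  if (any(bad)) {
    stop(what, ": unknown chromosome(s): ",
         paste(unique(chrom[bad]), collapse = ", "))
  }
  len <- unclass(sizes)[chrom]
  if (any(end > len)) {
    stop(what, ": end beyond chromosome length (first offender: ",
         chrom[end > len][1], ")")
  }
  invisible(TRUE)
}
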