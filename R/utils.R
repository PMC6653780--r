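## Seed plumbing.  Every stochastic operation takes an explicit seed, derives
## an independent substream from it with a Lehmer-style mix (all arithmetic
## stays below 2^53, results below 2^31), and restores the caller's RNG state
## on exit, so package functions never perturb user code.

lehmer <- function(x) (x * 48271) %% 2147483647

derive_seed <- function(seed, ...) {
  x <- lehmer((as.numeric(seed) %% 2147483646) + 1)
  for (tag in c(...)) x <- lehmer((x + as.numeric(tag)) %% 2147483646 + 1)
  as.integer(x)
}

local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
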