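# Independent brute-force oracles and fixture builders.  Nothing here calls
# the code paths it checks: AUC is the pairwise ranking probability, overlap
# is O(n^2) interval arithmetic, Jaccard is exhaustive set enumeration.

# Pairwise-ranking AUC: P(score_pos > score_neg) + 1/2 P(tie), with every
# unscored window holding one shared sentinel worst score.
brute_auc <- function(scores, ref_ids, n_universe) {
  sentinel <- if (length(scores)) min(scores) - 1 else 0
  pos_scored <- scores[names(scores) %in% ref_ids]
  neg_scored <- scores[!(names(scores) %in% ref_ids)]
  n_pos_unscored <- length(ref_ids) - length(pos_scored)
  n_neg_unscored <- (n_universe - length(ref_ids)) - length(neg_scored)
  pos <- c(unname(pos_scored), rep(sentinel, n_pos_unscored))
  neg <- c(unname(neg_scored), rep(sentinel, n_neg_unscored))
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# O(n^2) interval oracle: pairs with >= 1 bp intersection (maxgap 0 here
# means intersect-or-abut, matching the package's gap convention).
brute_partner_pairs <- function(A, B, maxgap = 0) {
  out <- NULL
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      same <- A$chrom[i] == B$chrom[j]
      if (same) {
        g <- max(max(A$start[i], B$start[j]) - min(A$end[i], B$end[j]), 0)
        if (g <= maxgap) out <- rbind(out, c(i, j))
      }
    }
  }
  out
}

adjusted_rand_index <- function(x, y) {
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  c_ <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expected <- b * c_ / choose(n, 2)
  maxi <- (b + c_) / 2
  if (maxi == expected) return(1)
  (a - expected) / (maxi - expected)
}

# random window-set fixture over a pool of ids
random_window_set <- function(pool, k, w, cs) {
  window_set(sample(pool, k), w, cs)
}

rand_peaks <- function(n, cs, max_len = 500) {
  ch <- sample(names(cs), n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  start <- floor(runif(n, 0, unclass(cs)[ch] - len))
  peaks(ch, start, start + len, name = sprintf("p%d", seq_len(n)))
}

test_sizes <- function() chrom_sizes(c(chrA = 100000, chrB = 60000))
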