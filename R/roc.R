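#' Trapezoid area under a curve
#'
#' @param x,y curve coordinates; `x` must be non-decreasing.
#' @return the trapezoid-rule area.
#' @export
auc_trapezoid <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2) return(0)
  dx <- diff(x)
  if (any(dx < 0)) stop("auc_trapezoid: x must be non-decreasing")
  sum(dx * (head(y, -1) + tail(y, -1)) / 2)
}

#' Window-mapped ROC and precision-recall curves
#'
#' Sweeps a descending significance threshold over scored windows against a
#' reference window set.  At threshold `t` a window is predicted positive iff
#' its score is `>= t`; windows absent from the scored map share one sentinel
#' worst rank and enter together in a final tie-completion step, so the ROC
#' always terminates at (1, 1) via a straight segment.  When the scored
#' windows cannot recall at least `validity_floor` of the reference before
#' that segment, the AUC is flagged unfaithful (`auc_valid = FALSE`) — the
#' asterisk condition for datasets whose peak calls never cover enough of the
#' reference.
#'
#' `auc_roc` is the trapezoid area over the full curve including the tie
#' segment (equal to the pairwise ranking probability with ties counted 1/2);
#' `auc_pr` is the trapezoid area over recall with the strictest-threshold
#' precision extended to recall 0 (linear PR interpolation).
#'
#' @param reference a [window_set()]: the positive windows.
#' @param scored a [scored_windows()] map for the candidate dataset.
#' @param chrom_sizes governing [chrom_sizes()]; with `window_size` it defines
#'   the window universe (all tiled windows genome-wide).
#' @param validity_floor minimum scored recall for a faithful AUC
#'   (default 0.75).
#' @return an object of class `evaluation_curve`: list with `curve`
#'   (data.frame `threshold`, `tp`, `fp`, `fn`, `tn`, `tpr`, `fpr`,
#'   `precision`; the final row is the tie-completion point with threshold
#'   `-Inf`), `auc_roc`, `auc_pr`, `scored_recall_max`, `auc_valid`, `n_pos`,
#'   `n_neg`.
#' @export
roc_prc <- function(reference, scored, chrom_sizes,
                    validity_floor = 0.75) {
  if (reference$window_size != scored$window_size) {
    stop("roc_prc: reference and scored window sizes differ")
  }
  w <- reference$window_size
  n_univ <- n_windows(chrom_sizes, w)
  n_pos <- length(reference$ids)
  n_neg <- n_univ - n_pos
  if (n_pos < 1) stop("roc_prc: empty reference window set")
  if (n_neg < 1) stop("roc_prc: reference covers the whole universe")

  s <- scored$scores
  lab <- names(s) %in% reference$ids
  o <- order(-s)
  s <- s[o]; lab <- lab[o]
  # one curve point per distinct score (all ties enter together)
  if (length(s)) {
    last <- c(s[-1] != s[-length(s)], TRUE)
    cum_tp <- cumsum(lab)[last]
    cum_pred <- seq_along(s)[last]
    thr <- s[last]
  } else {
    cum_tp <- integer(0); cum_pred <- integer(0); thr <- numeric(0)
  }
  tp <- cum_tp
  fp <- cum_pred - cum_tp
  tpr <- tp / n_pos
  fpr <- fp / n_neg
  precision <- tp / pmax(cum_pred, 1)

  scored_recall_max <- if (length(tp)) tpr[length(tpr)] else 0

  curve <- data.frame(threshold = c(thr, -Inf),
                      tp = c(tp, n_pos), fp = c(fp, n_neg),
                      fn = c(n_pos - tp, 0), tn = c(n_neg - fp, 0),
                      tpr = c(tpr, 1), fpr = c(fpr, 1),
                      precision = c(precision, n_pos / n_univ))

  auc_roc <- auc_trapezoid(c(0, curve$fpr), c(0, curve$tpr))
  # prepend (recall 0, strictest precision)
  p0 <- if (nrow(curve)) curve$precision[1] else 1
  auc_pr <- auc_trapezoid(c(0, curve$tpr), c(p0, curve$precision))

  structure(list(curve = curve, auc_roc = auc_roc, auc_pr = auc_pr,
                 scored_recall_max = scored_recall_max,
                 auc_valid = scored_recall_max >= validity_floor,
                 n_pos = n_pos, n_neg = n_neg,
                 validity_floor = validity_floor),
            class = "evaluation_curve")
}

#' @export
print.evaluation_curve <- function(x, ...) {
  cat("evaluation_curve: ", x$n_pos, " positive / ", x$n_neg,
      " negative windows\n",
      "  auc_roc = ", format(x$auc_roc, digits = 4),
      if (!x$auc_valid) " (*unfaithful: scored recall below floor)" else "",
      "\n  auc_pr  = ", format(x$auc_pr, digits = 4),
      "\n  scored_recall_max = ", format(x$scored_recall_max, digits = 4),
      " (validity floor ", x$validity_floor, ")\n", sep = "")
  invisible(x)
}

#' Write an evaluation curve as TSV
#'
#' Header comment lines carry the scalar summaries (`auc_roc`, `auc_pr`,
#' `scored_recall_max`, `auc_valid`); the table has one row per threshold.
#'
#' @param x an [roc_prc()] result.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_curve <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# auc_roc=", format(x$auc_roc, digits = 10)),
               paste0("# auc_pr=", format(x$auc_pr, digits = 10)),
               paste0("# scored_recall_max=",
                      format(x$scored_recall_max, digits = 10)),
               paste0("# auc_valid=", x$auc_valid)), con)
  utils::write.table(x$curve, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
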