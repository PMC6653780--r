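#' Jaccard index between two window sets
#'
#' `|A ∩ B| / |A ∪ B|`, defined as 1 when both sets are empty.  The sets must
#' share window size and genome.
#'
#' @param a,b [window_set()] objects.
#' @return the Jaccard index in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  if (a$window_size != b$window_size) {
    stop("jaccard: window sizes differ")
  }
  u <- length(union(a$ids, b$ids))
  if (u == 0) return(1)
  length(intersect(a$ids, b$ids)) / u
}

#' Pairwise Jaccard similarity matrix
#'
#' @param sets list of [window_set()] objects with compatible windowing.
#' @param labels dataset names; default the list names.
#' @return an object of class `similarity_matrix`: the labelled symmetric
#'   matrix `J` with unit diagonal.
#' @export
similarity_matrix <- function(sets, labels = names(sets)) {
  n <- length(sets)
  if (n < 2) stop("similarity_matrix: need >= 2 sets")
  if (is.null(labels)) labels <- paste0("set", seq_len(n))
  if (anyDuplicated(labels)) stop("similarity_matrix: duplicate labels")
  J <- diag(1, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      J[i, j] <- J[j, i] <- jaccard(sets[[i]], sets[[j]])
    }
  }
  dimnames(J) <- list(labels, labels)
  structure(J, class = c("similarity_matrix", "matrix"))
}

#' Hierarchical clustering of a similarity matrix
#'
#' Agglomerative clustering on the Jaccard distance `D = 1 - J`.  Ties are
#' broken deterministically by the smallest (i, j) cluster-index pair so
#' clusterograms are identical across runs and platforms.  The result is a
#' standard `hclust` object (use [stats::cutree()] or `plot()` on it).
#'
#' @param S a [similarity_matrix()].
#' @param linkage `"average"` (UPGMA, default), `"single"` or `"complete"`.
#' @return an object of classes `peak_dendrogram` and `hclust`.
#' @export
cluster_similarity <- function(S, linkage = c("average", "single",
                                              "complete")) {
  linkage <- match.arg(linkage)
  D <- 1 - unclass(S)
  if (any(!is.finite(D))) stop("cluster_similarity: non-finite distances")
  n <- nrow(D)
  if (n < 2) stop("cluster_similarity: need >= 2 labels")
  # active clusters indexed by creation order; leaves are -i, merges are +k
  id <- -seq_len(n)          # hclust member codes
  size <- rep(1, n)
  active <- rep(TRUE, n)
  d <- D
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); bd <- Inf
    act <- which(active)
    for (ii in seq_along(act)[-length(act)]) {
      i <- act[ii]
      for (j in act[(ii + 1):length(act)]) {
        if (d[i, j] < bd) { bd <- d[i, j]; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    merge[step, ] <- c(id[i], id[j])
    height[step] <- bd
    # Lance-Williams update into slot i
    for (k in act) {
      if (k == i || k == j) next
      d[i, k] <- d[k, i] <- switch(linkage,
        average  = (size[i] * d[i, k] + size[j] * d[j, k]) /
                   (size[i] + size[j]),
        single   = min(d[i, k], d[j, k]),
        complete = max(d[i, k], d[j, k]))
    }
    size[i] <- size[i] + size[j]
    active[j] <- FALSE
    id[i] <- step
  }
  res <- list(merge = merge, height = height,
              order = dendrogram_order(merge),
              labels = rownames(D), method = linkage,
              dist.method = "jaccard", call = match.call())
  class(res) <- c("peak_dendrogram", "hclust")
  res
}

## leaf order by left-to-right traversal of the merge tree
dendrogram_order <- function(merge) {
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  walk(nrow(merge))
}

#' Cut a clusterogram into k groups
#'
#' Thin wrapper over [stats::cutree()] keeping label names.
#'
#' @param dend a [cluster_similarity()] result.
#' @param k number of groups.
#' @return named integer membership vector.
#' @export
cut_dendrogram <- function(dend, k) {
  stats::cutree(structure(unclass(dend), class = "hclust"), k = k)
}

#' Write a similarity matrix as labelled TSV
#' @param S a [similarity_matrix()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_similarity <- function(S, path) {
  df <- data.frame(label = rownames(S), unclass(S), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a dendrogram merge table
#'
#' One row per merge: the two member codes (negative = leaf index, positive =
#' earlier merge), the merge height (Jaccard distance) and the merged size.
#'
#' @param dend a [cluster_similarity()] result.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_dendrogram <- function(dend, path) {
  sizes <- numeric(nrow(dend$merge))
  cnt <- function(m) if (m < 0) 1 else sizes[m]
  for (i in seq_len(nrow(dend$merge))) {
    sizes[i] <- cnt(dend$merge[i, 1]) + cnt(dend$merge[i, 2])
  }
  df <- data.frame(member_i = dend$merge[, 1], member_j = dend$merge[, 2],
                   height = dend$height, size = sizes)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
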