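#' Single-linkage hierarchical clustering of a similarity matrix
#'
#' Implements the clustering step of the lesion analysis: the averaged
#' pairwise similarity matrix is subtracted from 1 to form a dissimilarity
#' matrix, which is clustered agglomeratively with the single-linkage
#' update `d(A U B, C) = min(d(A, C), d(B, C))`. At every step the pair of
#' clusters at minimum distance is merged; exact ties are broken
#' deterministically by the smallest (first, then second) cluster creation
#' index (singletons 1..n in input order, then merged clusters in creation
#' order).
#'
#' @param sbar Symmetric similarity matrix with unit diagonal (tolerance
#'   1e-9), values <= 1; or, with `dissimilarity = TRUE`, a symmetric
#'   dissimilarity matrix with zero diagonal.
#' @param dissimilarity Interpret `sbar` directly as dissimilarities.
#' @return An object of class `lesion_dendrogram`: `merge` (n-1 x 2,
#'   `hclust` convention: negatives are leaves), `height` (nondecreasing),
#'   `labels`.
#' @export
linkage_single <- function(sbar, dissimilarity = FALSE) {
  sbar <- as.matrix(sbar)
  n <- nrow(sbar)
  stopifnot(n >= 2L, ncol(sbar) == n)
  if (max(abs(sbar - t(sbar))) > 1e-9) stop("input matrix must be symmetric")
  if (!dissimilarity) {
    if (max(abs(diag(sbar) - 1)) > 1e-9)
      stop("similarity matrix must have unit diagonal")
    D <- 1 - sbar
  } else D <- sbar
  labels <- rownames(sbar)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  # active-cluster bookkeeping: creation index (1..n singletons, then
  # n+step), hclust code (-leaf / +step), working distance matrix
  created <- seq_len(n)
  code <- -seq_len(n)
  W <- D
  diag(W) <- Inf
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    m <- min(W)
    cand <- which(W == m, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- cbind(pmin(created[cand[, 1]], created[cand[, 2]]),
                 pmax(created[cand[, 1]], created[cand[, 2]]))
    pick <- order(key[, 1], key[, 2])[1]
    i <- cand[pick, 1]; j <- cand[pick, 2]
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    merge[step, ] <- if (created[i] <= created[j]) c(code[i], code[j])
                     else c(code[j], code[i])
    height[step] <- m
    # single-linkage update into slot i, drop slot j
    newd <- pmin(W[i, ], W[j, ])
    W[i, ] <- newd
    W[, i] <- newd
    W[i, i] <- Inf
    keep <- setdiff(seq_len(nrow(W)), j)
    W <- W[keep, keep, drop = FALSE]
    created[i] <- n + step
    code[i] <- step
    created <- created[keep]
    code <- code[keep]
  }
  structure(list(merge = merge, height = height, labels = labels,
                 method = "single"),
            class = "lesion_dendrogram")
}

#' @export
print.lesion_dendrogram <- function(x, ...) {
  cat("<lesion_dendrogram> ", length(x$labels), " leaves, single linkage; ",
      "merge heights [", round(min(x$height), 4), ", ",
      round(max(x$height), 4), "]\n", sep = "")
  invisible(x)
}

#' Convert a dendrogram to a base-R `hclust` object
#'
#' @param dendrogram A `lesion_dendrogram`.
#' @return An object of class `hclust` (plottable with `plot()`).
#' @export
as_hclust <- function(dendrogram) {
  leaf_order <- function(code) {
    if (code < 0) return(-code)
    c(leaf_order(dendrogram$merge[code, 1]),
      leaf_order(dendrogram$merge[code, 2]))
  }
  structure(list(merge = dendrogram$merge, height = dendrogram$height,
                 order = leaf_order(nrow(dendrogram$merge)),
                 labels = dendrogram$labels, method = "single",
                 call = match.call(), dist.method = "1 - SSIM"),
            class = "hclust")
}

#' Cut a dendrogram into k groups
#'
#' Removes the k-1 largest-height merges (the last k-1 merges; single
#' linkage guarantees nondecreasing heights) and labels the resulting
#' connected components. Groups are numbered stably by their smallest
#' member index. If the cut falls inside a run of tied heights the result
#' depends on merge order; this is flagged in the `tie_at_cut` attribute.
#'
#' @param dendrogram A `lesion_dendrogram`.
#' @param k Number of groups, `1 <= k <= n`.
#' @return Integer vector of group labels (1..k) named by leaf labels, with
#'   attribute `tie_at_cut`.
#' @export
cut_groups <- function(dendrogram, k) {
  n <- length(dendrogram$labels)
  stopifnot(k >= 1L, k <= n)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  reps <- integer(n - 1L)   # representative leaf of each merged cluster
  use <- seq_len(max(0L, n - k))
  for (step in seq_len(n - 1L)) {
    a <- dendrogram$merge[step, 1]
    b <- dendrogram$merge[step, 2]
    ra <- if (a < 0) -a else reps[a]
    rb <- if (b < 0) -b else reps[b]
    reps[step] <- ra
    if (step %in% use) parent[find(rb)] <- find(ra)
  }
  root <- vapply(seq_len(n), find, integer(1))
  smallest <- vapply(seq_len(n), function(i) min(which(root == root[i])), integer(1))
  groups <- as.integer(factor(smallest, levels = sort(unique(smallest))))
  names(groups) <- dendrogram$labels
  tie <- k > 1L && k < n &&
    isTRUE(all.equal(dendrogram$height[n - k], dendrogram$height[n - k + 1L]))
  attr(groups, "tie_at_cut") <- tie
  groups
}
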