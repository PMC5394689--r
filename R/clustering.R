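#' Euclidean distances between samples
#'
#' Computes the pairwise Euclidean distance matrix between the columns of a
#' gene-by-sample matrix (samples are the clustering units; the matrix is
#' transposed internally so genes act as features).
#'
#' @param x Numeric matrix, genes in rows, samples in columns; all entries
#'   finite.
#' @return A symmetric numeric matrix of class `distance_matrix` with zero
#'   diagonal and sample ids as dimnames.
#' @export
sample_distances <- function(x) {
  bad <- which(!is.finite(x), arr.ind = TRUE)
  if (nrow(bad)) {
    feat <- if (is.null(rownames(x))) bad[1L, 1L] else rownames(x)[bad[1L, 1L]]
    samp <- if (is.null(colnames(x))) bad[1L, 2L] else colnames(x)[bad[1L, 2L]]
    stopf("non-finite value at feature '%s', sample '%s'", feat, samp)
  }
  d <- as.matrix(stats::dist(t(x), method = "euclidean"))
  distance_matrix(d)
}

#' @rdname sample_distances
#' @param d A symmetric nonnegative matrix with zero diagonal (validated).
#' @export
distance_matrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stopf("`d` must be a square matrix")
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("S", seq_len(nrow(d)))
  }
  if (anyNA(d) || any(!is.finite(d))) stopf("`d` contains non-finite entries")
  if (any(d < 0)) stopf("`d` contains negative distances")
  if (max(abs(d - t(d))) > 1e-8) stopf("`d` is not symmetric")
  if (any(abs(diag(d)) > 1e-12)) stopf("`d` has a nonzero diagonal")
  d <- (d + t(d)) / 2
  diag(d) <- 0
  class(d) <- c("distance_matrix", "matrix", "array")
  d
}

#' Complete-linkage agglomerative clustering
#'
#' Builds the sample dendrogram by repeatedly merging the two clusters with
#' the smallest complete-linkage distance (the maximum pairwise distance
#' between their members); the merge height is that distance. Ties are broken
#' deterministically: among tied pairs, the pair whose smallest contained leaf
#' index is lowest wins, then the smaller second index. Complete linkage
#' guarantees non-decreasing merge heights, which is asserted on every run.
#'
#' @param d A `distance_matrix` (or plain symmetric matrix) over n >= 2
#'   samples.
#' @return A `dendrogram_cl` list with `merge` (hclust-style (n-1) x 2
#'   matrix: negative entries are leaves, positive entries earlier merges),
#'   `height`, and `labels`.
#' @export
complete_linkage <- function(d) {
  if (!inherits(d, "distance_matrix")) d <- distance_matrix(as.matrix(d))
  n <- nrow(d)
  if (n < 2L) stopf("need at least 2 samples to cluster")
  labels <- rownames(d)
  D <- unclass(d)
  diag(D) <- Inf
  active <- rep(TRUE, n)
  node_id <- -seq_len(n) # hclust convention: leaves negative
  min_leaf <- seq_len(n) # smallest original leaf index in each cluster
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    act <- which(active)
    sub <- D[act, act, drop = FALSE]
    h <- min(sub)
    # all tied candidate pairs, as positions in `act`
    cand <- which(sub <= h, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    a <- act[cand[, 1L]]
    b <- act[cand[, 2L]]
    lo <- pmin(min_leaf[a], min_leaf[b])
    hi <- pmax(min_leaf[a], min_leaf[b])
    pick <- order(lo, hi)[1L]
    i <- a[pick]
    j <- b[pick]
    ni <- node_id[i]
    nj <- node_id[j]
    # hclust merge-row convention: singletons before clusters, ordered within
    if ((ni < 0 && nj < 0 && ni > nj) || (ni > 0 && nj < 0) ||
      (ni > 0 && nj > 0 && ni > nj)) {
      tmp <- ni
      ni <- nj
      nj <- tmp
    }
    merge[step, ] <- c(ni, nj)
    height[step] <- h
    # Lance-Williams update for complete linkage: new distances are maxima
    newd <- pmax(D[i, ], D[j, ])
    D[i, ] <- newd
    D[, i] <- newd
    D[i, i] <- Inf
    active[j] <- FALSE
    D[j, ] <- Inf
    D[, j] <- Inf
    node_id[i] <- step
    min_leaf[i] <- min(min_leaf[i], min_leaf[j])
  }
  if (any(diff(height) < -1e-9)) {
    stopf("internal error: complete-linkage heights decreased")
  }
  structure(
    list(merge = merge, height = height, labels = labels),
    class = "dendrogram_cl"
  )
}

#' @export
print.dendrogram_cl <- function(x, ...) {
  cat(sprintf(
    "<dendrogram_cl> %d leaves, %d merges, height range [%g, %g]\n",
    length(x$labels), nrow(x$merge), min(x$height), max(x$height)
  ))
  invisible(x)
}

#' Convert to a base-R hclust object
#'
#' @param x A `dendrogram_cl`.
#' @param ... Unused.
#' @return An object of class `hclust` (usable with `plot()`, `cutree()`...).
#' @export
as.hclust.dendrogram_cl <- function(x, ...) {
  n <- length(x$labels)
  # build a valid leaf order by walking the merge tree
  order_of <- function(node) {
    if (node < 0) {
      return(-node)
    }
    c(order_of(x$merge[node, 1L]), order_of(x$merge[node, 2L]))
  }
  structure(
    list(
      merge = x$merge, height = x$height, order = order_of(n - 1L),
      labels = x$labels, method = "complete", call = match.call(),
      dist.method = "euclidean"
    ),
    class = "hclust"
  )
}

#' Cophenetic distance matrix of a dendrogram
#'
#' The cophenetic distance between two leaves is the merge height at which
#' their branches first join. The resulting matrix is ultrametric:
#' `c(i,k) <= max(c(i,j), c(j,k))` for all triples.
#'
#' @param tree A `dendrogram_cl` from [complete_linkage()].
#' @return A symmetric matrix of class `cophenetic_matrix` with zero
#'   diagonal, sample ids as dimnames.
#' @export
cophenetic_matrix <- function(tree) {
  if (!inherits(tree, "dendrogram_cl")) stopf("`tree` must be a dendrogram_cl")
  n <- length(tree$labels)
  C <- matrix(0, n, n, dimnames = list(tree$labels, tree$labels))
  members <- vector("list", n - 1L)
  for (step in seq_len(n - 1L)) {
    side <- function(node) if (node < 0) -node else members[[node]]
    left <- side(tree$merge[step, 1L])
    right <- side(tree$merge[step, 2L])
    C[left, right] <- tree$height[step]
    C[right, left] <- tree$height[step]
    members[[step]] <- c(left, right)
  }
  class(C) <- c("cophenetic_matrix", "matrix", "array")
  C
}

#' Export a dendrogram as a Newick string
#'
#' Branch lengths are differences between parent and child merge heights
#' (leaves sit at height 0), so root-to-leaf path lengths reproduce the merge
#' heights.
#'
#' @param tree A `dendrogram_cl`.
#' @param path Optional file to write to.
#' @param digits Significant digits for branch lengths.
#' @return The Newick string, invisibly if `path` is given.
#' @export
to_newick <- function(tree, path = NULL, digits = 10) {
  fmt <- function(x) formatC(x, digits = digits, format = "g")
  build <- function(node, parent_height) {
    if (node < 0) {
      leaf <- -node
      return(sprintf("%s:%s", tree$labels[leaf], fmt(parent_height)))
    }
    h <- tree$height[node]
    sprintf(
      "(%s,%s):%s",
      build(tree$merge[node, 1L], h), build(tree$merge[node, 2L], h),
      fmt(parent_height - h)
    )
  }
  n <- length(tree$labels)
  root <- n - 1L
  h <- tree$height[root]
  nwk <- sprintf(
    "(%s,%s);",
    build(tree$merge[root, 1L], h), build(tree$merge[root, 2L], h)
  )
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

#' Check the ultrametric inequality on a matrix
#'
#' @param C Symmetric matrix.
#' @param tol Absolute slack.
#' @return TRUE/FALSE.
#' @export
is_ultrametric <- function(C, tol = 1e-9) {
  n <- nrow(C)
  for (j in seq_len(n)) {
    # c(i,k) <= max(c(i,j), c(j,k)) for all i,k, vectorized over the j-th pivot
    m <- outer(C[, j], C[j, ], pmax)
    if (any(C > m + tol)) {
      return(FALSE)
    }
  }
  TRUE
}
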