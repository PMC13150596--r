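#' Principal component analysis by SVD
#'
#' Computed as the singular value decomposition of the (already centered)
#' data matrix: loadings are right singular vectors, scores the projections,
#' and the explained-variance ratio of component i is
#' `100 * sigma_i^2 / sum(sigma_j^2)`. Sign convention: the
#' largest-magnitude element of each loading column is positive, so score
#' plots are reproducible.
#'
#' @param x centered numeric matrix (column means ~ 0; enforced).
#' @param k number of components, `1 <= k <= min(n - 1, p)`.
#' @param tol tolerance on column means for the centering contract.
#' @return list of class `pca_result`: `scores` (n x k), `loadings` (p x k),
#'   `explained_variance_ratio` (length k, percent), `k`.
#' @export
pca <- function(x, k = 2L, tol = 1e-8) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (max(abs(colMeans(x))) > tol * max(1, max(abs(x)))) {
    stop("pca() expects a centered matrix (column means above tolerance)",
         call. = FALSE)
  }
  if (k < 1L || k > min(n - 1L, p)) {
    stop(sprintf("k must lie in [1, %d]", min(n - 1L, p)), call. = FALSE)
  }
  sv <- svd(x)
  load <- sv$v[, seq_len(k), drop = FALSE]
  flip <- apply(load, 2L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  load <- sweep(load, 2L, flip, "*")
  tot <- sum(sv$d^2)
  evr <- if (tot > 0) 100 * sv$d[seq_len(k)]^2 / tot else rep(0, k)
  structure(list(scores = x %*% load, loadings = load,
                 explained_variance_ratio = evr, k = k),
            class = "pca_result")
}

#' Agglomerative hierarchical clustering
#'
#' Bottom-up clustering from the Euclidean distance matrix with
#' Lance-Williams updates. Ties are broken deterministically: among pairs at
#' the minimal distance, the lexicographically smallest pair of active
#' cluster positions (creation order: singletons in row order, then merges)
#' is merged, so the dendrogram is invariant to row order up to relabelling.
#'
#' @param x numeric matrix (rows clustered) or a [spectral_dataset].
#' @param metric distance metric; only `"euclidean"`.
#' @param linkage `"average"`, `"complete"` or `"ward"` (Ward.D2 form, on
#'   Euclidean distances).
#' @param labels optional leaf labels (default: dataset sample ids or row
#'   numbers).
#' @return list of class `dendrogram_result`: `merge` (hclust-style merge
#'   matrix), `height`, `order`, `labels`, `linkage`, and `sizes` (cluster
#'   size after each merge).
#' @export
hca <- function(x, metric = "euclidean",
                linkage = c("average", "complete", "ward"), labels = NULL) {
  linkage <- match.arg(linkage)
  metric <- match.arg(metric, "euclidean")
  if (inherits(x, "spectral_dataset")) {
    if (is.null(labels)) labels <- x$sample_ids
    x <- x$intensities
  }
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2L) stop("clustering needs at least 2 rows", call. = FALSE)
  if (is.null(labels)) labels <- as.character(seq_len(n))

  D <- as.matrix(stats::dist(x))
  # active cluster bookkeeping: id in hclust convention (-row or +merge)
  ids <- -seq_len(n)
  sizes <- rep(1L, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  msize <- integer(n - 1L)
  for (step in seq_len(n - 1L)) {
    m <- length(ids)
    bi <- bj <- 0L; best <- Inf
    for (i in seq_len(m - 1L)) {
      for (j in seq.int(i + 1L, m)) {
        if (D[i, j] < best) { best <- D[i, j]; bi <- i; bj <- j }
      }
    }
    merge[step, ] <- sort(c(ids[bi], ids[bj]))
    height[step] <- best
    ni <- sizes[bi]; nj <- sizes[bj]
    msize[step] <- ni + nj
    # Lance-Williams update of distances to the merged cluster
    keep <- setdiff(seq_len(m), c(bi, bj))
    dnew <- vapply(keep, function(kk) {
      di <- D[kk, bi]; dj <- D[kk, bj]; nk <- sizes[kk]
      switch(linkage,
        average = (ni * di + nj * dj) / (ni + nj),
        complete = max(di, dj),
        ward = sqrt(((nk + ni) * di^2 + (nk + nj) * dj^2 -
                       nk * best^2) / (nk + ni + nj))
      )
    }, numeric(1))
    D <- D[keep, keep, drop = FALSE]
    D <- rbind(cbind(D, dnew), c(dnew, 0))
    ids <- c(ids[keep], step)
    sizes <- c(sizes[keep], ni + nj)
  }
  ord <- dendro_leaf_order(merge, n)
  structure(list(merge = merge, height = height, order = ord,
                 labels = labels, linkage = linkage, sizes = msize),
            class = "dendrogram_result")
}

dendro_leaf_order <- function(merge, n) {
  leaves <- function(node) {
    if (node < 0L) return(-node)
    c(leaves(merge[node, 1L]), leaves(merge[node, 2L]))
  }
  leaves(n - 1L)
}

#' Convert a dendrogram to a base hclust object
#'
#' @param dendro a `dendrogram_result` from [hca()].
#' @return an object of class `hclust`.
#' @export
as_hclust <- function(dendro) {
  structure(list(merge = dendro$merge, height = dendro$height,
                 order = dendro$order, labels = dendro$labels,
                 method = dendro$linkage, call = NULL,
                 dist.method = "euclidean"),
            class = "hclust")
}

#' Export a dendrogram as a Newick string
#'
#' Branch lengths are merge-height differences (ultrametric tree).
#'
#' @param dendro a `dendrogram_result`.
#' @param path optional file to write to.
#' @return the Newick string, invisibly when written to file.
#' @export
dendrogram_newick <- function(dendro, path = NULL) {
  phy <- ape::as.phylo(as_hclust(dendro))
  s <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}

#' Two-group separation purity of a dendrogram
#'
#' Cuts the tree at the top merge into two clusters and reports the fraction
#' of leaves whose cluster's majority class equals their own class. Purity
#' 1.0 means the top split recovers the two classes exactly.
#'
#' @param dendro a `dendrogram_result`.
#' @param classes per-leaf class labels (two labels).
#' @return purity fraction in [0, 1].
#' @export
two_group_separation <- function(dendro, classes) {
  n <- nrow(dendro$merge) + 1L
  if (n < 2L) stop("degenerate single-leaf tree", call. = FALSE)
  stopifnot(length(classes) == n)
  cl <- stats::cutree(as_hclust(dendro), k = 2L)
  correct <- 0L
  for (g in unique(cl)) {
    members <- which(cl == g)
    tab <- sort(table(classes[members]), decreasing = TRUE)
    maj <- names(tab)[1]  # alphabetical first on exact ties (sort is stable)
    correct <- correct + sum(classes[members] == maj)
  }
  correct / n
}
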