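#' Kennard-Stone sample selection
#'
#' Deterministic max-min selection: the first two picks are the pair of rows
#' at maximal Euclidean distance (ties: lexicographically smallest index
#' pair); every subsequent pick maximizes the minimum distance to the rows
#' already selected (ties: smallest row index). The returned order is the
#' selection order, so prefixes are themselves Kennard-Stone selections.
#'
#' @param x numeric matrix of candidate rows.
#' @param n_select number of rows to select, `2 <= n_select <= nrow(x)`.
#' @return integer vector of row indices in selection order.
#' @export
kennard_stone <- function(x, n_select) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n_select < 2L || n_select > n) {
    stop(sprintf("n_select must lie in [2, %d]", n), call. = FALSE)
  }
  D <- as.matrix(stats::dist(x))
  # farthest pair, lexicographically smallest among ties
  best <- -Inf; bi <- bj <- 1L
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (D[i, j] > best) { best <- D[i, j]; bi <- i; bj <- j }
    }
  }
  sel <- c(bi, bj)
  mind <- pmin(D[, bi], D[, bj])  # min distance of each row to the selection
  while (length(sel) < n_select) {
    mind[sel] <- -Inf
    nxt <- as.integer(which.max(mind))  # smallest index among exact ties
    sel <- c(sel, nxt)
    mind <- pmin(mind, D[, nxt])
  }
  unname(sel)
}

#' Class-stratified Kennard-Stone train/test split
#'
#' Runs [kennard_stone()] within each class on that class's (preprocessed,
#' replicate-averaged) spectra. The per-class training quota is
#' `floor(train_fraction * n_class + 0.5)`; with the 2/3 default on a
#' 15 + 18 design this yields the 10 + 12 = 22 training and 11 test samples
#' of a two-thirds division. Remaining rows form the test set.
#'
#' @param ds a [spectral_dataset] with two classes.
#' @param train_fraction per-class training fraction (default 2/3).
#' @return list of class `split_result`: `train_indices`, `test_indices`
#'   (row indices into `ds`, train in KS selection order),
#'   `per_class_train_counts` (named integer vector).
#' @export
stratified_split <- function(ds, train_fraction = 2 / 3) {
  validate_dataset(ds, require_two_classes = TRUE)
  labs <- sort(unique(ds$classes))
  train <- integer(0)
  counts <- stats::setNames(integer(length(labs)), labs)
  for (lab in labs) {
    rows <- which(ds$classes == lab)
    n_lab <- length(rows)
    if (n_lab < 3L) {
      stop(sprintf("class '%s' has %d samples; need >= 3 to split",
                   lab, n_lab), call. = FALSE)
    }
    quota <- floor(train_fraction * n_lab + 0.5)
    if (quota < 1L || quota >= n_lab) {
      stop(sprintf(
        "degenerate split for class '%s': quota %d of %d samples",
        lab, quota, n_lab), call. = FALSE)
    }
    quota <- max(quota, 2L)  # KS needs at least a pair
    picked <- kennard_stone(ds$intensities[rows, , drop = FALSE], quota)
    train <- c(train, rows[picked])
    counts[lab] <- quota
  }
  structure(list(train_indices = train,
                 test_indices = setdiff(seq_len(nrow(ds$intensities)), train),
                 per_class_train_counts = counts),
            class = "split_result")
}
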