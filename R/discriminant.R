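#' Fit a two-class linear discriminant
#'
#' Classical two-class LDA with equal priors: the weight vector is
#' `pooled_covariance^-1 (mean_pos - mean_neg)` with the pooled covariance
#' equal to the within-class scatter divided by `n - 2`, and the bias places
#' the decision boundary at the midpoint of the class means. If the pooled
#' covariance is numerically singular (reciprocal condition below
#' `rcond_tol`), a ridge `lambda * trace/k * I` is added with `lambda`
#' escalated by decades from 1e-8 to 1e-2 and recorded, so unregularized
#' ("classical") fits are identifiable by `lambda = 0`.
#'
#' @param x training matrix, a [spectral_dataset] or numeric matrix.
#' @param classes per-row class labels (taken from the dataset when `x` is
#'   one); exactly two labels, each with at least 2 rows.
#' @param indices optional column indices to restrict the model to (the
#'   selected variables).
#' @param positive_class label treated as "positive" in scores and figures
#'   of merit; default the first label in sorted order.
#' @param rcond_tol reciprocal-condition threshold triggering regularization.
#' @return list of class `discriminant_model`: `weights`, `bias`,
#'   `class_means`, `pooled_covariance`, `selected_indices`,
#'   `positive_class`, `negative_class`, `lambda`.
#' @export
fit_lda <- function(x, classes = NULL, indices = NULL, positive_class = NULL,
                    rcond_tol = 1e-10) {
  if (inherits(x, "spectral_dataset")) {
    classes <- x$classes
    x <- x$intensities
  }
  x <- as.matrix(x)
  if (!is.null(indices)) x <- x[, indices, drop = FALSE]
  labs <- sort(unique(classes))
  if (length(labs) != 2L) stop("fit_lda requires exactly two classes",
                               call. = FALSE)
  if (is.null(positive_class)) positive_class <- labs[1]
  stopifnot(positive_class %in% labs)
  neg <- setdiff(labs, positive_class)
  if (min(table(classes)) < 2L) {
    stop("each class needs at least 2 training rows", call. = FALSE)
  }
  n <- nrow(x); k <- ncol(x)
  if (k > n - 2L) {
    stop(sprintf("%d variables exceed the n - 2 = %d LDA limit", k, n - 2L),
         call. = FALSE)
  }
  xp <- x[classes == positive_class, , drop = FALSE]
  xn <- x[classes == neg, , drop = FALSE]
  mp <- colMeans(xp); mn <- colMeans(xn)
  sc <- function(m) crossprod(sweep(m, 2L, colMeans(m)))
  S <- (sc(xp) + sc(xn)) / (n - 2)
  reg <- regularize_spd(S, rcond_tol)
  if (is.null(reg)) {
    stop("pooled covariance singular even after regularization cap",
         call. = FALSE)
  }
  w <- drop(solve(reg$S, mp - mn))
  b <- -sum(w * (mp + mn) / 2)
  structure(list(weights = w, bias = b,
                 class_means = list(positive = mp, negative = mn),
                 pooled_covariance = reg$S,
                 selected_indices = indices,
                 positive_class = positive_class, negative_class = neg,
                 lambda = reg$lambda),
            class = "discriminant_model")
}

# ridge escalation shared by all LDA fits; returns NULL if the cap is hit
regularize_spd <- function(S, rcond_tol = 1e-10) {
  k <- ncol(S)
  ok <- function(M) is.finite(rcond(M)) && rcond(M) > rcond_tol
  if (ok(S)) return(list(S = S, lambda = 0))
  tr <- sum(diag(S)) / k
  if (tr <= 0) tr <- 1
  lambda <- 1e-8
  while (lambda <= 1e-2) {
    M <- S + lambda * tr * diag(k)
    if (ok(M)) return(list(S = M, lambda = lambda))
    lambda <- lambda * 10
  }
  NULL
}

#' Discriminant scores
#'
#' `weights . x + bias` per row; positive score classifies as the positive
#' class, a score of exactly 0 (ties) as the negative class.
#'
#' @param model a `discriminant_model`.
#' @param x matrix of rows restricted to the model's selected variables, or
#'   a [spectral_dataset] / full matrix when the model stores
#'   `selected_indices`.
#' @return numeric vector of discriminant values.
#' @export
score_lda <- function(model, x) {
  if (inherits(x, "spectral_dataset")) x <- x$intensities
  x <- as.matrix(x)
  if (!is.null(model$selected_indices) &&
      ncol(x) != length(model$weights)) {
    x <- x[, model$selected_indices, drop = FALSE]
  }
  if (ncol(x) != length(model$weights)) {
    stop("column count does not match the model dimension", call. = FALSE)
  }
  drop(x %*% model$weights) + model$bias
}

#' Classify with a discriminant model
#'
#' @inheritParams score_lda
#' @return character vector of predicted class labels.
#' @export
predict_lda <- function(model, x) {
  s <- score_lda(model, x)
  ifelse(s > 0, model$positive_class, model$negative_class)
}

#' Confusion counts for two-class predictions
#'
#' @param truth,predicted class label vectors.
#' @param positive_class the label counted as positive.
#' @return list of class `confusion_counts` with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(truth, predicted, positive_class) {
  pos <- truth == positive_class
  ppos <- predicted == positive_class
  structure(list(TP = sum(pos & ppos), TN = sum(!pos & !ppos),
                 FP = sum(!pos & ppos), FN = sum(pos & !ppos)),
            class = "confusion_counts")
}

#' Figures of merit from confusion counts
#'
#' Sensitivity `= TP/(TP+FN) * 100`, specificity `= TN/(TN+FP) * 100`,
#' accuracy `= (TP+TN)/(TP+TN+FP+FN) * 100`, all in percent.
#'
#' @param counts a `confusion_counts`.
#' @return list of class `figures_of_merit` with `sensitivity`,
#'   `specificity`, `accuracy` (percent).
#' @export
figures_of_merit <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (counts$TP + counts$FN == 0) {
    stop("sensitivity undefined: no positive-class samples (TP + FN = 0)",
         call. = FALSE)
  }
  if (counts$TN + counts$FP == 0) {
    stop("specificity undefined: no negative-class samples (TN + FP = 0)",
         call. = FALSE)
  }
  n <- counts$TP + counts$TN + counts$FP + counts$FN
  structure(list(
    sensitivity = 100 * counts$TP / (counts$TP + counts$FN),
    specificity = 100 * counts$TN / (counts$TN + counts$FP),
    accuracy = 100 * (counts$TP + counts$TN) / n
  ), class = "figures_of_merit")
}

#' Leave-one-out cross-validated LDA
#'
#' Each row is classified by a model fitted on all remaining rows. A fold
#' whose pooled covariance stays singular after the regularization cap (or
#' that empties a class) is counted as a misclassification with a warning,
#' keeping the estimator total. Deterministic; invariant to row order.
#'
#' @inheritParams fit_lda
#' @return list with `confusion` (a `confusion_counts`), `fom` (a
#'   `figures_of_merit`) and `predicted` (per-row labels; `NA` for failed
#'   folds).
#' @export
loo_cv <- function(x, classes = NULL, indices = NULL, positive_class = NULL) {
  if (inherits(x, "spectral_dataset")) {
    classes <- x$classes
    x <- x$intensities
  }
  x <- as.matrix(x)
  if (!is.null(indices)) x <- x[, indices, drop = FALSE]
  labs <- sort(unique(classes))
  stopifnot(length(labs) == 2L)
  if (is.null(positive_class)) positive_class <- labs[1]
  if (min(table(classes)) < 3L) {
    stop("leave-one-out needs at least 3 rows per class", call. = FALSE)
  }
  n <- nrow(x)
  pred <- rep(NA_character_, n)
  failed <- 0L
  for (i in seq_len(n)) {
    fit <- try(fit_lda(x[-i, , drop = FALSE], classes[-i],
                       positive_class = positive_class), silent = TRUE)
    if (inherits(fit, "try-error")) { failed <- failed + 1L; next }
    pred[i] <- predict_lda(fit, x[i, , drop = FALSE])
  }
  if (failed > 0L) {
    warning(sprintf("%d singular fold(s) counted as misclassifications",
                    failed), call. = FALSE)
  }
  # NA predictions count against the truth (wrong by construction)
  eff <- ifelse(is.na(pred),
                ifelse(classes == positive_class,
                       setdiff(labs, positive_class), positive_class),
                pred)
  cc <- confusion_counts(classes, eff, positive_class)
  list(confusion = cc, fom = figures_of_merit(cc), predicted = pred)
}

#' Leave-one-out LDA misclassification fraction
#'
#' The scalar cost both variable-selection searches minimize; computed by
#' compiled code for speed and asserted equal to [loo_cv()] in the test
#' suite.
#'
#' @param x numeric matrix (rows = training samples, columns = the candidate
#'   variables).
#' @param classes per-row labels, exactly two.
#' @param positive_class optional; irrelevant to the error fraction.
#' @return misclassification fraction in [0, 1].
#' @export
loo_cost <- function(x, classes, positive_class = NULL) {
  labs <- sort(unique(classes))
  stopifnot(length(labs) == 2L)
  if (is.null(positive_class)) positive_class <- labs[1]
  y <- as.integer(classes == positive_class)
  loo_lda_cost_cpp(as.matrix(x), y)
}

#' Evaluate a train/test split on selected variables
#'
#' Cross-validated figures come from [loo_cv()] on the training partition;
#' test figures from a single fit on all training rows scored on the test
#' partition. Discriminant values are reported for every sample (train and
#' test flags) for plotting, alongside per-variable Fisher weights.
#'
#' @param train,test [spectral_dataset] partitions (disjoint); `test` may be
#'   `NULL` or empty.
#' @param indices selected column indices.
#' @param positive_class optional positive label (default first sorted).
#' @return list of class `evaluation_report`: `cv` and `test` (each with
#'   `confusion` and `fom`; `test` is `NULL` with `test_absent = TRUE` when
#'   no test rows), `scores` (data.frame sample_id/class/set/score/predicted),
#'   `fisher` (from [fisher_weights()]), `model`, `positive_class`.
#' @export
evaluate_split <- function(train, test = NULL, indices,
                           positive_class = NULL) {
  validate_dataset(train, require_two_classes = TRUE)
  cv <- loo_cv(train, indices = indices, positive_class = positive_class)
  model <- fit_lda(train, indices = indices, positive_class = positive_class)
  fisher <- fisher_weights(train, indices)
  str_train <- score_lda(model, train$intensities[, indices, drop = FALSE])
  scores <- data.frame(
    sample_id = train$sample_ids, class = train$classes, set = "train",
    score = str_train,
    predicted = ifelse(str_train > 0, model$positive_class,
                       model$negative_class),
    stringsAsFactors = FALSE
  )
  test_absent <- is.null(test) || nrow(test$intensities) == 0L
  test_res <- NULL
  if (!test_absent) {
    st <- score_lda(model, test$intensities[, indices, drop = FALSE])
    pred <- ifelse(st > 0, model$positive_class, model$negative_class)
    cc <- confusion_counts(test$classes, pred, model$positive_class)
    test_res <- list(confusion = cc, fom = figures_of_merit(cc))
    scores <- rbind(scores, data.frame(
      sample_id = test$sample_ids, class = test$classes, set = "test",
      score = st, predicted = pred, stringsAsFactors = FALSE
    ))
  }
  structure(list(cv = list(confusion = cv$confusion, fom = cv$fom),
                 test = test_res, test_absent = test_absent,
                 scores = scores, fisher = fisher, model = model,
                 positive_class = model$positive_class),
            class = "evaluation_report")
}
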