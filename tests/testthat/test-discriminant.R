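test_that("fit_lda reproduces the symmetric one-dimensional case", {
  x <- matrix(c(-2, -1, 0, 0, 1, 2), ncol = 1)
  classes <- rep(c("b", "a"), each = 3)  # positive = "a", mean +1
  m <- fit_lda(x, classes)
  expect_equal(unname(m$weights), 2)   # 2 * 1^-1 * (1 - (-1)) / 2
  expect_equal(m$bias, 0)
  expect_equal(m$lambda, 0)
  expect_equal(score_lda(m, matrix(0)), 0)
  expect_identical(predict_lda(m, matrix(0)), "b")  # tie -> negative class
  # class means classify as their own class
  expect_identical(predict_lda(m, matrix(1)), "a")
  expect_identical(predict_lda(m, matrix(-1)), "b")
})

test_that("equal class means degenerate to the negative-class tie rule", {
  x <- matrix(c(-1, 0, 1, -1, 0, 1), ncol = 1)
  classes <- rep(c("A", "B"), each = 3)
  m <- fit_lda(x, classes)
  expect_equal(unname(m$weights), 0)
  expect_equal(score_lda(m, x), rep(0, 6))
  expect_identical(unique(predict_lda(m, x)), "B")
})

test_that("fit_lda predictions equal the Mahalanobis closest-class rule", {
  set.seed(61)
  for (rep in 1:10) {
    n <- 20
    xtr <- matrix(rnorm(2 * n), n, 2)
    xtr[1:10, 1] <- xtr[1:10, 1] + 2
    ytr <- rep(c("A", "B"), each = 10)
    xte <- matrix(rnorm(30), 15, 2)
    m <- fit_lda(xtr, ytr)
    expect_identical(predict_lda(m, xte),
                     mahalanobis_oracle(xtr, ytr, xte, "A"))
  }
})

test_that("fit_lda agrees with MASS::lda on well-conditioned data", {
  skip_if_not_installed("MASS")
  set.seed(62)
  xtr <- rbind(matrix(rnorm(30, -1), 10, 3), matrix(rnorm(30, 1), 10, 3))
  ytr <- rep(c("A", "B"), each = 10)
  xte <- matrix(rnorm(60), 20, 3)
  ref <- MASS::lda(xtr, grouping = ytr, prior = c(0.5, 0.5))
  expect_identical(predict_lda(fit_lda(xtr, ytr), xte),
                   as.character(predict(ref, xte)$class))
})

test_that("score_lda vanishes at the class-mean midpoint and is positive at the positive mean", {
  set.seed(63)
  x <- rbind(matrix(rnorm(20, 2), 5, 4), matrix(rnorm(24, -1), 6, 4))
  classes <- rep(c("A", "B"), c(5, 6))
  m <- fit_lda(x, classes)
  mid <- (m$class_means$positive + m$class_means$negative) / 2
  expect_equal(score_lda(m, matrix(mid, 1)), 0, tolerance = 1e-10)
  expect_gt(score_lda(m, matrix(m$class_means$positive, 1)), 0)
  expect_error(score_lda(m, matrix(0, 1, 2)), "column count")
})

test_that("LDA rejects more variables than the sample size supports", {
  x <- matrix(rnorm(5 * 8), 5, 8)
  expect_error(fit_lda(x, c("A", "A", "B", "B", "B")), "exceed")
})

test_that("loo_cv conserves counts and is row-permutation invariant", {
  set.seed(64)
  x <- rbind(matrix(rnorm(30, 1.5), 10, 3), matrix(rnorm(36, -1.5), 12, 3))
  classes <- rep(c("A", "B"), c(10, 12))
  res <- loo_cv(x, classes)
  cc <- res$confusion
  expect_equal(cc$TP + cc$TN + cc$FP + cc$FN, 22)
  perm <- sample(22)
  res_p <- loo_cv(x[perm, ], classes[perm])
  expect_equal(unclass(res_p$confusion), unclass(cc))
  expect_identical(res_p$predicted, res$predicted[perm])
})

test_that("loo_cv and the compiled cost agree across random problems", {
  set.seed(65)
  for (rep in 1:20) {
    n <- sample(10:16, 1)
    k <- sample(1:5, 1)
    x <- matrix(rnorm(n * k), n, k)
    if (rep %% 4 == 0 && k >= 2) x[, 2] <- x[, 1]  # duplicated column
    classes <- sample(rep(c("A", "B"), c(ceiling(n / 2), floor(n / 2))))
    res <- suppressWarnings(loo_cv(x, classes))
    frac_wrong <- (res$confusion$FP + res$confusion$FN) / n
    expect_equal(loo_cost(x, classes), frac_wrong)
  }
})

test_that("loo_cv reaches 100% on separated data and chance on permuted labels", {
  ps <- perfectly_separable(n_a = 8, n_b = 9, p = 3, sep_col = 1, seed = 66)
  res <- loo_cv(ps$x, ps$classes)
  expect_equal(res$fom$sensitivity, 100)
  expect_equal(res$fom$specificity, 100)
  expect_equal(res$fom$accuracy, 100)
  set.seed(67)
  acc <- replicate(10, {
    x <- matrix(rnorm(22 * 2), 22, 2)  # no class signal at all
    loo_cv(x, rep(c("A", "B"), 11))$fom$accuracy
  })
  expect_gt(mean(acc), 20)
  expect_lt(mean(acc), 65)
})

test_that("figures of merit match hand arithmetic exactly", {
  perfect <- structure(list(TP = 5L, TN = 6L, FP = 0L, FN = 0L),
                       class = "confusion_counts")
  f <- figures_of_merit(perfect)
  expect_equal(c(f$sensitivity, f$specificity, f$accuracy), c(100, 100, 100))
  cc <- structure(list(TP = 3L, TN = 4L, FP = 2L, FN = 1L),
                  class = "confusion_counts")
  f2 <- figures_of_merit(cc)
  expect_equal(f2$sensitivity, 75)
  expect_equal(f2$specificity, 100 * 4 / 6)
  expect_equal(f2$accuracy, 70)
  bad <- structure(list(TP = 0L, TN = 4L, FP = 2L, FN = 0L),
                   class = "confusion_counts")
  expect_error(figures_of_merit(bad), "sensitivity undefined")
})

test_that("accuracy is the prevalence-weighted combination of SEN and SPE", {
  set.seed(68)
  for (rep in 1:20) {
    cc <- structure(as.list(stats::setNames(sample(0:10, 4, replace = TRUE),
                                            c("TP", "TN", "FP", "FN"))),
                    class = "confusion_counts")
    if (cc$TP + cc$FN == 0 || cc$TN + cc$FP == 0) next
    f <- figures_of_merit(cc)
    n <- cc$TP + cc$TN + cc$FP + cc$FN
    expect_equal(f$accuracy,
                 (f$sensitivity * (cc$TP + cc$FN) +
                    f$specificity * (cc$TN + cc$FP)) / n)
  }
})

test_that("evaluate_split reports consistent CV and test metrics end-to-end", {
  fix <- uv_samples(seed = 7)
  part <- supervised_partition(fix$samples)
  markers <- c(fix$ground_truth$marker_indices_a,
               fix$ground_truth$marker_indices_b)
  rep_ <- evaluate_split(part$train, part$test, markers)
  expect_equal(rep_$cv$fom$accuracy, 100)
  expect_equal(rep_$test$fom$accuracy, 100)
  # metrics recompute exactly from the stored confusion counts
  expect_equal(unclass(rep_$cv$fom),
               unclass(figures_of_merit(rep_$cv$confusion)))
  expect_equal(unclass(rep_$test$fom),
               unclass(figures_of_merit(rep_$test$confusion)))
  expect_equal(nrow(rep_$scores), 33)
  expect_setequal(unique(rep_$scores$set), c("train", "test"))
  # empty test partition -> explicit flag, cv only
  rep0 <- evaluate_split(part$train, NULL, markers)
  expect_true(rep0$test_absent)
  expect_null(rep0$test)
})
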