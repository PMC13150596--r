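# brute-force Savitzky-Golay oracle: explicit least-squares fit per window,
# edge windows evaluated at the edge positions
sg_oracle <- function(y, w, p) {
  n <- length(y)
  h <- (w - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, min(i - h, n - w + 1L))
    xs <- lo:(lo + w - 1L)
    X <- outer(xs, 0:p, "^")
    beta <- qr.solve(X, y[xs])
    out[i] <- sum(beta * i^(0:p))
  }
  out
}

test_that("SG filter reproduces polynomials up to its order exactly", {
  expect_equal(savgol_smooth(rep(5, 20), 13, 2), rep(5, 20))
  x <- 0:19
  expect_equal(savgol_smooth(x^2, 13, 2), x^2, tolerance = 1e-9)
  expect_equal(savgol_smooth(3 - 2 * x + 0.5 * x^2, 13, 2),
               3 - 2 * x + 0.5 * x^2, tolerance = 1e-9)
  expect_error(savgol_smooth(1:5, 13, 2), "too short")
  expect_error(savgol_smooth(1:20, 12, 2), "odd")
})

test_that("SG filter equals the per-window least-squares oracle on a cubic", {
  y <- (0:20)^3
  expect_equal(savgol_smooth(y, 13, 2), sg_oracle(y, 13L, 2L),
               tolerance = 1e-8)
  set.seed(9)
  y2 <- cumsum(rnorm(40))
  for (w in c(5L, 9L, 13L)) {
    expect_equal(savgol_smooth(y2, w, 2), sg_oracle(y2, w, 2L),
                 tolerance = 1e-8)
    expect_equal(savgol_smooth(y2, w, 3), sg_oracle(y2, w, 3L),
                 tolerance = 1e-8)
  }
})

test_that("baseline correction modes behave as specified", {
  expect_equal(baseline_correct(c(1, 2, 3), mode = "offset"), c(0, 1, 2))
  ax <- seq(240, 400, 10)
  lin <- 0.5 + 0.01 * ax
  expect_equal(baseline_correct(lin, ax, "linear_endpoints"),
               rep(0, length(ax)))
  expect_equal(baseline_correct(lin, ax, "none"), lin)
  # Gaussian band on a sloped baseline: endpoints exactly 0, equals
  # explicit line subtraction
  bandv <- band_profile(ax, band(320, 20, 1))
  y <- bandv + 0.3 - 0.002 * ax
  corr <- baseline_correct(y, ax, "linear_endpoints")
  line <- y[1] + (y[length(y)] - y[1]) / (ax[length(ax)] - ax[1]) * (ax - ax[1])
  expect_equal(corr, y - line)
  expect_equal(corr[c(1, length(corr))], c(0, 0))
  expect_true(all(corr >= -max(bandv[c(1, length(bandv))]) - 1e-12))
})

test_that("min-max normalization maps to [0,1] with both bounds attained", {
  expect_equal(minmax_normalize(c(1, 2, 3)), c(0, 0.5, 1))
  expect_equal(minmax_normalize(c(0, 1)), c(0, 1))
  expect_equal(minmax_normalize(c(-2, 0, 6)), c(0, 0.25, 1))
  set.seed(4)
  v <- minmax_normalize(rnorm(50))
  expect_equal(range(v), c(0, 1))
  expect_error(minmax_normalize(rep(2, 10)), "degenerate")
})

test_that("mean_center zeroes column means and returns them", {
  mc <- mean_center(matrix(c(1, 3, 2, 4), 2, 2))
  expect_equal(mc$centered, matrix(c(-1, 1, -1, 1), 2, 2))
  expect_equal(mc$means, c(2, 3))
  set.seed(5)
  x <- matrix(rnorm(50), 10, 5)
  cc <- mean_center(x)
  expect_true(all(abs(colSums(cc$centered)) < 1e-10))
  # idempotence
  expect_equal(mean_center(cc$centered)$centered, cc$centered)
  expect_error(mean_center(matrix(1, 1, 3)), "2 rows")
})

test_that("the preprocessing chain honours its configuration", {
  ds <- generate_dataset(uv_default_config(seed = 3))$dataset
  idcfg <- preprocess_config(sg_window = 0L, baseline_mode = "none",
                             normalize = "none", center = "none")
  expect_equal(preprocess_dataset(ds, idcfg)$dataset$intensities,
               ds$intensities)
  # paper-default chain: the pre-centering intermediate is min 0 / max 1
  pre <- preprocess_dataset(ds, preprocess_config(center = "none"))$dataset
  expect_equal(unname(apply(pre$intensities, 1, min)),
               rep(0, nrow(pre$intensities)))
  expect_equal(unname(apply(pre$intensities, 1, max)),
               rep(1, nrow(pre$intensities)))
  expect_identical(pre$metadata$preprocess$normalize, "minmax01")
})

test_that("centering is train-fitted, not refit on held-out data", {
  ds <- generate_dataset(uv_default_config(seed = 3))$dataset
  cfg <- preprocess_config()
  tr <- preprocess_dataset(subset_rows(ds, 1:60), cfg)
  te <- preprocess_dataset(subset_rows(ds, 61:99), cfg,
                           fitted_means = tr$fitted_means)
  expect_equal(te$fitted_means, tr$fitted_means)
  # train columns are zero-mean, test columns generally are not
  expect_true(max(abs(colMeans(tr$dataset$intensities))) < 1e-10)
  expect_gt(max(abs(colMeans(te$dataset$intensities))), 1e-6)
  expect_error(
    preprocess_dataset(ds, cfg, fitted_means = 1:3), "length")
})

test_that("the chain is row-permutation equivariant and axis-direction agnostic", {
  ds <- generate_dataset(uv_default_config(seed = 8, n_class_a = 3L,
                                           n_class_b = 3L,
                                           replicates = 1L))$dataset
  cfg <- preprocess_config(center = "none")
  out <- preprocess_dataset(ds, cfg)$dataset$intensities
  perm <- c(4, 2, 6, 1, 3, 5)
  out_p <- preprocess_dataset(subset_rows(ds, perm), cfg)$dataset$intensities
  expect_equal(out_p, out[perm, ])
  # reversing axis and columns reverses the output
  rev_ds <- ds
  rev_ds$axis <- rev(ds$axis)
  rev_ds$intensities <- ds$intensities[, ncol(ds$intensities):1]
  out_r <- preprocess_dataset(rev_ds, cfg)$dataset$intensities
  expect_equal(out_r, out[, ncol(out):1], tolerance = 1e-10)
})
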