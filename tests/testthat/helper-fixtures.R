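# shared fixtures: small synthetic datasets and a supervised-partition
# helper mirroring the pipeline's split/centering logic

tiny_dataset <- function() {
  spectral_dataset(
    matrix(c(1, 2, 3, 4, 5,
             3, 4, 5, 6, 7,
             2, 2, 2, 4, 4,
             4, 4, 4, 6, 6), 4, 5, byrow = TRUE),
    axis = c(240, 250, 260, 270, 280),
    sample_ids = c("LU01", "LU01", "MI01", "MI01"),
    replicate_ids = c(1L, 2L, 1L, 2L),
    classes = c("LU", "LU", "MI", "MI")
  )
}

# replicate-averaged, per-spectrum-preprocessed (no centering) UV dataset
uv_samples <- function(seed = 7, normalize = "minmax01", ...) {
  gen <- generate_dataset(uv_default_config(seed = seed, ...))
  avg <- average_replicates(gen$dataset)
  pre <- preprocess_dataset(
    avg, preprocess_config(normalize = normalize, center = "none"))$dataset
  list(samples = pre, ground_truth = gen$ground_truth)
}

# KS split with train-fitted centering, as the supervised stages use it
supervised_partition <- function(samples, train_fraction = 2 / 3) {
  sp <- stratified_split(samples, train_fraction)
  train <- subset_rows(samples, sp$train_indices)
  test <- subset_rows(samples, sp$test_indices)
  mc <- mean_center(train$intensities)
  train$intensities <- mc$centered
  test$intensities <- sweep(test$intensities, 2L, mc$means)
  list(train = train, test = test, split = sp)
}

# Mahalanobis closest-class oracle with pooled covariance, equal priors
mahalanobis_oracle <- function(xtr, ytr, xte, positive) {
  labs <- sort(unique(ytr))
  neg <- setdiff(labs, positive)
  mp <- colMeans(xtr[ytr == positive, , drop = FALSE])
  mn <- colMeans(xtr[ytr == neg, , drop = FALSE])
  sc <- function(m) crossprod(sweep(m, 2, colMeans(m)))
  S <- (sc(xtr[ytr == positive, , drop = FALSE]) +
          sc(xtr[ytr == neg, , drop = FALSE])) / (nrow(xtr) - 2)
  dp <- stats::mahalanobis(xte, mp, S)
  dn <- stats::mahalanobis(xte, mn, S)
  ifelse(dp < dn, positive, neg)
}

# a matrix where column `sep_col` alone separates the two classes exactly
perfectly_separable <- function(n_a = 6, n_b = 6, p = 4, sep_col = 2,
                                seed = 3) {
  set.seed(seed)
  x <- matrix(rnorm(p * (n_a + n_b), sd = 0.3), n_a + n_b, p)
  x[, sep_col] <- c(rnorm(n_a, -2, 0.1), rnorm(n_b, 2, 0.1))
  list(x = x, classes = rep(c("A", "B"), c(n_a, n_b)), sep_col = sep_col)
}
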