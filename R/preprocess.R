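#' Preprocessing chain configuration
#'
#' The default chain is Savitzky-Golay smoothing (window 13, order 2),
#' linear-endpoint baseline correction, per-spectrum min-max normalization
#' to [0, 1], then mean-centering fitted on the data it is applied to.
#'
#' @param sg_window odd Savitzky-Golay window length (points); 0 disables
#'   smoothing.
#' @param sg_polyorder polynomial order of the smoothing fit (< sg_window).
#' @param baseline_mode `"linear_endpoints"` (subtract the straight line
#'   through the first and last point), `"offset"` (subtract the minimum) or
#'   `"none"`.
#' @param normalize `"minmax01"` or `"none"`.
#' @param center `"global_mean"` or `"none"`.
#' @return a `preprocess_config` object.
#' @export
preprocess_config <- function(sg_window = 13L, sg_polyorder = 2L,
                              baseline_mode = c("linear_endpoints", "offset",
                                                "none"),
                              normalize = c("minmax01", "none"),
                              center = c("global_mean", "none")) {
  baseline_mode <- match.arg(baseline_mode)
  normalize <- match.arg(normalize)
  center <- match.arg(center)
  sg_window <- as.integer(sg_window)
  if (sg_window > 0L) {
    if (sg_window %% 2L == 0L) stop("sg_window must be odd", call. = FALSE)
    if (sg_window <= sg_polyorder) {
      stop("sg_window must exceed sg_polyorder", call. = FALSE)
    }
  }
  structure(list(sg_window = sg_window,
                 sg_polyorder = as.integer(sg_polyorder),
                 baseline_mode = baseline_mode, normalize = normalize,
                 center = center),
            class = "preprocess_config")
}

#' Savitzky-Golay smoothing
#'
#' Least-squares polynomial smoothing: each point is replaced by the value
#' at that point of the polynomial of order `polyorder` fitted over the
#' centered `window`. Edge points use the polynomial fitted on the first or
#' last full window, evaluated at the edge positions, so the output keeps
#' the input length.
#'
#' @param spectrum numeric vector, length >= `window`.
#' @param window odd window length in points.
#' @param polyorder polynomial order, < `window`.
#' @return smoothed vector of the same length.
#' @export
savgol_smooth <- function(spectrum, window = 13L, polyorder = 2L) {
  window <- as.integer(window)
  if (window %% 2L == 0L || window <= polyorder) {
    stop("window must be odd and greater than polyorder", call. = FALSE)
  }
  if (length(spectrum) < window) {
    stop(sprintf("spectrum too short for smoothing: %d points < window %d",
                 length(spectrum), window), call. = FALSE)
  }
  as.numeric(signal::sgolayfilt(spectrum, p = polyorder, n = window))
}

#' Baseline correction
#'
#' @param spectrum numeric vector.
#' @param axis axis values (same length; used by `linear_endpoints`).
#' @param mode `"offset"` subtracts the spectrum minimum;
#'   `"linear_endpoints"` subtracts the straight line through the two
#'   endpoints; `"none"` is the identity.
#' @return corrected vector.
#' @export
baseline_correct <- function(spectrum, axis = seq_along(spectrum),
                             mode = c("linear_endpoints", "offset", "none")) {
  mode <- match.arg(mode)
  stopifnot(length(spectrum) == length(axis))
  switch(mode,
    none = spectrum,
    offset = spectrum - min(spectrum),
    linear_endpoints = {
      n <- length(spectrum)
      slope <- (spectrum[n] - spectrum[1]) / (axis[n] - axis[1])
      spectrum - (spectrum[1] + slope * (axis - axis[1]))
    }
  )
}

#' Min-max normalization to [0, 1]
#'
#' `(x - min) / (max - min)` over the full spectral range of one spectrum.
#'
#' @param spectrum numeric vector with at least two distinct values.
#' @return normalized vector with min 0 and max 1.
#' @export
minmax_normalize <- function(spectrum) {
  r <- range(spectrum)
  if (r[1] == r[2]) {
    stop("degenerate constant spectrum: min-max normalization undefined",
         call. = FALSE)
  }
  (spectrum - r[1]) / (r[2] - r[1])
}

#' Column mean-centering
#'
#' @param x numeric matrix, `n >= 2` rows.
#' @return list with `centered` (each column mean 0) and `means` (the
#'   column means, for applying to held-out data).
#' @export
mean_center <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("mean-centering needs at least 2 rows",
                         call. = FALSE)
  m <- colMeans(x)
  list(centered = sweep(x, 2L, m), means = m)
}

#' Apply the preprocessing chain to a dataset
#'
#' Smoothing, baseline correction and normalization are applied per
#' spectrum, in that order; centering is applied last across the data set.
#' When `fitted_means` is supplied (test-set application) those means are
#' subtracted instead of refitting, so centering is train-fitted and never
#' leaks held-out information.
#'
#' @param ds a [spectral_dataset].
#' @param cfg a [preprocess_config].
#' @param fitted_means optional length-p vector of column means from a
#'   training application.
#' @return list with `dataset` (preprocessed, chain recorded in
#'   `metadata$preprocess`) and `fitted_means` (the means used; `NULL` when
#'   centering is disabled).
#' @export
preprocess_dataset <- function(ds, cfg = preprocess_config(),
                               fitted_means = NULL) {
  validate_dataset(ds)
  stopifnot(inherits(cfg, "preprocess_config"))
  x <- ds$intensities
  if (cfg$sg_window > 0L) {
    x <- t(apply(x, 1L, savgol_smooth, window = cfg$sg_window,
                 polyorder = cfg$sg_polyorder))
  }
  if (cfg$baseline_mode != "none") {
    x <- t(apply(x, 1L, baseline_correct, axis = ds$axis,
                 mode = cfg$baseline_mode))
  }
  if (cfg$normalize == "minmax01") {
    x <- t(apply(x, 1L, minmax_normalize))
  }
  means <- NULL
  if (cfg$center == "global_mean") {
    if (!is.null(fitted_means)) {
      stopifnot(length(fitted_means) == ncol(x))
      means <- fitted_means
      x <- sweep(x, 2L, means)
    } else {
      mc <- mean_center(x)
      x <- mc$centered
      means <- mc$means
    }
  }
  out <- spectral_dataset(x, ds$axis, ds$sample_ids, ds$replicate_ids,
                          ds$classes, ds$modality,
                          metadata = c(ds$metadata,
                                       list(preprocess = unclass(cfg))))
  list(dataset = out, fitted_means = means)
}
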