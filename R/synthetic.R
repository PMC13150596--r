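#' Gaussian absorption band
#'
#' @param center band center, in axis units (nm or cm-1).
#' @param width Gaussian sigma, axis units, > 0.
#' @param amplitude peak absorbance, >= 0.
#' @return a `band` object.
#' @export
band <- function(center, width, amplitude) {
  if (!is.finite(width) || width <= 0) stop("band width must be > 0",
                                            call. = FALSE)
  if (!is.finite(amplitude) || amplitude < 0) {
    stop("band amplitude must be >= 0", call. = FALSE)
  }
  structure(list(center = center, width = width, amplitude = amplitude),
            class = "band")
}

#' Evaluate a Gaussian band profile on an axis
#'
#' Returns `amplitude * exp(-(x - center)^2 / (2 * width^2))` at every axis
#' point.
#'
#' @param axis strictly monotone numeric grid.
#' @param b a [band].
#' @return numeric vector, same length as `axis`.
#' @export
band_profile <- function(axis, b) {
  check_monotone_axis(axis)
  stopifnot(inherits(b, "band"))
  b$amplitude * exp(-(axis - b$center)^2 / (2 * b$width^2))
}

#' Synthetic two-class spectra configuration
#'
#' Describes a two-class band-mixture generator: both classes share
#' `shared_bands`; each class additionally carries its exclusive marker
#' bands. Per sample, a multiplicative scatter factor is drawn
#' (N(1, scatter_sd), preparation/concentration variation); per replicate,
#' a linear baseline drift (offset ~ U(0, drift), end-to-end tilt
#' ~ U(-drift, drift)) and i.i.d. Gaussian noise are added.
#'
#' Defaults mirror the study design this generator emulates: 15 class-A
#' vs 18 class-B samples, UV-vis in triplicate on 240-400 nm (1 nm step).
#'
#' @param axis_start,axis_stop,axis_step axis grid; `axis_start > axis_stop`
#'   yields a descending axis (FTIR instrument export convention).
#' @param n_class_a,n_class_b sample counts per class (>= 2).
#' @param replicates replicate spectra per sample (>= 1).
#' @param shared_bands list of [band] present in both classes.
#' @param marker_bands_a,marker_bands_b class-exclusive [band] lists; marker
#'   centers of the two classes must be at least `3 * axis_step` apart.
#' @param baseline_drift_max maximum baseline offset/tilt (absorbance).
#' @param scatter_sd sd of the per-sample multiplicative scatter factor.
#' @param noise_sd sd of the per-point additive Gaussian noise (absorbance).
#' @param modality `"uv"` or `"ftir"` tag for the output dataset.
#' @param class_labels length-2 character vector of class labels.
#' @param seed integer RNG seed; same config (incl. seed) gives bit-identical
#'   output.
#' @return a `synthetic_config` object.
#' @export
synthetic_config <- function(axis_start = 240, axis_stop = 400, axis_step = 1,
                             n_class_a = 15L, n_class_b = 18L,
                             replicates = 3L,
                             shared_bands = list(),
                             marker_bands_a = list(),
                             marker_bands_b = list(),
                             baseline_drift_max = 0.05,
                             scatter_sd = 0.05,
                             noise_sd = 0.005,
                             modality = "uv",
                             class_labels = c("LU", "MI"),
                             seed = 1L) {
  if (axis_step <= 0) stop("axis_step must be > 0", call. = FALSE)
  if (n_class_a < 2L || n_class_b < 2L) {
    stop("need at least 2 samples per class", call. = FALSE)
  }
  if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  axis <- if (axis_start <= axis_stop) {
    seq(axis_start, axis_stop, by = axis_step)
  } else {
    seq(axis_start, axis_stop, by = -axis_step)
  }
  rng <- range(axis)
  for (b in c(shared_bands, marker_bands_a, marker_bands_b)) {
    stopifnot(inherits(b, "band"))
    if (b$center < rng[1] || b$center > rng[2]) {
      stop(sprintf("band center %g lies outside the axis range [%g, %g]",
                   b$center, rng[1], rng[2]), call. = FALSE)
    }
  }
  ca <- vapply(marker_bands_a, `[[`, numeric(1), "center")
  cb <- vapply(marker_bands_b, `[[`, numeric(1), "center")
  if (length(ca) && length(cb) &&
      min(abs(outer(ca, cb, "-"))) < 3 * axis_step) {
    stop("class marker centers must be >= 3 axis steps apart", call. = FALSE)
  }
  structure(list(
    axis = axis, axis_step = axis_step,
    n_class_a = as.integer(n_class_a), n_class_b = as.integer(n_class_b),
    replicates = as.integer(replicates),
    shared_bands = shared_bands,
    marker_bands_a = marker_bands_a, marker_bands_b = marker_bands_b,
    baseline_drift_max = baseline_drift_max,
    scatter_sd = scatter_sd, noise_sd = noise_sd,
    modality = modality, class_labels = as.character(class_labels),
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Default UV-vis-like generator configuration
#'
#' 15 "LU" vs 18 "MI" samples in triplicate on 240-400 nm (1 nm step).
#' Shared bands give the smooth overlapping phenolic profile; class markers
#' sit at 259 nm (class A, isoflavone Band II region) and 284 / 356 nm
#' (class B, phenolic B-ring and flavonol Band I regions), amplitudes 20x
#' the additive noise sd.
#'
#' @param seed integer RNG seed.
#' @param ... overrides passed on to [synthetic_config()].
#' @return a `synthetic_config`.
#' @export
uv_default_config <- function(seed = 1L, ...) {
  args <- list(
    axis_start = 240, axis_stop = 400, axis_step = 1,
    n_class_a = 15L, n_class_b = 18L, replicates = 3L,
    shared_bands = list(
      band(250, 15, 0.80),
      band(275, 12, 0.55),
      band(330, 22, 0.35)
    ),
    marker_bands_a = list(band(259, 4, 0.10)),
    marker_bands_b = list(band(284, 4, 0.10), band(356, 5, 0.10)),
    baseline_drift_max = 0.05, scatter_sd = 0.05, noise_sd = 0.005,
    modality = "uv", class_labels = c("LU", "MI"), seed = seed
  )
  args[names(list(...))] <- list(...)
  do.call(synthetic_config, args)
}

#' Default FTIR-like generator configuration
#'
#' 15 "LU" vs 18 "MI" samples in duplicate on a descending 1800-600 cm-1
#' grid (2 cm-1 step). Class markers sit at 1658 cm-1 (class A, amide-I /
#' quinolizidine C=O region) and 1561 / 1103 cm-1 (class B, aromatic ring
#' and C-O stretch regions).
#'
#' @param seed integer RNG seed.
#' @param ... overrides passed on to [synthetic_config()].
#' @return a `synthetic_config`.
#' @export
ftir_default_config <- function(seed = 1L, ...) {
  args <- list(
    axis_start = 1800, axis_stop = 600, axis_step = 2,
    n_class_a = 15L, n_class_b = 18L, replicates = 2L,
    shared_bands = list(
      band(1640, 30, 0.70),
      band(1520, 25, 0.45),
      band(1440, 20, 0.40),
      band(1240, 30, 0.35),
      band(1050, 40, 0.60),
      band(830, 25, 0.25)
    ),
    marker_bands_a = list(band(1658, 8, 0.10)),
    marker_bands_b = list(band(1561, 8, 0.10), band(1103, 8, 0.10)),
    baseline_drift_max = 0.05, scatter_sd = 0.05, noise_sd = 0.005,
    modality = "ftir", class_labels = c("LU", "MI"), seed = seed
  )
  args[names(list(...))] <- list(...)
  do.call(synthetic_config, args)
}

#' Generate a synthetic two-class spectral dataset
#'
#' Each replicate spectrum is
#' `(shared bands + class markers) * (1 + sample scatter) + baseline + noise`
#' with the scatter factor drawn once per sample and baseline/noise per
#' replicate (see [synthetic_config()]). Deterministic given the config's
#' seed.
#'
#' @param cfg a [synthetic_config].
#' @return list with elements `dataset` (a [spectral_dataset]; sample ids
#'   `<label>01..`, classes from `cfg$class_labels`) and `ground_truth`
#'   (list of `marker_indices_a` / `marker_indices_b`: column indices of the
#'   planted marker centers, nearest grid point).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  axis <- cfg$axis
  p <- length(axis)
  sum_bands <- function(bands) {
    v <- numeric(p)
    for (b in bands) v <- v + band_profile(axis, b)
    v
  }
  base_a <- sum_bands(cfg$shared_bands) + sum_bands(cfg$marker_bands_a)
  base_b <- sum_bands(cfg$shared_bands) + sum_bands(cfg$marker_bands_b)

  n_samples <- cfg$n_class_a + cfg$n_class_b
  n_rows <- n_samples * cfg$replicates
  classes_s <- rep(cfg$class_labels, c(cfg$n_class_a, cfg$n_class_b))
  sample_ids_s <- c(sprintf("%s%02d", cfg$class_labels[1],
                            seq_len(cfg$n_class_a)),
                    sprintf("%s%02d", cfg$class_labels[2],
                            seq_len(cfg$n_class_b)))

  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)

  t01 <- if (p > 1) (seq_len(p) - 1) / (p - 1) else 0  # axis position 0..1
  X <- matrix(0, n_rows, p)
  sample_ids <- character(n_rows)
  replicate_ids <- integer(n_rows)
  classes <- character(n_rows)
  row <- 0L
  for (s in seq_len(n_samples)) {
    pure <- if (classes_s[s] == cfg$class_labels[1]) base_a else base_b
    scatter <- if (cfg$scatter_sd > 0) rnorm(1, 0, cfg$scatter_sd) else 0
    for (r in seq_len(cfg$replicates)) {
      row <- row + 1L
      offs <- if (cfg$baseline_drift_max > 0) {
        runif(1, 0, cfg$baseline_drift_max)
      } else 0
      tilt <- if (cfg$baseline_drift_max > 0) {
        runif(1, -cfg$baseline_drift_max, cfg$baseline_drift_max)
      } else 0
      noise <- if (cfg$noise_sd > 0) rnorm(p, 0, cfg$noise_sd) else 0
      X[row, ] <- pure * (1 + scatter) + offs + tilt * t01 + noise
      sample_ids[row] <- sample_ids_s[s]
      replicate_ids[row] <- r
      classes[row] <- classes_s[s]
    }
  }

  nearest <- function(bands) {
    sort(unique(vapply(bands, function(b) {
      which.min(abs(axis - b$center))
    }, integer(1))))
  }
  list(
    dataset = spectral_dataset(X, axis, sample_ids, replicate_ids, classes,
                               cfg$modality,
                               metadata = list(generator_seed = cfg$seed)),
    ground_truth = list(marker_indices_a = nearest(cfg$marker_bands_a),
                        marker_indices_b = nearest(cfg$marker_bands_b))
  )
}
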