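#' Labelled spectral dataset
#'
#' The container every stage of the pipeline operates on: a numeric matrix of
#' absorbance spectra on a common, strictly monotone axis (wavelength in nm
#' for UV-vis, wavenumber in cm-1 for FTIR; either direction), with per-row
#' sample, replicate and class labels.
#'
#' @param intensities numeric matrix, rows = spectra, columns = axis points.
#' @param axis numeric vector, strictly monotone (ascending or descending),
#'   length equal to `ncol(intensities)`.
#' @param sample_ids character vector of per-row sample identifiers
#'   (e.g. "LU03"); replicates of one sample share the identifier.
#' @param replicate_ids integer vector of per-row replicate numbers.
#' @param classes character vector of per-row class labels; supervised
#'   stages require exactly two distinct labels.
#' @param modality one of `"uv"`, `"ftir"` (axis unit tag).
#' @param metadata list of free-form metadata (e.g. preprocessing history).
#'
#' @return An object of class `spectral_dataset`.
#' @export
spectral_dataset <- function(intensities, axis, sample_ids, replicate_ids,
                             classes, modality = c("uv", "ftir"),
                             metadata = list()) {
  modality <- match.arg(modality)
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  axis <- as.numeric(axis)
  ds <- structure(
    list(
      axis = axis,
      intensities = intensities,
      sample_ids = as.character(sample_ids),
      replicate_ids = as.integer(replicate_ids),
      classes = as.character(classes),
      modality = modality,
      metadata = metadata
    ),
    class = "spectral_dataset"
  )
  validate_dataset(ds)
  ds
}

#' Validate a spectral dataset
#'
#' Checks the structural invariants: matching row-label lengths, a strictly
#' monotone axis, no missing values.
#'
#' @param ds a `spectral_dataset`.
#' @param require_two_classes if `TRUE`, additionally require exactly two
#'   distinct class labels (the precondition of every supervised stage).
#' @return `ds`, invisibly.
#' @export
validate_dataset <- function(ds, require_two_classes = FALSE) {
  stopifnot(inherits(ds, "spectral_dataset"))
  n <- nrow(ds$intensities)  # 0 rows allowed: write_dataset emits header only
  if (length(ds$axis) != ncol(ds$intensities)) {
    stop("axis length does not match intensity columns", call. = FALSE)
  }
  if (length(ds$sample_ids) != n || length(ds$replicate_ids) != n ||
      length(ds$classes) != n) {
    stop("row label vectors must match the number of spectra", call. = FALSE)
  }
  check_monotone_axis(ds$axis)
  if (anyNA(ds$intensities) || anyNA(ds$axis)) {
    stop("dataset contains missing values", call. = FALSE)
  }
  ncl <- length(unique(ds$classes))
  if (require_two_classes && ncl != 2L) {
    stop(sprintf("supervised stages require exactly 2 class labels, found %d",
                 ncl), call. = FALSE)
  }
  invisible(ds)
}

check_monotone_axis <- function(axis) {
  if (length(axis) < 2L) stop("axis needs at least 2 points", call. = FALSE)
  d <- diff(axis)
  if (!(all(d > 0) || all(d < 0))) {
    stop("axis must be strictly monotone (ascending or descending)",
         call. = FALSE)
  }
  invisible(axis)
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf(
    "<spectral_dataset> %s | %d spectra x %d points | axis %g..%g | classes: %s\n",
    x$modality, nrow(x$intensities), ncol(x$intensities),
    x$axis[1], x$axis[length(x$axis)],
    paste(sprintf("%s(%d)", names(table(x$classes)), table(x$classes)),
          collapse = ", ")
  ))
  invisible(x)
}

#' @export
dim.spectral_dataset <- function(x) dim(x$intensities)

#' Subset the variables (columns) of a dataset
#'
#' @param ds a `spectral_dataset`.
#' @param cols integer column indices to keep (order preserved as given).
#' @return a `spectral_dataset` on the subsetted axis.
#' @export
subset_variables <- function(ds, cols) {
  validate_dataset(ds)
  stopifnot(all(cols >= 1L), all(cols <= ncol(ds$intensities)))
  spectral_dataset(ds$intensities[, cols, drop = FALSE], ds$axis[cols],
                   ds$sample_ids, ds$replicate_ids, ds$classes,
                   ds$modality, ds$metadata)
}

#' Subset the rows of a dataset
#'
#' @param ds a `spectral_dataset`.
#' @param rows integer row indices to keep.
#' @return a `spectral_dataset` with those rows.
#' @export
subset_rows <- function(ds, rows) {
  validate_dataset(ds)
  spectral_dataset(ds$intensities[rows, , drop = FALSE], ds$axis,
                   ds$sample_ids[rows], ds$replicate_ids[rows],
                   ds$classes[rows], ds$modality, ds$metadata)
}
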