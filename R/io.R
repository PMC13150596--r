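#' Read a labelled spectral matrix from CSV
#'
#' The CSV dialect is strict: comma separator, dot decimal, UTF-8. The first
#' row holds the numeric axis (after three empty label cells), each following
#' row is `sample_id,replicate_id,class,<values...>`. Axis direction is
#' preserved as stored (FTIR exports are typically descending).
#'
#' @param path path to the CSV file.
#' @param modality `"uv"` or `"ftir"`.
#' @return a validated [spectral_dataset].
#' @export
read_dataset <- function(path, modality = c("uv", "ftir")) {
  modality <- match.arg(modality)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L) stop("empty file: ", path, call. = FALSE)
  if (grepl(";", lines[1], fixed = TRUE)) {
    stop("semicolon-separated file: only the comma/dot CSV dialect is read",
         call. = FALSE)
  }
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (length(header) < 4L) stop("header row too short", call. = FALSE)
  axis_cells <- header[-(1:3)]
  axis <- suppressWarnings(as.numeric(axis_cells))
  if (anyNA(axis)) {
    bad <- which(is.na(axis))[1]
    stop(sprintf("non-numeric axis cell '%s' (header column %d)",
                 axis_cells[bad], bad + 3L), call. = FALSE)
  }
  if (length(lines) < 2L) stop("empty dataset: file has header only",
                               call. = FALSE)
  body <- strsplit(lines[-1], ",", fixed = TRUE)
  widths <- lengths(body)
  if (any(widths != length(header))) {
    bad <- which(widths != length(header))[1]
    stop(sprintf("ragged row %d: %d cells, expected %d",
                 bad + 1L, widths[bad], length(header)), call. = FALSE)
  }
  cells <- do.call(rbind, body)
  vals <- suppressWarnings(
    matrix(as.numeric(cells[, -(1:3), drop = FALSE]), nrow = nrow(cells))
  )
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric intensity cell at row %d, column %d",
                 bad[1] + 1L, bad[2] + 3L), call. = FALSE)
  }
  spectral_dataset(vals, axis,
                   sample_ids = cells[, 1],
                   replicate_ids = as.integer(cells[, 2]),
                   classes = cells[, 3],
                   modality = modality)
}

#' Write a spectral dataset to CSV
#'
#' Inverse of [read_dataset()]: first row is the axis, first three columns
#' are `sample_id`, `replicate_id`, `class`; numeric cells at full double
#' precision so that write-then-read round-trips.
#'
#' @param ds a [spectral_dataset].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  validate_dataset(ds)
  num <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
  header <- paste(c("sample_id", "replicate_id", "class", num(ds$axis)),
                  collapse = ",")
  rows <- vapply(seq_len(nrow(ds$intensities)), function(i) {
    paste(c(ds$sample_ids[i], ds$replicate_ids[i], ds$classes[i],
            num(ds$intensities[i, ])), collapse = ",")
  }, character(1))
  con <- try(file(path, "w", encoding = "UTF-8"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot write: ", path, call. = FALSE)
  on.exit(close(con))
  writeLines(c(header, rows), con)
  invisible(path)
}

#' Average replicate spectra per sample
#'
#' Collapses each sample's replicates to their arithmetic mean spectrum
#' (multivariate figures in this workflow present per-sample averages).
#' Output rows follow the first-appearance order of sample ids and carry
#' `replicate_id = 0`.
#'
#' @param ds a [spectral_dataset].
#' @return a [spectral_dataset] with one row per sample id.
#' @export
average_replicates <- function(ds) {
  validate_dataset(ds)
  ids <- unique(ds$sample_ids)
  cls <- character(length(ids))
  out <- matrix(0, length(ids), ncol(ds$intensities))
  for (k in seq_along(ids)) {
    rows <- which(ds$sample_ids == ids[k])
    ck <- unique(ds$classes[rows])
    if (length(ck) != 1L) {
      stop(sprintf("sample '%s' carries conflicting class labels: %s",
                   ids[k], paste(ck, collapse = ", ")), call. = FALSE)
    }
    cls[k] <- ck
    out[k, ] <- colMeans(ds$intensities[rows, , drop = FALSE])
  }
  spectral_dataset(out, ds$axis, ids, rep(0L, length(ids)), cls,
                   ds$modality, ds$metadata)
}
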