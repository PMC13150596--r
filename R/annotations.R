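#' Static spectral band annotation table
#'
#' Literature-style tentative assignments for the discriminant regions this
#' workflow targets: isoflavone/flavonol UV absorption bands and the
#' amide-I / C-O FTIR stretches characteristic of quinolizidine-alkaloid
#' vs flavonoid-rich extracts. A fixed lookup, never inferred from data.
#'
#' @return data.frame with `modality`, `position` (nm or cm-1),
#'   `selected_variable` (printed label), `assignment`, `relevance`.
#' @export
band_annotations <- function() {
  data.frame(
    modality = c("uv", "uv", "uv", "ftir", "ftir"),
    position = c(259, 284, 358.5, 1658, 1105),
    selected_variable = c("~259 nm", "284 nm", "356-361 nm",
                          "1658 cm-1", "1103-1107 cm-1"),
    assignment = c(
      "Band II (Ring A) absorption of isoflavones",
      "Band II absorption/phenolic B-ring",
      "Band I (Ring B) absorption of flavonols",
      "C=O stretching (Amide I)",
      "C-O stretching vibrations"
    ),
    relevance = c(
      "genistein and derivatives in Lupinus",
      "variation in hydroxyl/methoxyl substitutions",
      "flavones and flavonols (e.g. quercetin) in Mimosa",
      "carbonyl groups in quinolizidine alkaloids",
      "flavonoid glycosides and phenolic backbones"
    ),
    stringsAsFactors = FALSE
  )
}

#' Annotate selected axis positions
#'
#' Joins each selected wavelength/wavenumber to the nearest entry of
#' [band_annotations()] within tolerance (+-3 nm for UV, +-6 cm-1 for
#' FTIR); positions with no entry in range are reported as "unannotated".
#'
#' @param axis_values numeric vector of selected positions.
#' @param modality `"uv"` or `"ftir"`.
#' @return data.frame with `axis_value`, `assignment`, `relevance`.
#' @export
annotate_variables <- function(axis_values, modality = c("uv", "ftir")) {
  modality <- match.arg(modality)
  tol <- if (modality == "uv") 3 else 6
  ann <- band_annotations()
  ann <- ann[ann$modality == modality, , drop = FALSE]
  # the 356-361 nm and 1103-1107 cm-1 entries are ranges; widen by half-span
  halfspan <- ifelse(ann$position %in% c(358.5, 1105), 2.5, 0)
  out <- lapply(axis_values, function(v) {
    d <- pmax(abs(v - ann$position) - halfspan, 0)
    i <- which.min(d)
    if (length(i) && d[i] <= tol) {
      data.frame(axis_value = v, assignment = ann$assignment[i],
                 relevance = ann$relevance[i], stringsAsFactors = FALSE)
    } else {
      data.frame(axis_value = v, assignment = "unannotated",
                 relevance = "", stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}
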