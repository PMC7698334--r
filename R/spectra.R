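VALID_LABELS <- c("IDHmut", "IDHwt", "unknown")

#' Assemble a cohort of spectra into the long tidy representation
#'
#' A cohort of frequency-domain spectra is stored as one long tibble of class
#' `mrs_spectra` with columns `sample_id`, `label`, `point` (1-based index,
#' point 1 = highest ppm), `ppm`, `real` and `imag` (`NA` when the imaginary
#' channel is absent). The shared [ppm_axis()] travels as an attribute.
#'
#' @param data A data frame with columns `sample_id`, `label`, `point`,
#'   `real` and optionally `imag`.
#' @param axis The shared [ppm_axis()].
#' @return An `mrs_spectra` tibble.
#' @export
mrs_spectra <- function(data, axis) {
  stopifnot(inherits(axis, "ppm_axis"))
  data <- tibble::as_tibble(data)
  req <- c("sample_id", "label", "point", "real")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols)) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!"imag" %in% names(data)) data$imag <- NA_real_
  check_labels(data$label)
  counts <- table(data$sample_id)
  if (any(counts != axis$n_points)) {
    bad <- names(counts)[counts != axis$n_points][1]
    abort(sprintf(
      "sample '%s' has %d points but the axis expects %d.",
      bad, counts[[bad]], axis$n_points
    ), class = "gliomrs_format_error")
  }
  data <- dplyr::arrange(data, .data$sample_id, .data$point)
  data$ppm <- ppm_values(axis, data$point)
  data <- data[, c("sample_id", "label", "point", "ppm", "real", "imag")]
  new_mrs_spectra(data, axis)
}

new_mrs_spectra <- function(data, axis) {
  structure(
    tibble::as_tibble(data),
    axis = axis,
    class = c("mrs_spectra", class(tibble::tibble()))
  )
}

#' @export
print.mrs_spectra <- function(x, ...) {
  ax <- spectra_axis(x)
  cat(sprintf("<mrs_spectra> %d spectra on a %d-point axis\n",
              dplyr::n_distinct(x$sample_id), ax$n_points))
  NextMethod()
}

#' Retrieve the ppm axis attached to a spectra or feature object
#' @param x An `mrs_spectra` or `mrs_features` object.
#' @return The [ppm_axis()].
#' @export
spectra_axis <- function(x) attr(x, "axis")

check_labels <- function(label) {
  bad <- setdiff(unique(label), VALID_LABELS)
  if (length(bad)) {
    abort(sprintf(
      "invalid label(s): %s (must be one of %s).",
      paste(bad, collapse = ", "), paste(VALID_LABELS, collapse = ", ")
    ), class = "gliomrs_label_error")
  }
  invisible(label)
}

# one list element per sample: list(sample_id, label, real, imag)
spectra_split <- function(spectra) {
  split(spectra, spectra$sample_id)[unique(spectra$sample_id)]
}

spectra_from_vectors <- function(sample_id, label, real, imag, axis) {
  tibble::tibble(
    sample_id = sample_id, label = label,
    point = seq_along(real), real = real,
    imag = if (is.null(imag)) NA_real_ else imag
  )
}
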