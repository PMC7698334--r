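#' Write one spectrum to a plain-text file
#'
#' The on-disk format mirrors a jMRUI-style text export: `#`-prefixed header
#' lines (`key: value` pairs for `n_points`, `sweep_width_hz`,
#' `spectrometer_freq_mhz`, `carrier_ppm`, `sample_id`, `label`) followed by
#' one intensity per line in point order (point 1 = highest ppm), or two
#' whitespace-separated columns (real, imaginary) when the imaginary channel
#' is present. Values round-trip exactly through [read_spectrum_txt()].
#'
#' @param spectra An `mrs_spectra` tibble containing exactly one sample.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum_txt <- function(spectra, path) {
  stopifnot(inherits(spectra, "mrs_spectra"))
  if (dplyr::n_distinct(spectra$sample_id) != 1L) {
    abort("write_spectrum_txt() writes one spectrum per file; got a multi-sample cohort.")
  }
  if (!nzchar(path)) abort("`path` must be a non-empty file path.")
  ax <- spectra_axis(spectra)
  spectra <- dplyr::arrange(spectra, .data$point)
  header <- c(
    sprintf("# n_points: %d", ax$n_points),
    sprintf("# sweep_width_hz: %.17g", ax$sweep_width),
    sprintf("# spectrometer_freq_mhz: %.17g", ax$spectrometer_freq),
    sprintf("# carrier_ppm: %.17g", ax$carrier_ppm),
    sprintf("# sample_id: %s", spectra$sample_id[1]),
    sprintf("# label: %s", spectra$label[1])
  )
  has_imag <- !anyNA(spectra$imag)
  body <- if (has_imag) {
    sprintf("%.17g %.17g", spectra$real, spectra$imag)
  } else {
    sprintf("%.17g", spectra$real)
  }
  con <- tryCatch(file(path, "w"), error = function(e) {
    abort(sprintf("cannot open '%s' for writing: %s", path, conditionMessage(e)))
  })
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Read one spectrum from a plain-text file
#'
#' @param path Path to a file written by [write_spectrum_txt()] (or any text
#'   export with the same layout).
#' @param axis Optional [ppm_axis()]; when `NULL` the axis is reconstructed
#'   from the header. When supplied, the file's point count must match.
#' @return An `mrs_spectra` tibble with one sample.
#' @export
read_spectrum_txt <- function(path, axis = NULL) {
  lines <- readLines(path)
  is_header <- startsWith(lines, "#")
  hdr <- parse_header(lines[is_header])
  body <- lines[!is_header & nzchar(trimws(lines))]

  if (is.null(axis)) {
    need <- c("n_points", "sweep_width_hz", "spectrometer_freq_mhz", "carrier_ppm")
    missing_keys <- setdiff(need, names(hdr))
    if (length(missing_keys)) {
      abort(sprintf("'%s': header lacks key(s): %s (pass `axis` explicitly).",
                    path, paste(missing_keys, collapse = ", ")),
            class = "gliomrs_format_error")
    }
    axis <- ppm_axis(as.numeric(hdr["n_points"]), as.numeric(hdr["sweep_width_hz"]),
                     as.numeric(hdr["spectrometer_freq_mhz"]), as.numeric(hdr["carrier_ppm"]))
  }
  if (length(body) != axis$n_points) {
    abort(sprintf("'%s': expected %d data points, found %d.",
                  path, axis$n_points, length(body)),
          class = "gliomrs_format_error")
  }
  line_no <- which(!is_header & nzchar(trimws(lines)))
  fields <- strsplit(trimws(body), "[[:space:]]+")
  n_cols <- lengths(fields)
  if (any(n_cols > 2L)) {
    abort(sprintf("'%s': line %d has %d columns (expected 1 or 2).",
                  path, line_no[which(n_cols > 2L)[1]], max(n_cols)),
          class = "gliomrs_format_error")
  }
  vals <- suppressWarnings(lapply(fields, as.numeric))
  bad <- which(vapply(vals, anyNA, logical(1)))
  if (length(bad)) {
    abort(sprintf("'%s': non-numeric value on line %d: '%s'.",
                  path, line_no[bad[1]], body[bad[1]]),
          class = "gliomrs_parse_error")
  }
  real <- vapply(vals, `[`, numeric(1), 1L)
  imag <- if (all(n_cols == 2L)) vapply(vals, `[`, numeric(1), 2L) else NA_real_
  sample_id <- if ("sample_id" %in% names(hdr)) hdr[["sample_id"]] else basename(path)
  label <- if ("label" %in% names(hdr)) hdr[["label"]] else "unknown"
  mrs_spectra(
    tibble::tibble(sample_id = sample_id, label = label,
                   point = seq_along(real), real = real, imag = imag),
    axis
  )
}

parse_header <- function(lines) {
  lines <- sub("^#[[:space:]]*", "", lines)
  keep <- grepl(":", lines, fixed = TRUE)
  kv <- strsplit(lines[keep], ":", fixed = TRUE)
  vals <- vapply(kv, function(x) trimws(paste(x[-1], collapse = ":")), character(1))
  names(vals) <- vapply(kv, function(x) trimws(x[1]), character(1))
  vals
}

#' Read a cohort of spectrum text files
#'
#' @param paths Character vector of file paths.
#' @param axis Optional shared [ppm_axis()] (see [read_spectrum_txt()]).
#' @return An `mrs_spectra` tibble with one sample per file.
#' @export
read_cohort_txt <- function(paths, axis = NULL) {
  specs <- lapply(paths, read_spectrum_txt, axis = axis)
  ax <- spectra_axis(specs[[1]])
  for (s in specs[-1]) {
    if (!axes_equal(spectra_axis(s), ax)) {
      abort("spectra do not share one ppm axis.", class = "gliomrs_axis_mismatch")
    }
  }
  ids <- vapply(specs, function(s) s$sample_id[1], character(1))
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicated sample_id: %s", ids[duplicated(ids)][1]))
  }
  new_mrs_spectra(dplyr::bind_rows(specs), ax)
}

#' Write / read a binned feature matrix as CSV
#'
#' One row per sample: `sample_id`, then one column per bin named
#' `"<upper>..<lower>"` with the bin's ppm interval, then `label`.
#' RFC-4180 CSV with '.' decimal separator.
#'
#' @param features An `mrs_features` tibble (see [bin_spectrum()]).
#' @param path File path.
#' @return `write_feature_matrix_csv()` returns `path` invisibly;
#'   `read_feature_matrix_csv()` returns an `mrs_features` tibble.
#' @export
write_feature_matrix_csv <- function(features, path) {
  stopifnot(inherits(features, "mrs_features"))
  wide <- features_wide(features)
  lbl <- wide$label
  wide$label <- NULL
  wide$label <- lbl # move label last
  readr::write_csv(wide, path)
  invisible(path)
}

#' @param stage Processing stage to stamp on the result (the CSV itself is
#'   stage-agnostic); one of `"binned"`, `"region_selected"`, `"normalized"`,
#'   `"log2"`.
#' @rdname write_feature_matrix_csv
#' @export
read_feature_matrix_csv <- function(path, stage = "log2") {
  wide <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("sample_id", "label") %in% names(wide))) {
    abort(sprintf("'%s': need 'sample_id' and 'label' columns.", path),
          class = "gliomrs_format_error")
  }
  if (anyDuplicated(wide$sample_id)) {
    abort(sprintf("'%s': duplicated sample_id '%s'.", path,
                  wide$sample_id[duplicated(wide$sample_id)][1]))
  }
  check_labels(wide$label)
  bin_cols <- setdiff(names(wide), c("sample_id", "label"))
  edges <- strsplit(bin_cols, "..", fixed = TRUE)
  if (any(lengths(edges) != 2L)) {
    abort(sprintf("'%s': bin column names must look like '<upper>..<lower>'.", path),
          class = "gliomrs_format_error")
  }
  upper <- as.numeric(vapply(edges, `[`, character(1), 1L))
  lower <- as.numeric(vapply(edges, `[`, character(1), 2L))
  long <- tidyr::pivot_longer(wide, dplyr::all_of(bin_cols),
                              names_to = "bin_name", values_to = "value")
  long$bin <- match(long$bin_name, bin_cols)
  long$ppm_upper <- upper[long$bin]
  long$ppm_lower <- lower[long$bin]
  long$ppm_mid <- (long$ppm_upper + long$ppm_lower) / 2
  long <- long[, c("sample_id", "label", "bin", "ppm_upper", "ppm_lower",
                   "ppm_mid", "value")]
  new_mrs_features(long, stage = stage, axis = NULL)
}

#' Pivot an `mrs_features` tibble to the wide sample-by-bin layout
#'
#' @param features An `mrs_features` tibble.
#' @return A tibble with `sample_id`, `label` and one column per bin.
#' @export
features_wide <- function(features) {
  f <- features
  f$bin_name <- sprintf("%.6g..%.6g", f$ppm_upper, f$ppm_lower)
  wide <- tidyr::pivot_wider(
    f[, c("sample_id", "label", "bin_name", "value")],
    names_from = "bin_name", values_from = "value"
  )
  wide[order(match(wide$sample_id, unique(features$sample_id))), ]
}
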