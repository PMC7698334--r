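FEATURE_STAGES <- c("binned", "region_selected", "normalized", "log2")

#' Preprocessing configuration
#'
#' @param reference_ppm Chemical shift the reference peak is aligned to;
#'   3.20 ppm, the choline trimethyl resonance.
#' @param reference_search_window Two-element ppm window searched for the
#'   reference maximum (default 3.00-3.40 ppm).
#' @param bin_size Number of consecutive points summed into one bin (default 4).
#' @param region Two-element ppm interval of bins kept for analysis (default
#'   0.7-4.5 ppm), excluding the residual water signal and empty regions.
#' @param log_floor Positive floor applied before the log2 transform.
#' @param phase_step_deg Grid step (degrees) of the zero-order phase search.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(reference_ppm = 3.20,
                              reference_search_window = c(3.00, 3.40),
                              bin_size = 4L, region = c(0.7, 4.5),
                              log_floor = 1e-6, phase_step_deg = 1) {
  region <- sort(as.numeric(region))
  window <- sort(as.numeric(reference_search_window))
  stopifnot(length(region) == 2L, region[1] < region[2],
            length(window) == 2L, bin_size >= 1L, log_floor > 0,
            phase_step_deg > 0)
  structure(list(
    reference_ppm = as.numeric(reference_ppm),
    reference_search_window = window,
    bin_size = as.integer(bin_size), region = region,
    log_floor = as.numeric(log_floor),
    phase_step_deg = as.numeric(phase_step_deg)
  ), class = "preprocess_config")
}

window_indices <- function(axis, window) {
  ppm <- ppm_values(axis)
  idx <- which(ppm >= window[1] & ppm <= window[2])
  if (!length(idx)) {
    abort(sprintf("search window [%g, %g] ppm contains no axis points.",
                  window[1], window[2]), class = "gliomrs_window_error")
  }
  idx
}

#' Zero-order phase correction
#'
#' For each spectrum with an imaginary channel, searches a grid of zero-order
#' phase angles (default 1 degree steps over \[-180, 180\]) and applies the
#' rotation `real' = real cos(phi) - imag sin(phi)` (with
#' `imag' = real sin(phi) + imag cos(phi)`) that maximizes the maximum real
#' intensity inside the reference search window. Ties prefer the smallest
#' `|phi|`, so an already-phased spectrum is returned unchanged. Spectra
#' without an imaginary channel pass through as-is.
#'
#' @param spectra An `mrs_spectra` tibble.
#' @param config A [preprocess_config()].
#' @return The phased `mrs_spectra`; per-sample angles are recorded in the
#'   `preprocess_log` attribute (`phase_deg`).
#' @export
phase_correct <- function(spectra, config = preprocess_config()) {
  stopifnot(inherits(spectra, "mrs_spectra"))
  ax <- spectra_axis(spectra)
  win <- window_indices(ax, config$reference_search_window)
  step <- config$phase_step_deg
  grid <- seq(-180, 180, by = step) * pi / 180
  grid <- grid[order(abs(grid))] # smallest |phi| wins ties

  out <- dplyr::group_modify(
    dplyr::group_by(spectra, .data$sample_id),
    function(df, key) {
      df <- df[order(df$point), ]
      if (anyNA(df$imag)) {
        df$phase_deg <- 0
        return(df)
      }
      re_w <- df$real[win]
      im_w <- df$imag[win]
      scores <- vapply(grid, function(phi) {
        max(re_w * cos(phi) - im_w * sin(phi))
      }, numeric(1))
      phi <- grid[which.max(scores)]
      new_re <- df$real * cos(phi) - df$imag * sin(phi)
      new_im <- df$real * sin(phi) + df$imag * cos(phi)
      df$real <- new_re
      df$imag <- new_im
      df$phase_deg <- phi * 180 / pi
      df
    }
  )
  out <- dplyr::ungroup(out)
  log <- dplyr::distinct(out[, c("sample_id", "phase_deg")])
  out$phase_deg <- NULL
  out <- out[, c("sample_id", "label", "point", "ppm", "real", "imag")]
  res <- new_mrs_spectra(out[order(match(out$sample_id, unique(spectra$sample_id)),
                                   out$point), ], ax)
  attr(res, "preprocess_log") <- merge_log(attr(spectra, "preprocess_log"), log)
  res
}

#' Align spectra to the choline reference
#'
#' Circularly shifts each spectrum by the integer number of points that places
#' the maximum real intensity inside the reference search window exactly at
#' the axis point nearest `reference_ppm`. Expected shifts are small (a few
#' points), so the wrap-around affects only the spectrum edges, far outside
#' the analysed 4.5-0.7 ppm region.
#'
#' @inheritParams phase_correct
#' @return The aligned `mrs_spectra`; shifts are recorded in the
#'   `preprocess_log` attribute (`shift_points`).
#' @export
align_to_reference <- function(spectra, config = preprocess_config()) {
  stopifnot(inherits(spectra, "mrs_spectra"))
  ax <- spectra_axis(spectra)
  win <- window_indices(ax, config$reference_search_window)
  target <- ppm_to_index(ax, config$reference_ppm)

  out <- dplyr::group_modify(
    dplyr::group_by(spectra, .data$sample_id),
    function(df, key) {
      df <- df[order(df$point), ]
      w <- df$real[win]
      if (diff(range(w)) == 0) {
        abort(sprintf(
          "alignment failed for sample '%s': flat reference window.",
          key$sample_id[[1]]), class = "gliomrs_alignment_error")
      }
      shift <- target - win[which.max(w)]
      n <- nrow(df)
      idx <- ((seq_len(n) - 1L - shift) %% n) + 1L
      df$real <- df$real[idx]
      df$imag <- df$imag[idx]
      df$shift_points <- shift
      df
    }
  )
  out <- dplyr::ungroup(out)
  log <- dplyr::distinct(out[, c("sample_id", "shift_points")])
  out$shift_points <- NULL
  out <- out[, c("sample_id", "label", "point", "ppm", "real", "imag")]
  res <- new_mrs_spectra(out[order(match(out$sample_id, unique(spectra$sample_id)),
                                   out$point), ], ax)
  attr(res, "preprocess_log") <- merge_log(attr(spectra, "preprocess_log"), log)
  res
}

merge_log <- function(old, new) {
  if (is.null(old)) return(tibble::as_tibble(new))
  dplyr::left_join(tibble::as_tibble(old), tibble::as_tibble(new),
                   by = "sample_id")
}

new_mrs_features <- function(data, stage, axis = NULL) {
  stopifnot(stage %in% FEATURE_STAGES)
  structure(
    tibble::as_tibble(data),
    stage = stage, axis = axis,
    class = c("mrs_features", class(tibble::tibble()))
  )
}

#' @export
print.mrs_features <- function(x, ...) {
  cat(sprintf("<mrs_features> %d samples x %d bins, stage '%s'\n",
              dplyr::n_distinct(x$sample_id), dplyr::n_distinct(x$bin),
              feature_stage(x)))
  NextMethod()
}

#' Processing stage of a feature tibble
#' @param features An `mrs_features` tibble.
#' @return One of `"binned"`, `"region_selected"`, `"normalized"`, `"log2"`.
#' @export
feature_stage <- function(features) attr(features, "stage")

#' Equidistant binning
#'
#' Sums each run of `bin_size` consecutive points into one bin, traversing
#' from the high-ppm end; the `n_points %% bin_size` leftover points at the
#' low-ppm end are dropped. Summing (rather than averaging) conserves total
#' intensity, so the later normalization to a total signal intensity of 1 is
#' well defined. 1024 points at bin size 4 give 256 bins of about 0.038 ppm.
#'
#' @param spectra An `mrs_spectra` tibble (uses the real channel).
#' @param config A [preprocess_config()].
#' @return An `mrs_features` tibble at stage `"binned"` with columns
#'   `sample_id`, `label`, `bin`, `ppm_upper`, `ppm_lower`, `ppm_mid`, `value`.
#' @export
bin_spectrum <- function(spectra, config = preprocess_config()) {
  stopifnot(inherits(spectra, "mrs_spectra"))
  ax <- spectra_axis(spectra)
  bs <- config$bin_size
  if (bs > ax$n_points) {
    abort(sprintf("bin_size (%d) exceeds the number of points (%d).",
                  bs, ax$n_points))
  }
  n_bins <- ax$n_points %/% bs
  used <- n_bins * bs
  ppm <- ppm_values(ax)
  half <- ax$spacing_ppm / 2
  bin_of <- rep(seq_len(n_bins), each = bs)
  ppm_upper <- ppm[seq(1L, used, by = bs)] + half
  ppm_lower <- ppm[seq(bs, used, by = bs)] - half
  ppm_mid <- (ppm_upper + ppm_lower) / 2

  df <- spectra[spectra$point <= used, ]
  df$bin <- bin_of[df$point]
  agg <- dplyr::summarise(
    dplyr::group_by(df, .data$sample_id, .data$label, .data$bin),
    value = sum(.data$real), .groups = "drop"
  )
  agg$ppm_upper <- ppm_upper[agg$bin]
  agg$ppm_lower <- ppm_lower[agg$bin]
  agg$ppm_mid <- ppm_mid[agg$bin]
  agg <- agg[order(match(agg$sample_id, unique(spectra$sample_id)), agg$bin),
             c("sample_id", "label", "bin", "ppm_upper", "ppm_lower",
               "ppm_mid", "value")]
  new_mrs_features(agg, stage = "binned", axis = ax)
}

#' Keep only bins inside the analysis region
#'
#' Retains bins whose ppm midpoint lies inside the configured region
#' (default 0.7-4.5 ppm), discarding the residual water signal and signal-free
#' edges; order is preserved.
#'
#' @param features An `mrs_features` tibble at stage `"binned"`.
#' @param config A [preprocess_config()].
#' @return An `mrs_features` tibble at stage `"region_selected"`.
#' @export
select_region <- function(features, config = preprocess_config()) {
  check_stage(features, "binned")
  keep <- features$ppm_mid >= config$region[1] & features$ppm_mid <= config$region[2]
  out <- features[keep, ]
  if (!nrow(out)) {
    abort(sprintf("no bins fall inside the region [%g, %g] ppm.",
                  config$region[1], config$region[2]))
  }
  new_mrs_features(out, stage = "region_selected", axis = spectra_axis(features))
}

#' Normalize each sample to total signal intensity 1
#'
#' Negative bin values (pure noise excursions) are clipped to 0, then each
#' sample's bins are divided by their sum.
#'
#' @param features An `mrs_features` tibble at stage `"region_selected"` (or
#'   `"binned"`).
#' @return An `mrs_features` tibble at stage `"normalized"`; every sample's
#'   values sum to 1.
#' @export
normalize_total <- function(features) {
  check_stage(features, c("binned", "region_selected"))
  out <- dplyr::mutate(
    dplyr::group_by(features, .data$sample_id),
    value = pmax(.data$value, 0)
  )
  totals <- dplyr::summarise(out, total = sum(.data$value))
  zero <- totals$sample_id[totals$total <= 0]
  if (length(zero)) {
    abort(sprintf("sample '%s' has zero total intensity; cannot normalize.",
                  zero[1]), class = "gliomrs_normalization_error")
  }
  out <- dplyr::ungroup(
    dplyr::mutate(out, value = .data$value / sum(.data$value))
  )
  new_mrs_features(out, stage = "normalized", axis = spectra_axis(features))
}

#' Log2 transform
#'
#' Replaces each normalized value `v` by `log2(max(v, log_floor))`; the floor
#' keeps zero bins finite. Reduces the heteroscedasticity of peak-dominated
#' intensities.
#'
#' @param features An `mrs_features` tibble at stage `"normalized"`.
#' @param config A [preprocess_config()].
#' @return An `mrs_features` tibble at stage `"log2"`.
#' @export
log2_transform <- function(features, config = preprocess_config()) {
  check_stage(features, "normalized")
  out <- dplyr::mutate(features, value = log2(pmax(.data$value, config$log_floor)))
  new_mrs_features(out, stage = "log2", axis = spectra_axis(features))
}

check_stage <- function(features, expected) {
  stopifnot(inherits(features, "mrs_features"))
  st <- feature_stage(features)
  if (!st %in% expected) {
    abort(sprintf("expected feature stage %s, got '%s'.",
                  paste(sQuote(expected), collapse = " or "), st),
          class = "gliomrs_stage_error")
  }
  invisible(features)
}

#' Full preprocessing pipeline for a cohort
#'
#' Applies, per spectrum: zero-order phase correction, alignment to the
#' choline reference at 3.20 ppm, equidistant binning (4 points per bin),
#' selection of the 4.5-0.7 ppm region, normalization to total intensity 1
#' and the log2 transform.
#'
#' @param spectra An `mrs_spectra` tibble (all samples on one axis).
#' @param config A [preprocess_config()].
#' @return An `mrs_features` tibble at stage `"log2"`; the `preprocess_log`
#'   attribute records each sample's phase angle and alignment shift.
#' @export
preprocess_cohort <- function(spectra, config = preprocess_config()) {
  phased <- phase_correct(spectra, config)
  aligned <- align_to_reference(phased, config)
  feats <- log2_transform(
    normalize_total(select_region(bin_spectrum(aligned, config), config)),
    config
  )
  attr(feats, "preprocess_log") <- attr(aligned, "preprocess_log")
  feats
}
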