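#' Construct a chemical-shift (ppm) axis from acquisition metadata
#'
#' Builds the bijection between spectral point index and chemical shift for a
#' frequency-domain spectrum, following the NMR display convention: index 1 is
#' the left edge (highest ppm) and ppm decreases with increasing index. The
#' axis is symmetric about the carrier (transmitter) frequency, so the carrier
#' chemical shift lies within half a point spacing of the central point.
#'
#' The point spacing is `sweep_width / (n_points * spectrometer_freq)` ppm and
#' the spectral bandwidth (`n_points` spacings) equals
#' `sweep_width / spectrometer_freq` ppm.
#'
#' @param n_points Number of real data points (e.g. 1024).
#' @param sweep_width Spectral width in Hz (e.g. 1200).
#' @param spectrometer_freq Proton Larmor frequency in MHz (about 123.25 at
#'   3 T).
#' @param carrier_ppm Chemical shift of the carrier, i.e. the centre of the
#'   spectral window; the residual water signal at 4.70 ppm for in vivo
#'   acquisitions.
#' @return An object of class `ppm_axis`.
#' @examples
#' ax <- ppm_axis(1024, 1200, 123.25, 4.70)
#' range(ppm_values(ax))
#' ppm_to_index(ax, 3.20)
#' @export
ppm_axis <- function(n_points, sweep_width, spectrometer_freq, carrier_ppm) {
  for (nm in c("n_points", "sweep_width", "spectrometer_freq", "carrier_ppm")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      abort(sprintf("`%s` must be a single positive number (got %s).",
                    nm, deparse(v)), class = "gliomrs_invalid_parameter")
    }
  }
  n_points <- as.integer(n_points)
  sweep_width <- as.numeric(sweep_width)
  spectrometer_freq <- as.numeric(spectrometer_freq)
  carrier_ppm <- as.numeric(carrier_ppm)
  structure(
    list(
      n_points = n_points,
      sweep_width = sweep_width,
      spectrometer_freq = spectrometer_freq,
      carrier_ppm = carrier_ppm,
      spacing_ppm = sweep_width / (n_points * spectrometer_freq)
    ),
    class = "ppm_axis"
  )
}

#' @export
print.ppm_axis <- function(x, ...) {
  cat(sprintf(
    "<ppm_axis> %d points, %g Hz @ %g MHz, carrier %g ppm (%.6f ppm/point)\n",
    x$n_points, x$sweep_width, x$spectrometer_freq, x$carrier_ppm,
    x$spacing_ppm
  ))
  invisible(x)
}

#' Chemical shift of every point on an axis
#'
#' @param axis A [ppm_axis()].
#' @param index Optional integer vector of 1-based point indices; defaults to
#'   all points.
#' @return Numeric vector of chemical shifts in ppm, strictly decreasing with
#'   index.
#' @export
ppm_values <- function(axis, index = seq_len(axis$n_points)) {
  stopifnot(inherits(axis, "ppm_axis"))
  centre <- (axis$n_points + 1) / 2
  axis$carrier_ppm + (centre - index) * axis$spacing_ppm
}

#' Nearest point index for a chemical shift
#'
#' @param axis A [ppm_axis()].
#' @param ppm Numeric vector of chemical shifts.
#' @return Integer vector of 1-based indices of the nearest axis points.
#' @export
ppm_to_index <- function(axis, ppm) {
  stopifnot(inherits(axis, "ppm_axis"))
  centre <- (axis$n_points + 1) / 2
  idx <- as.integer(round(centre + (axis$carrier_ppm - ppm) / axis$spacing_ppm))
  pmin(pmax(idx, 1L), axis$n_points)
}

#' @rdname ppm_axis
#' @description `default_axis()` returns the acquisition geometry used
#'   throughout: 1024 real points over a 1200 Hz sweep at 3 T (123.25 MHz),
#'   centred on the residual water signal at 4.70 ppm.
#' @export
default_axis <- function() ppm_axis(1024L, 1200, 123.25, 4.70)

axes_equal <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 1e-12))
}
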