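#' Default metabolite basis set for glioma 1H-MRS simulation
#'
#' Returns one row per metabolite resonance with class-conditional
#' concentration distributions. Multiplets are collapsed to a few weighted
#' singlets per metabolite (relative amplitudes summing to 1); at the ~0.04 ppm
#' bin width the downstream analysis consumes, J-structure below that scale is
#' invisible, but multiplets wider than a bin (the strongly coupled spin
#' systems of Glu, Gln and 2-HG spread over roughly 0.1 ppm) are represented
#' by several sub-resonances so their dilution over the 2.0-2.5 ppm cluster is
#' reproduced. Chemical shifts follow standard proton assignments: choline
#' (Cho) 3.20 ppm, creatine (Cr) 3.03/3.93 ppm, N-acetylaspartate (NAA)
#' 2.01 ppm, lactate (Lac) 1.33 (CH3) and 4.10 ppm (CH), glutamate (Glu)
#' 2.04-2.35 plus 3.75 ppm, glutamine (Gln) 2.08-2.46 plus 3.77 ppm,
#' myo-inositol (M-ins) 3.52/3.61/4.05/3.27 ppm in proton-stoichiometric
#' proportion, glycine (Gly) 3.55 ppm singlet, D-2-hydroxyglutarate
#' (2-HG) with its two H-beta centred at 1.91 ppm, two H-gamma centred at
#' 2.24 ppm and H-alpha at 4.02 ppm, GABA 1.89/2.28/3.01 ppm and mobile
#' lipids at 0.9/1.3 ppm.
#'
#' Class effects (IDH-mutant vs wildtype) encode the expected biology: 2-HG is
#' present only in mutants, glycine is decreased (x0.6) and myo-inositol
#' increased (x1.5) in mutants, glutamate mildly decreased (x0.8). The
#' 2-HG H-gamma resonance sits in the Glu/Gln 2.2-2.45 ppm cluster, so at in
#' vivo linewidths those signals overlap into one hump.
#'
#' @param effect_scale Scales the mutant-vs-wildtype concentration differences:
#'   0 removes all class effects (mutant means equal wildtype means, 2-HG
#'   absent in both), 1 gives the default effects.
#' @return A tibble of class `mrs_basis` with columns `metabolite`, `shift_ppm`,
#'   `amplitude` (relative, summing to 1 within metabolite), `mean_mut`,
#'   `sd_mut`, `mean_wt`, `sd_wt`.
#' @export
default_basis <- function(effect_scale = 1) {
  stopifnot(is.numeric(effect_scale), length(effect_scale) == 1L,
            effect_scale >= 0)
  peak <- function(met, shifts, amps, mean_wt, sd_wt, mean_mut = mean_wt,
                   sd_mut = sd_wt) {
    tibble::tibble(metabolite = met, shift_ppm = shifts,
                   amplitude = amps / sum(amps),
                   mean_mut = mean_mut, sd_mut = sd_mut,
                   mean_wt = mean_wt, sd_wt = sd_wt)
  }
  basis <- dplyr::bind_rows(
    peak("Cho",   3.20, 1, 1.2, 0.17),
    peak("Cr",    c(3.03, 3.93), c(0.6, 0.4), 0.8, 0.10),
    peak("NAA",   c(2.01, 2.60), c(0.8, 0.2), 0.8, 0.17),
    peak("Lac",   c(1.33, 4.10), c(0.75, 0.25), 0.6, 0.30),
    peak("Glu",   c(2.04, 2.12, 2.30, 2.35, 3.75), c(0.15, 0.15, 0.20, 0.20, 0.30),
         1.0, 0.23, mean_mut = 0.8, sd_mut = 0.23),
    peak("Gln",   c(2.08, 2.16, 2.39, 2.46, 3.77), c(0.15, 0.15, 0.20, 0.20, 0.30),
         0.5, 0.17),
    peak("M-ins", c(3.52, 3.61, 4.05, 3.27), c(1/3, 1/3, 1/6, 1/6), 1.0, 0.13,
         mean_mut = 1.5, sd_mut = 0.20),
    peak("Gly",   3.55, 1, 0.6, 0.08, mean_mut = 0.36, sd_mut = 0.08),
    peak("2-HG",  c(1.86, 1.91, 1.96, 2.19, 2.24, 2.29, 3.98, 4.02, 4.06),
         c(0.13, 0.14, 0.13, 0.13, 0.14, 0.13, 0.065, 0.07, 0.065), 0.0, 0.0,
         mean_mut = 0.4, sd_mut = 0.13),
    peak("GABA",  c(1.89, 2.28, 3.01), c(0.35, 0.35, 0.30), 0.3, 0.10),
    peak("Lip",   c(0.90, 1.30), c(0.4, 0.6), 0.8, 0.27)
  )
  basis$mean_mut <- basis$mean_wt + effect_scale * (basis$mean_mut - basis$mean_wt)
  basis$sd_mut <- basis$sd_wt + effect_scale * (basis$sd_mut - basis$sd_wt)
  structure(basis, class = c("mrs_basis", class(basis)))
}

#' Simulation configuration
#'
#' @param axis Output [ppm_axis()]; default the in vivo 3 T geometry
#'   ([default_axis()]).
#' @param linewidth_fwhm Lorentzian full width at half maximum in Hz; 6 Hz is
#'   typical for single-voxel in vivo spectra at 3 T, 1 Hz for ex vivo
#'   high-resolution spectra.
#' @param noise_sd Standard deviation of the additive i.i.d. Gaussian noise,
#'   in the same arbitrary units as the lineshape amplitudes.
#' @param shift_jitter_sd Standard deviation (ppm) of the per-spectrum global
#'   frequency offset, emulating B0 drift that choline alignment corrects.
#' @param phase_error_sd Standard deviation (degrees) of the per-spectrum
#'   zero-order phase error.
#' @param baseline_amplitude Scale of the smooth random cubic baseline; 0
#'   disables the baseline.
#' @param n_mut,n_wt Cohort sizes per class; the defaults mirror a 34-patient
#'   cohort with 22 IDH-mutant and 12 IDH-wildtype gliomas.
#' @param seed Master seed for reproducible cohort generation.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(axis = default_axis(), linewidth_fwhm = 6,
                       noise_sd = 0.6, shift_jitter_sd = 0.01,
                       phase_error_sd = 10, baseline_amplitude = 0.5,
                       n_mut = 22L, n_wt = 12L, seed = 1L) {
  stopifnot(inherits(axis, "ppm_axis"), linewidth_fwhm > 0, noise_sd >= 0,
            shift_jitter_sd >= 0, phase_error_sd >= 0,
            baseline_amplitude >= 0, n_mut >= 0, n_wt >= 0)
  structure(list(
    axis = axis, linewidth_fwhm = as.numeric(linewidth_fwhm),
    noise_sd = as.numeric(noise_sd),
    shift_jitter_sd = as.numeric(shift_jitter_sd),
    phase_error_sd = as.numeric(phase_error_sd),
    baseline_amplitude = as.numeric(baseline_amplitude),
    n_mut = as.integer(n_mut), n_wt = as.integer(n_wt),
    seed = as.integer(seed)
  ), class = "sim_config")
}

# complex unit-area Lorentzian on a ppm grid: absorption + i * dispersion
lorentzian_complex <- function(ppm, centre, hwhm_ppm) {
  d <- ppm - centre
  denom <- pi * (d^2 + hwhm_ppm^2)
  complex(real = hwhm_ppm / denom, imaginary = -d / denom)
}

#' Simulate one spectrum
#'
#' The spectrum is the concentration-weighted sum of unit-area complex
#' Lorentzians (one per basis resonance, FWHM `linewidth_fwhm` converted to
#' ppm), shifted by one global frequency-jitter draw, rotated by a zero-order
#' phase-error draw, plus a smooth random cubic baseline and i.i.d. Gaussian
#' noise. Concentration draws are Gaussian truncated at zero. The real channel
#' carries the displayed spectrum; the imaginary channel is retained so
#' downstream phase correction has both quadratures.
#'
#' @param basis A basis tibble as from [default_basis()].
#' @param label `"IDHmut"` or `"IDHwt"`: selects the class-conditional
#'   concentration distributions.
#' @param config A [sim_config()].
#' @param seed Integer seed making the draw reproducible.
#' @param sample_id Sample identifier.
#' @return An `mrs_spectra` tibble with one sample.
#' @export
simulate_spectrum <- function(basis, label, config = sim_config(),
                              seed = 1L, sample_id = "sim01") {
  if (!label %in% c("IDHmut", "IDHwt")) {
    abort(sprintf("label must be 'IDHmut' or 'IDHwt', got '%s'.", label),
          class = "gliomrs_label_error")
  }
  ax <- config$axis
  ppm <- ppm_values(ax)
  hwhm_ppm <- (config$linewidth_fwhm / 2) / ax$spectrometer_freq

  old <- .Random.seed_safe()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  mu <- if (label == "IDHmut") basis$mean_mut else basis$mean_wt
  sigma <- if (label == "IDHmut") basis$sd_mut else basis$sd_wt
  mets <- unique(basis$metabolite)
  conc_by_met <- setNames(numeric(length(mets)), mets)
  for (m in mets) {
    i <- which(basis$metabolite == m)[1]
    conc_by_met[m] <- max(0, rnorm(1, mu[i], sigma[i]))
  }
  jitter <- rnorm(1, 0, config$shift_jitter_sd)
  phase <- rnorm(1, 0, config$phase_error_sd) * pi / 180

  signal <- complex(real = numeric(ax$n_points), imaginary = numeric(ax$n_points))
  for (r in seq_len(nrow(basis))) {
    conc <- conc_by_met[[basis$metabolite[r]]]
    if (conc == 0) next
    signal <- signal + conc * basis$amplitude[r] *
      lorentzian_complex(ppm, basis$shift_ppm[r] + jitter, hwhm_ppm)
  }
  signal <- signal * exp(1i * phase)

  baseline <- if (config$baseline_amplitude > 0) {
    x <- seq(-1, 1, length.out = ax$n_points)
    coef <- rnorm(4) / (1 + 0:3)
    config$baseline_amplitude * (coef[1] + coef[2] * x + coef[3] * (2 * x^2 - 1) +
                                   coef[4] * (4 * x^3 - 3 * x))
  } else {
    rnorm(4) # keep the stream position identical whether or not baseline is on
    numeric(ax$n_points)
  }
  noise_re <- if (config$noise_sd > 0) rnorm(ax$n_points, 0, config$noise_sd) else 0
  noise_im <- if (config$noise_sd > 0) rnorm(ax$n_points, 0, config$noise_sd) else 0

  real <- Re(signal) + baseline + noise_re
  imag <- Im(signal) + noise_im
  mrs_spectra(
    tibble::tibble(sample_id = sample_id, label = label,
                   point = seq_len(ax$n_points), real = real, imag = imag),
    ax
  )
}

#' Simulate a labeled cohort
#'
#' Draws `n_mut` IDH-mutant and `n_wt` IDH-wildtype spectra. One master seed
#' spawns an independent per-sample seed, so cohorts are reproducible and any
#' single spectrum can be regenerated in isolation.
#'
#' @inheritParams simulate_spectrum
#' @return An `mrs_spectra` tibble with `n_mut + n_wt` samples (mutants first).
#' @export
simulate_cohort <- function(basis = default_basis(), config = sim_config()) {
  n <- config$n_mut + config$n_wt
  if (n < 2L) abort("n_mut + n_wt must be at least 2.")
  old <- .Random.seed_safe()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  sample_seeds <- sample.int(.Machine$integer.max - 1L, n)
  labels <- c(rep("IDHmut", config$n_mut), rep("IDHwt", config$n_wt))
  ids <- sprintf("%s%02d", ifelse(labels == "IDHmut", "mut", "wt"),
                 c(seq_len(config$n_mut), seq_len(config$n_wt)))
  specs <- purrr::pmap(
    list(labels, sample_seeds, ids),
    function(lab, sd_i, id) simulate_spectrum(basis, lab, config, seed = sd_i,
                                              sample_id = id)
  )
  new_mrs_spectra(dplyr::bind_rows(specs), config$axis)
}

#' Simulate an ex vivo high-resolution spectrum
#'
#' Same generative model as [simulate_spectrum()] but on a fine axis with a
#' narrow linewidth (default 1 Hz FWHM at 600 MHz, emulating a 14.1 T
#' spectrometer) and, by default, no noise, jitter, phase error or baseline.
#' At this resolution the glycine singlet (3.55 ppm), the myo-inositol
#' multiplet (3.52/3.61 ppm) and the 2-HG resonances separate from the
#' glutamate/glutamine cluster that swallows them in vivo.
#'
#' @inheritParams simulate_spectrum
#' @param linewidth_fwhm FWHM in Hz (default 1).
#' @param noise_sd Noise level (default 0).
#' @export
simulate_highres <- function(basis, label, seed = 1L, linewidth_fwhm = 1,
                             noise_sd = 0, sample_id = "exvivo01") {
  axis_hr <- ppm_axis(8192L, 7200, 600, 4.70) # 12 ppm window at 600 MHz
  cfg <- sim_config(axis = axis_hr, linewidth_fwhm = linewidth_fwhm,
                    noise_sd = noise_sd, shift_jitter_sd = 0,
                    phase_error_sd = 0, baseline_amplitude = 0,
                    n_mut = 1L, n_wt = 1L, seed = seed)
  simulate_spectrum(basis, label, cfg, seed = seed, sample_id = sample_id)
}

.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
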