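# Fixtures are built in code; nothing is stored on disk.

# A features tibble built directly from a samples-by-features matrix, with
# bins laid out on a plausible decreasing ppm grid. Lets classifier tests run
# without simulating spectra.
toy_features <- function(X, labels, stage = "log2") {
  n <- nrow(X)
  p <- ncol(X)
  ids <- sprintf("s%02d", seq_len(n))
  width <- 0.038
  upper <- 4.5 - (seq_len(p) - 1) * width
  long <- tibble::tibble(
    sample_id = rep(ids, each = p),
    label = rep(labels, each = p),
    bin = rep(seq_len(p), n),
    ppm_upper = rep(upper, n),
    ppm_lower = rep(upper - width, n),
    ppm_mid = rep(upper - width / 2, n),
    value = as.vector(t(X))
  )
  gliomrs:::new_mrs_features(long, stage = stage, axis = NULL)
}

# Two Gaussian clouds separated along the first `informative` features.
toy_classes <- function(n_pos = 10, n_neg = 10, p = 20, informative = 1,
                        effect = 3, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm((n_pos + n_neg) * p), n_pos + n_neg, p)
  X[seq_len(n_pos), seq_len(informative)] <-
    X[seq_len(n_pos), seq_len(informative)] + effect
  labels <- c(rep("IDHmut", n_pos), rep("IDHwt", n_neg))
  toy_features(X, labels)
}

# Re-label a features tibble by sample (used for permutation nulls).
relabel_features <- function(features, labels_by_id) {
  features$label <- unname(labels_by_id[features$sample_id])
  features
}

# A small, fast cohort: fewer samples and lower-resolution axis than the
# defaults, same generative model.
quick_cohort <- function(n_mut = 6, n_wt = 6, seed = 1, noise_sd = 0.6, ...) {
  cfg <- sim_config(n_mut = n_mut, n_wt = n_wt, seed = seed,
                    noise_sd = noise_sd, ...)
  simulate_cohort(default_basis(), cfg)
}

# Single-metabolite basis for geometry tests.
singlet_basis <- function(shift = 3.20, conc = 1, sd = 0) {
  b <- default_basis()[1, ]
  b$metabolite <- "X"
  b$shift_ppm <- shift
  b$amplitude <- 1
  b$mean_mut <- conc; b$mean_wt <- conc
  b$sd_mut <- sd; b$sd_wt <- sd
  b
}

# Deterministic simulation settings: all stochastic nuisance terms off
# (individually overridable).
clean_config <- function(...) {
  args <- list(noise_sd = 0, shift_jitter_sd = 0, phase_error_sd = 0,
               baseline_amplitude = 0)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# Chemical shift snapped to the nearest axis grid point, so a singlet's
# absorption maximum falls exactly on a sampled point.
grid_ppm <- function(ppm, axis = default_axis()) {
  ppm_values(axis)[ppm_to_index(axis, ppm)]
}
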