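---
title: "Classifying IDH genotype from single-voxel 1H-MR spectra: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying IDH genotype from single-voxel 1H-MR spectra: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`gliomrs` takes frequency-domain single-voxel ¹H-MR spectra of gliomas,
preprocesses them into binned log-intensity feature vectors, and estimates how
well the IDH genotype can be read off those vectors with a nested leave-one-out
cross-validated linear SVM. Because patient spectra are rarely shareable, the
package ships a synthetic-cohort generator that reproduces the statistical
structure this analysis assumes, so every stage is testable end to end. This
vignette records the models, the defaults and the design decisions.

## The spectral axis

A spectrum is a vector of `n_points` real intensities (optionally with the
imaginary quadrature) on a chemical-shift axis defined by the acquisition:
sweep width `sw` (Hz), spectrometer frequency `f` (MHz) and the carrier shift
(4.70 ppm, the residual water resonance, for in vivo acquisitions). The point
spacing is `sw/(n_points * f)` ppm, so the n-point bandwidth equals `sw/f`
exactly. Points are stored left-to-right from high to low ppm (the NMR display
convention) on an axis symmetric about the carrier; with the default geometry
(1024 points, 1200 Hz, 123.25 MHz at 3 T) the spacing is 0.0095 ppm and the
axis runs from about 9.56 down to −0.16 ppm. The symmetric convention keeps a
two-point axis straddling the carrier and puts the carrier within half a
spacing of the central point.

## The generative model

`simulate_spectrum()` draws one spectrum as

> Σ_metabolites conc × Σ_peaks amplitude × L(shift + δ, FWHM) · e^{iφ}
> + baseline + noise

where `L` is a complex unit-area Lorentzian (absorption + i·dispersion), `δ` a
single per-spectrum frequency offset (Gaussian, `shift_jitter_sd`, default
0.01 ppm), `φ` a zero-order phase error (Gaussian, `phase_error_sd`, default
10°), the baseline a random cubic scaled by `baseline_amplitude` (default
0.5), and the noise i.i.d. Gaussian per point (`noise_sd`, default 0.6).
Concentrations are Gaussian draws truncated at zero. One global `δ` per
spectrum — rather than per-peak jitter — models the B₀/frequency drift that
choline referencing corrects; per-peak jitter has no physical counterpart at
these linewidths. The default in vivo linewidth is 6 Hz FWHM (typical for
3 T single-voxel acquisitions); `simulate_highres()` switches to a 600 MHz
axis and 1 Hz FWHM, emulating ex vivo spectra of tissue extracts in which the
in vivo overlaps resolve.

The basis (`default_basis()`) collapses each metabolite's J-coupled multiplets
into a few weighted Lorentzian singlets. Structure finer than the 0.038 ppm
analysis bins is invisible downstream, but multiplets *wider* than a bin
matter, so the strongly coupled spin systems of Glu, Gln and 2-HG are spread
over several sub-resonances spanning their ~0.1 ppm widths (2-HG: Hβ centred
at 1.91 ppm, Hγ at 2.24 ppm, Hα at 4.02 ppm; myo-inositol carries its four
in vivo resonances at 3.52/3.61/4.05/3.27 ppm in proton-stoichiometric
proportion). Chemical shifts are standard literature values; everything —
shifts, amplitudes, class-conditional means and SDs — lives in an editable
tibble, not in code constants.

Class effects encode IDH biology: 2-HG present only in mutants; glycine
decreased (×0.6) and myo-inositol increased (×1.5) in mutants; glutamate
mildly decreased (×0.8). `default_basis(effect_scale = s)` interpolates the
mutant parameters between "no class difference" (s = 0) and the defaults
(s = 1), which is how the monotone-difficulty property is tested.

**Calibration.** The free parameters (noise SD, concentration CVs) were fixed
once, by design, so that (a) class separation is real but imperfect — a 22+12
cohort classifies at roughly 85–90% accuracy, the regime a realistic clinical
cohort occupies — and (b) the 2.0–2.5 ppm Glu/Gln/GABA cluster is variable
enough between subjects that the 2-HG increment is not a reliable single
marker, reproducing the in vivo situation in which whole-spectrum
classification is needed at all. Concretely: concentration CVs of 10–30% with
the largest variability on Glu, Gln and Lac; 2-HG mean 0.4 (relative to
Glu = 1); noise SD 0.6, i.e. a peak SNR of ~26 for choline. These defaults
were frozen before the acceptance checks were written and are all
overridable.

**What the generator does not emulate:** full density-matrix J-coupling
evolution, macromolecule baselines fitted to tissue data, eddy-current or
first-order phase distortions, B₀ inhomogeneity across the voxel, correlated
(residual-water) noise, and partial-volume or CSF contamination. Passing the
synthetic benchmarks therefore demonstrates that the *pipeline* is correct and
unbiased under the stated statistical structure — not that any particular
accuracy will be attained on scanner data.

## Preprocessing

Per spectrum, in order:

1. **Zero-order phase correction** — grid search over φ ∈ [−180°, 180°] in 1°
   steps maximizing the maximum real intensity inside the reference window
   (3.00–3.40 ppm). Spectra without an imaginary channel pass through. Ties
   prefer |φ| = 0, so phasing is idempotent. On a discrete grid the criterion
   has a small bias (a few degrees) when the reference peak falls between
   sample points; the residual dispersion admixture is far below the noise.
2. **Choline alignment** — circular shift placing the window maximum exactly
   at the point nearest 3.20 ppm. Shifts are a few points, so the wrap-around
   touches only the spectrum edges, well outside the analysis region. A flat
   window is an error naming the sample.
3. **Binning** — sums of 4 consecutive points, traversed from the high-ppm
   end; `floor(1024/4) = 256` bins, remainder points dropped. Sums (not
   means) conserve total intensity, which keeps "normalize to total intensity
   1" well defined. Other edge-trimming conventions would change this count
   by a few bins without affecting the selected region below.
4. **Region selection** — keep bins whose ppm *midpoint* lies in
   [0.7, 4.5] ppm (midpoint rule: unambiguous for boundary-straddling bins),
   discarding residual water and empty edges; ≈100 bins remain.
5. **Normalization** — negative bin values (noise excursions) are clipped to
   0, then each sample is scaled to total intensity 1. Clipping is required
   for the log step and removes only noise, as real metabolite signal is
   non-negative.
6. **log₂ transform** — `log2(max(v, 1e-6))`; the floor keeps empty bins
   finite and compresses the heteroscedastic peak-dominated scale.

The pipeline is scale-equivariant: multiplying a raw spectrum by any positive
constant leaves its final feature vector unchanged.

## The classifier and its cross-validation

The classifier is a linear soft-margin SVM with cost C = 1 (the conventional
default, deliberately not tuned), trained on features standardized by
training-fold mean and SD. Training solves the C-SVM dual by sequential
minimal optimization (maximal-violating-pair working set, tolerance 1e-8) in
compiled code; the solver is cross-checked in the test suite against both a
brute-force grid minimization of the regularized hinge objective and an
independent SVM library. Decision values are positive on the IDH-mutant side;
an exact zero decision is classified as mutant (a documented, test-pinned tie
rule). Mutant is the positive class throughout, so "sensitivity" always means
mutation detection.

Feature selection is a Welch t-test filter: features are ranked by |t|
(unequal-variance form, the safer choice for 22-vs-12 class sizes);
zero-variance features rank last, ties break toward the lower bin index.

`nested_loocv()` runs the fully nested procedure. For each held-out sample:
the remaining n−1 samples form the outer-training set; an inner leave-one-out
loop over that set evaluates every feature count k = 1, 2, …, `k_max`
(default 15), *re-ranking features on each inner-training subset* so that no
inner held-out sample leaks into its own ranking; the k with the best inner
accuracy wins, smallest k on ties ("global max" rule — a "first local max"
alternative is available for sensitivity analysis); features are then
re-ranked on the full outer-training set, the top k are kept, the SVM is
trained, and the held-out sample is predicted. Whether re-ranking should
happen per inner fold or once per outer-training set is a genuinely open
choice; full nesting is the unbiased reading and is the default. The
procedure contains no randomness: a fixed feature matrix gives a bit-identical
result, and `nested_fold()` exposes any single fold's decision path so the
strict train/test separation can be audited directly (the test suite replaces
held-out samples with arbitrary values and checks the fold's model is
unchanged).

## Reporting

- **Confusion-derived rates** with percentages rounded half away from zero to
  one decimal (88.235 → 88.2, 95.4545… → 95.5).
- **Exact Clopper–Pearson intervals** via the beta-quantile closed form;
  boundary cases are closed-form (x = 0 → lower 0; x = n → upper 1, lower
  (α/2)^{1/n}). Exactness is verified against tail-sum bisection for every
  (x, n ≤ 40). No asymptotic interval is offered: at n = 12–22 the normal
  approximation is visibly wrong.
- **AUC** as the Mann–Whitney probability over pooled outer-fold decision
  values, ties counted ½. Pooling decision values across folds is the
  standard construction for LOOCV ROC curves; per-fold curves are undefined
  for single held-out samples.
- **Feature annotation** maps each selected bin to every basis metabolite
  whose resonance lies within 0.04 ppm (about one in vivo linewidth) of the
  bin's interval; unmatched bins are "unassigned".
- **Class-averaged spectra** are computed on the normalized (pre-log) scale,
  where class differences in the 4.1–3.5 ppm window are directly
  interpretable as intensity-fraction changes.

## Numerical and interface choices

- Spectrometer frequency (123.25 MHz) and water carrier (4.70 ppm) are config
  defaults, not constants; only the field strength fixes them.
- Text spectra: `#`-prefixed `key: value` headers carrying the axis metadata,
  then one (real) or two (real imaginary) floats per line; full-precision
  round trip. Feature matrices: RFC-4180 CSV, bins as `upper..lower` ppm
  column labels, `sample_id` first and `label` last.
- Every artifact a run writes carries a hash of the canonical YAML form of
  its configuration; readers refuse to mix artifacts from different
  configurations.
- Cohort seeding: one master seed spawns per-sample seeds, so single spectra
  are reproducible in isolation.

## Problem sizes used by the test suite

Unit tests run on reduced cohorts (6–20 samples) and constructed feature
matrices. The statistical property checks use: all (x, n ≤ 40) for interval
exactness; 200 random score sets for AUC; a 20-sample cohort with every fold
perturbed for leakage freedom; 50 label permutations of one 34-sample cohort
for the null calibration; 10 seeded 22+12 replicates for signal recovery; and
a 3-level effect-size sweep with 6 replicates per level for the difficulty
trend. These sizes were chosen to make the sampling distributions tight
enough for the assertions while keeping the default test run fast.

## Known limitations

Zero-order phasing only; no baseline subtraction (the classifier sees the
baseline as nuisance variation); no metabolite quantification — the pipeline
classifies binned patterns, it does not estimate concentrations; binary
genotype only; no probability calibration of decision values. The mean number
of selected features at the synthetic defaults (≈9–11) is larger than what a
concentrated two-peak signal would give: the synthetic class signal is spread
over several multiplet bins, so the inner loop legitimately keeps more of
them. On data whose discriminative signal is concentrated in one or two bins,
the same procedure selects one or two features, as the constructed-data tests
demonstrate.
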