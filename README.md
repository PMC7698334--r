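# gliomrs

Non-invasive prediction of IDH genotype in glioma from standard single-voxel
¹H-MR spectra, as a reusable, fully testable R pipeline.

## The problem

Gliomas carrying an *isocitrate dehydrogenase* (*IDH*) mutation have a markedly
better prognosis than *IDH*-wildtype tumors, so the genotype matters before
surgery — but confirming it normally requires tissue. The mutant enzyme
produces the oncometabolite D-2-hydroxyglutarate (2-HG), which is visible by
NMR in principle; in vivo at 3 T, however, the 2-HG multiplets (Hβ ≈ 1.91 ppm,
Hγ ≈ 2.24 ppm) drown in the overlapping glutamate/glutamine/GABA cluster.
The way out is to classify the *whole* spectrum instead of one peak: an
*IDH* mutation shifts several metabolites at once, most visibly glycine (Gly,
down) and myo-inositol (M-ins, up) around 3.5–3.65 ppm.

`gliomrs` implements that analysis end to end:

1. **Simulation** (`simulate_cohort()`) — labeled cohorts of synthetic
   single-voxel spectra (1024 points, 1200 Hz sweep at 3 T, water carrier
   4.70 ppm) built from a metabolite basis of Lorentzian lineshapes with
   class-conditional concentrations, frequency jitter, phase error, baseline
   and noise. A narrow-linewidth mode (`simulate_highres()`) emulates ex vivo
   14.1 T spectra in which the overlapped resonances resolve.
2. **Preprocessing** (`preprocess_cohort()`) — zero-order phase correction;
   alignment to the choline singlet at 3.20 ppm; equidistant binning of 4
   points per bin; restriction to 4.5–0.7 ppm (≈100 bins); normalization to
   total intensity 1; log₂ transform.
3. **Classification** (`nested_loocv()`) — nested leave-one-out
   cross-validation around a linear soft-margin SVM (cost C = 1). In every
   outer fold the number of features k is tuned by an inner leave-one-out
   loop that re-ranks features on each inner training subset by the absolute
   Welch t statistic and increases k in steps of one; the held-out spectrum
   never influences ranking, k, standardization or training.
4. **Reporting** (`performance_report()`) — confusion counts; accuracy,
   sensitivity and specificity with exact Clopper–Pearson 95% confidence
   intervals; AUC from pooled outer-fold decision values (Mann–Whitney, ties
   ½); per-bin selection frequencies annotated with candidate metabolites;
   class-averaged spectra.

The linear SVM is trained by a package-native SMO solver (C++); the statistics
it reports are, for x successes in n trials,

    CI_lower = qbeta(α/2, x, n − x + 1),   CI_upper = qbeta(1 − α/2, x + 1, n − x)

and AUC = P(score⁺ > score⁻) + ½·P(tie), estimated over all
positive/negative pairs.

## Worked example

```r
library(gliomrs)

cfg <- run_config(output_dir = "demo", seed = 1)   # 22 IDHmut + 12 IDHwt
report <- run_pipeline(cfg)
print(report)
```

```
IDH-status prediction, 34 samples (positive class IDHmut)
  accuracy     91.2%  (31/34)
  sensitivity  90.9%  (95% CI 70.8-98.9%)
  specificity  91.7%  (95% CI 61.5-99.8%)
  AUC          0.86
  mean features per fold: 10.7
  most selected bins:
     2.38-2.34 ppm  100%  Glu, Gln
     2.23-2.19 ppm   97%  Gln, 2-HG
     1.92-1.89 ppm   97%  2-HG, GABA
     2.27-2.23 ppm   94%  Glu, 2-HG, GABA
     3.79-3.75 ppm   91%  Glu, Gln
```

Reading: of 34 simulated patients, 31 were genotyped correctly by spectra
alone; the exact binomial intervals are wide because each class contributes
only 22 and 12 samples. `run_pipeline()` also writes the feature matrix,
per-sample predictions, selected-feature table, a JSON report and the YAML
configuration (all stamped with a config hash) into `output_dir`.
`tidy()`/`glance()` methods and `autoplot()`/`plot_class_spectra()` give
tibble summaries and ggplot figures of the same objects. A command-line
wrapper lives at `inst/cli/gliomrs.R`.

Statistics from published counts work directly:

```r
clopper_pearson(21, 22)   # sensitivity 95.5%, 95% CI 0.772-0.999
confusion_metrics(data.frame(
  truth = rep(c("IDHmut", "IDHwt"), c(22, 12)),
  predicted = rep(c("IDHmut", "IDHwt", "IDHwt", "IDHmut"), c(21, 1, 9, 3))
))                        # accuracy 88.2%, sensitivity 95.5%, specificity 75.0%
```

## Limitations

The simulator collapses J-coupled multiplets to weighted Lorentzian
singlets, uses a single global frequency offset per spectrum and i.i.d.
Gaussian noise, and does not model macromolecule baselines or eddy currents;
see the methods vignette (`vignettes/idh-mrs-classification.Rmd`) for the
generative model, parameter defaults and what synthetic results do and do not
establish about patient data. Native Siemens `.rda` files are not parsed:
spectra enter as plain-text point lists (the jMRUI-style text export) via
`read_spectrum_txt()`.
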