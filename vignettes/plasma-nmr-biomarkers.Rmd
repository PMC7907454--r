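---
title: "Plasma 1H-NMR biomarker discovery for foie gras quality: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plasma 1H-NMR biomarker discovery: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gavageNMR)
```

## The problem

*Foie gras* quality is driven by two correlated liver traits measured at or
after slaughter: liver weight (LW, g; the French label requires > 300 g) and
cooking technological yield (TY, %; the share of crude liver mass retained
through cooking once visibly melted lipids are credited back, required to
exceed 70%). Because TY can only be measured destructively, producers want
*plasmatic* biomarkers — metabolites measurable in a blood sample taken
before slaughter — that predict the traits. Overfeeding mule ducks for 6 to
12 days produces a wide spread of both traits (roughly 300–915 g and
55–99.5%, with an LW–TY correlation near −0.82), which is the statistical
leverage this pipeline exploits.

`gavageNMR` implements the complete discovery pipeline on frequency-domain
plasma ^1^H-NMR spectra, in two parallel branches:

1. **Bucket method** — spectra are calibrated on the TSP reference, aligned,
   integrated into fixed 0.01-ppm buckets over 0.5–10 ppm (water 4.5–5.1 and
   residual extraction methanol 3.33–3.38 excluded) and normalized by
   whole-spectrum intensity.
2. **Metabolite method** — spectra are deconvolved against a fingerprint
   library (peak shift ranges, multiplicities, proton counts) by
   non-negative least squares, yielding unit-less relative concentrations,
   followed by a 50% within-day presence filter.

Each branch feeds the same chemometric machinery: Pareto scaling, a
single-component PLS regression per trait, VIP scoring, 7-fold
cross-validated Q², RMSEE/RMSECv, and a 500-permutation validation. Candidate
variables (VIP > 1) are screened by one-by-one regressions with
Benjamini–Hochberg (BH) correction: *significant* below 0.05, *tendency*
in [0.05, 0.10). The two branches are reconciled by a Venn comparison and
the selected biomarkers summarised as a correlation network against the
trait.

## The statistical model

For a Pareto-scaled predictor matrix $X$ (samples × buckets or metabolites)
and centred response $y$ (LW or TY), the single-component PLS1 solution is

$$w = \frac{X^\top y}{\lVert X^\top y\rVert},\qquad t = Xw,\qquad
  p = \frac{X^\top t}{t^\top t},\qquad q = \frac{y^\top t}{t^\top t},$$

with $R^2X = \lVert t p^\top\rVert^2 / \lVert X\rVert^2$ and
$R^2Y = 1 - \lVert y - tq\rVert^2 / \lVert y - \bar y\rVert^2$. For one
component the standard VIP formula reduces to
$\mathrm{VIP}_k = \sqrt{p_{\mathrm{vars}}\, w_k^2}$, so the mean squared VIP
is exactly 1 and "VIP > 1" reads as *more important than average*. Q² uses
seeded shuffled contiguous 7-fold cross-validation,
$Q^2 = 1 - \mathrm{PRESS}/\sum (y-\bar y)^2$, with
$\mathrm{RMSECv} = \sqrt{\mathrm{PRESS}/n}$ and
$\mathrm{RMSEE} = \sqrt{\mathrm{RSS}/(n - 1 - a)}$, $a = 1$ component (the
chemometric convention; the two should be close for a well-specified
model). Permutation validation refits the model on randomly permuted
responses: the model is *valid* when every permuted Q² lies below the
original and the regression line of Q² on |correlation with the original
response| (original point included at 1) has a non-positive intercept. The
|correlation| abscissa makes the intercept criterion well defined when a
permutation happens to anti-correlate with $y$.

Univariate screening regresses each variable on the trait; the p-value of
the slope t-test is direction-invariant for simple regression, so which
side of the regression carries the trait does not matter. BH families are
formed per trait × method run (four families), never pooled. BH adjustment
itself is delegated to `stats::p.adjust(method = "BH")`; the test suite
checks it against an independent brute-force step-up implementation.

## The synthetic cohort generator

No public spectra exist for this design, so the generator is a first-class
module that forges cohorts with the study's statistical structure and
provides the ground truth all recovery tests rely on.

* **Phenotypes.** LW is drawn from day-specific Gaussians whose means
  interpolate the configured range across overfeeding days 6/8/10/12
  (16, 16, 16, 17 animals by default), truncated to the range; the
  within-day SD (80 g by default) is an assumption of the generator — the
  emulated study reports ranges, not within-day variances. TY is generated
  jointly as $\mathrm{TY} = \mu + \sigma(\rho z + \sqrt{1-\rho^2}\,
  \varepsilon)$ with $z$ the standardized LW and $\rho = -0.82$ by default,
  with $\sigma$ set to one sixth of the TY range so that clamping to the
  range is rare and the sample correlation lands within 0.05 of the target
  on average.
* **Concentrations.** `conc = baseline + sign·effect·noise_sd·z(LW) +
  N(0, noise_sd)`, truncated at zero (configurations that would truncate
  more than half of a metabolite's values are rejected as implausible).
  Default signs and effect sizes emulate the reported correlation
  structure — lactate trait-positive for LW, the amino-acid and polyol
  biomarkers negative, with `effect = |r|/sqrt(1-r^2)` derived from the
  published bucket-route correlations; valine is modelled LW-positive (it
  tracks TY negatively) and glucose, xylitol and ethanolamine are nulls.
* **Spectra.** Each metabolite's fingerprint is rendered as Lorentzian
  multiplets (FWHM 0.002 ppm, lines 0.012 ppm apart with binomial
  intensities; a "multiplet" is rendered as five evenly spaced lines) on a
  2^15-point grid over −0.5 to 10.5 ppm, stored high-to-low. Per-peak area
  is proportional to concentration × proton count; every rendered line is
  rescaled so its *discrete* integral matches its intended area exactly,
  which makes total-intensity conservation hold by construction regardless
  of Lorentzian tail truncation (render window ±0.8 ppm). A TSP reference
  singlet at 0.0 ppm, a Gaussian residual-water hump at 4.79 ppm and a
  residual methanol singlet at 3.355 ppm are added, then a global
  chemical-shift jitter (N(0, 0.003 ppm) by default) and additive Gaussian
  intensity noise (SD 10 by default, a high-SNR regime appropriate for
  cryoprobe plasma acquisitions), truncated at zero.

What the generator deliberately does **not** emulate: time-domain (FID)
processing, phase and baseline errors, J-coupling physics, peak-position
dependence on pH or ionic strength, and between-metabolite peak-shape
differences. Passing recovery tests therefore demonstrates that the
*pipeline logic* is sound — they cannot certify performance on real plasma
spectra, where template mismatch and baseline artifacts dominate.

## Numerical and design choices

* **Bucket intensity** is the trapezoid integral of the curve over the
  half-open bucket `[lo, hi)`, not the apex height; integration is
  scale-consistent and robust to grid/bucket misalignment (bucket edges
  between grid points are handled by interpolating the cumulative
  integral).
* **Exclusion rule**: a bucket is dropped when it has *positive-measure*
  overlap with an exclusion range, so the water exclusion removes exactly
  60 buckets and methanol 5, leaving 885 of 950. Published bucket tables
  from comparable platforms sometimes report fewer columns (e.g. after
  removal of empty buckets); no attempt is made to reproduce any
  particular trimmed count.
* **Peak-to-bucket mapping** uses closed-interval overlap (a bucket
  touching a peak boundary is included); widening the tolerance can only
  grow a mapping.
* **Whole-spectrum intensity** for normalization is the sum over retained
  buckets — solvent regions are removed before normalization.
* **Relative concentration (RC)** is computed from *normalized* buckets
  (the bucket intensity is already relative), as the mean over mapped
  peaks of (summed bucket intensity)/(proton count); peaks with no
  surviving bucket are skipped from the mean rather than scored zero, so a
  metabolite with peaks lost to solvent exclusion can still be scored.
* **Calibration and alignment** shift intensities by an integer number of
  grid steps (TSP apex to 0.0 ppm; then a global cross-correlation lag
  within ±0.05 ppm against the median spectrum). Sub-grid remainders are
  below half a step and are ignored so that all spectra stay on the common
  grid the bucket and deconvolution stages require. Per-region (segment)
  alignment is out of scope.
* **Deconvolution** solves non-negative least squares of the unit-sum
  normalized spectrum (solvent regions masked) against raw-scale
  templates, so coefficients are exactly concentration-proportional for
  noiseless library mixtures. Because the design matrix is fixed across a
  cohort, each sample's problem is reduced to metabolite space through a
  Cholesky factor of the Gram matrix before calling the active-set solver;
  the solution is identical and the per-sample cost drops by an order of
  magnitude. This quantifier is a deliberate simplification of full
  statistical deconvolution tools: there is no per-metabolite local
  warping and no detection thresholding (presence means "> 0", with the
  threshold exposed as a parameter).
* **Fingerprint library**: 17 metabolites follow the published duck-plasma
  evidence tables; proton counts per peak are curated from standard
  reference spectra because the tables print shift ranges and
  multiplicities only. Six further metabolites (glucose, glucuronic acid,
  glycine, proline, serine, valine) carry literature-based placeholder
  shifts (`source = "literature"`), chosen where possible to limit
  template collinearity with the table-sourced fingerprints; acceptance
  checks rely only on table-sourced entries.
* **Cross-validation folds** are contiguous blocks of a seeded shuffle —
  the exact fold assignment of commercial chemometrics software is
  proprietary, so the seed is part of the configuration and all reported
  Q² values are reproducible.
* **R²X** is computed on the Pareto-scaled matrix (the matrix the model
  actually sees).
* **Single-Y models**: LW and TY are fitted as separate PLS1 models, not a
  two-column PLS2; orthogonalized variants (O-PLS) are excluded because of
  their overfitting risk at these sample sizes. PCA is exported as a score
  table for visual outlier screening only; no automatic exclusion rule is
  applied.

## Known limitations

The bucket route identifies a metabolite through *any* of its mapped
buckets, so metabolites whose fingerprint ranges share buckets alias each
other: in the shipped library, xylitol and ethanolamine overlap sorbitol's
3.58–3.83 ppm region, and their RC scores inherit whatever signal lives
there. This is the same ambiguity that manual chemical-shift identification
faces, and it is why the end-to-end recovery gate in the test suite is
evaluated on the deconvolution route, which separates such metabolites by
their distinct line positions. The recovery cohorts plant a sparse set of
six biomarkers (lactate positive; alanine, glutamine, glycine, proline,
serine negative) at 1.0 SD: a sparse planted set mirrors the metabolite
route's reported outcome (8 biomarkers of 43 quantified metabolites) and
keeps "VIP > 1" meaningful — when nearly every variable in a small library
carries an equal planted effect, no variable can be much more important
than average and the VIP criterion is structurally unattainable.

Test and acceptance problem sizes are the package's own choices: permutation
validation is exercised at 100 permutations × 20 runs (500 permutations
remain the pipeline default), null-Q² calibration at 100 replicates of
n = 65, and end-to-end recovery on 20 cohorts of 65 animals.

## A short tour

```{r eval = FALSE}
library(gavageNMR)

report <- run_pipeline(run_config(seed = 1))
print(report)

# or stage by stage:
cohort  <- simulate_cohort(cohort_config(seed = 1))
lib     <- default_fingerprint_library()
spectra <- synthesize_cohort_spectra(
  cohort$ground_truth$concentrations[, names(lib$metabolites)], lib,
  seed = 1000)
spectra <- lapply(spectra, calibrate_to_tsp)
buckets <- normalize_buckets(bucketize_spectra(align_spectra(spectra),
                                               bucket_grid()))
conc    <- presence_filter(quantify_cohort(spectra, lib),
                           cohort$phenotypes)
```

The `inst/scripts/gavage.R` wrapper exposes `simulate` and `run`
subcommands for shell use; the exported functions above are the primary
interface.
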