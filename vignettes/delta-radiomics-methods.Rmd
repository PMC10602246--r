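---
title: "Quantifying radiation dermatitis from skin surface images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying radiation dermatitis from skin surface images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dermaradiomics)
```

## The problem

Acute radiation dermatitis — the erythema, darkening and pigmentation of
irradiated skin during breast radiotherapy — is routinely graded by eye on
ordinal clinical scales, which compresses a continuum of change into a
handful of categories and depends on the observer. An alternative is to
photograph the skin with a close-up capture device (a ~1 cm² field at
1624 × 1212 pixels, in *normal*, *polarized* and *UV* illumination modes,
sensitive respectively to surface pores/redness, basal-layer melanin, and
sub-surface melanin/sebum) and quantify texture change numerically.

`dermaradiomics` implements that quantification end to end: grey-level
co-occurrence matrix (GLCM) texture features inside a centred circular
region of interest, *delta-radiomics* ratios that normalize every feature
to the patient's own pre-treatment baseline, and the longitudinal
statistical harness that asks whether the treated breast changes more than
the untreated one, whether the change tracks the measured skin dose, and
whether early change predicts later change.

## Feature extraction

Each RGB capture is split into its three channels. Each channel is cropped
to a circular region of interest of radius `roi_radius` (default 300
pixels) centred at `((H-1)/2, (W-1)/2)` with an inclusive boundary — a
symmetric, enumerable rule; the crop also removes the vignetted periphery
that UV-mode optics produce. Intensities are quantized to `Ng` grey levels
(default 64) on the **fixed** range 0–255, `level = floor(v·Ng/256) + 1`.
We deliberately do not use per-image min–max scaling: delta ratios across
timepoints are only comparable if the intensity-to-level map is
time-invariant.

A symmetric GLCM is accumulated at displacement `d = 1` for each of the
four offset angles 0°, 45°, 90° and 135°, counting every ordered pixel
pair whose *both* ends lie inside the mask. Eighteen texture features are
computed per GLCM (autocorrelation, contrast, correlation, cluster
prominence/shade, dissimilarity, energy, entropy, homogeneity, maximum
probability, variance, sum average/variance/entropy, difference
variance/entropy, IMC 1, IMC 2), using natural logarithms and
`0·log 0 = 0` throughout. Features are averaged over the four angles, then
over the three channels — in that fixed order.

### Feature dialects

Widely circulated MATLAB GLCM code differs from the 1973 textbook
definitions in three centrings, and published feature tables produced with
it show the fingerprint: the *difference variance* row coincides exactly
with the *contrast* row, and the *variance* row tracks *autocorrelation*.
The package therefore implements two dialects:

* `matlab_toolbox` (default): difference variance `= Σ k² p_{x−y}(k)`
  (identically equal to contrast), sum variance centred on the *sum
  entropy*, variance centred on the mean of the matrix entries
  (≈ 0, so it tracks the second moment of the marginal).
* `haralick_1973`: difference variance is the variance of `p_{x−y}`, sum
  variance is centred on the sum average, variance on the marginal mean
  level.

On a constant (single-level) region the GLCM collapses to one cell;
correlation and IMC 1 are then undefined (zero marginal variance/entropy)
and are returned as `NA` with a warning. Degenerate angles are skipped in
averaging; a feature degenerate at every angle propagates as missing,
never as zero.

## Delta-radiomics

For every (patient, side, site, mode) series, `delta_ratios()` divides
each feature at each timepoint by the same series' value at the
pre-treatment baseline, which therefore emits exactly 1 (and summary cells
of 1.000 ± 0.000). Ratios are scale-invariant under any positive
per-series rescaling of the raw features — the property that makes them
comparable across patients with different baseline skin. A zero or missing
baseline makes the series' delta missing, never zero.

The four measurement points per breast are reduced to one value per breast
by an arithmetic mean (`aggregate_points()`), the least surprising
reduction given that published per-breast tables do not state one; the
per-point table is retained because the dose-correlation analysis is
naturally per point (each point has its own dose). Modes are analysed
independently throughout; deltas are never formed across modes.

## Statistical harness

* **Two-way repeated-measures ANOVA** (`rm_anova_two_way()`): both factors
  (time, 4 levels; side, 2 levels) are within-subject — both breasts of
  one patient are observed — so the classical univariate contrast
  decomposition applies: for each effect an orthonormal contrast matrix is
  applied to the per-subject cell means, `F` is the contrast-mean over
  residual quadratic form. Sphericity is checked per effect with
  Mauchly's `W` (chi-square approximation including the standard
  second-order term); if it rejects at 0.05 the Greenhouse–Geisser
  `ε = tr(S)²/(q·tr(S²))` rescales both degrees of freedom. A two-level
  effect has a single contrast, is spherical by construction, and gets
  `ε = 1` and no correction.
* **Paired comparisons** (`gated_paired_test()`): Shapiro–Wilk on each of
  the two samples; both normal at 0.05 → paired *t*, otherwise Wilcoxon
  signed-rank (zeros dropped, exact null up to 25 non-zero pairs without
  ties, normal approximation with tie and continuity correction beyond).
  The three post-baseline timepoints are judged against the Bonferroni
  threshold 0.05/3 = 0.0167. All-zero differences are degenerate and
  reported as `p = 1` with a flag. The gate is applied to the two samples,
  not their differences; every result records the branch taken.
* **Correlations** (`gated_correlation()`): Shapiro–Wilk gate on both
  variables; Pearson when both pass, Spearman otherwise. Dose–delta
  correlations use the measurement point as the analysis unit (dose and
  delta at the same site, pooled across patients); early-vs-late delta
  correlations use patient-level values on the treated side.
* **Multiplicity**: within each mode × analysis family of 18 features,
  Benjamini–Hochberg step-up adjustment at a 5% false-discovery rate.
  Every Bonferroni-significant feature is necessarily BH-significant.

## The synthetic cohort generator

No public image data exist for this design (a prospective single-centre
cohort whose images were not deposited), so the generator is a first-class
module that emulates the *statistical structure* the analysis assumes:

* **Doses**: one draw per site per patient from
  N(253.1, 14.7²), N(247.8, 18.1²), N(212.4, 19.6²), N(226.8, 23.5²) cGy
  (upper/lower/inner/outer), truncated at zero — the published cohort
  means. Doses are sampled once per patient (a first-fraction
  measurement) and reused at all timepoints.
* **Base texture**: per (patient, side, site, mode), a smooth Gaussian
  random field (FFT convolution, correlation length 6 px, SD 10 intensity
  units) around the per-mode mean intensity (normal 150, polarized 140,
  UV 90), plus 2% dark "pore" speckle at depth 40. The base field is
  *identical across timepoints*, so only injury-driven change alters the
  texture.
* **Injury**: severity `s = w(t)·dose/235` on the treated side and
  `s = γ·w(t)` (dose-independent, γ = 0.25 by default) on the untreated
  side; the rendered image is
  `base − κ_dark·s − κ_het·s·blotch` (κ_dark = 30, κ_het = 20; `blotch` a
  second fixed smooth field), clipped to [0, 255]. Darkening drives the
  level-location features down (autocorrelation, variance, sum average,
  sum variance); the blotch term spreads the co-occurrence mass, lowering
  energy and raising entropy/contrast — the directions observed on treated
  breasts.
* **Severity profiles** `w(t)` default to monotone increase for all three
  modes — (0, 0.5, 1.0, 1.2) normal, (0, 0.4, 0.8, 1.0) polarized,
  (0, 0.6, 1.2, 1.5) UV (UV changes are the largest, as observed). A
  peaked normal-mode profile was considered, since some normal-mode
  features peak mid-course in published data, but under a single severity
  scalar a peaked profile cannot simultaneously give the monotone energy
  decline that is the normal mode's headline pattern; monotone profiles
  are the default and any profile can be supplied per mode.
* **Determinism**: a single master seed; every image and dose draw derives
  a sub-stream seed by hashing its metadata tuple, so a cohort is
  bit-reproducible and any single image can be regenerated alone.

γ has no published anchor (contralateral scatter dose was not measured);
it is a free simulation parameter chosen so the untreated side shows a
clearly attenuated echo, as reported.

### What passing tests do and do not show

The generator produces stationary Gaussian textures with a linear
dose–severity link and no registration error, illumination drift,
specular highlights, hair, or inter-visit repositioning. Tests passing on
it validate the *pipeline* — counting rules, formulas, gating logic,
calibration of the tests under their nulls, and the qualitative
dose/time/side pattern — not the clinical performance of any feature on
real skin.

## Problem sizes and numerical choices

The test-suite and end-to-end checks run the generator at 96 × 96 pixels
with a 40-pixel ROI (the full 1624 × 1212 geometry with a 300-pixel ROI
remains the default and is exercised dimensionally); texture statistics at
Ng = 64 are well populated already at ~5,000 in-mask pixels, and a 20-patient
cohort (1,920 images) processes in well under a minute. Monte-Carlo
calibration of the tests uses 2,000 null replicates at n = 20. Other
numerical choices: `imc2`'s radicand is clamped at zero against rounding;
Mauchly's `W` is floored at the smallest double before the log; ties in
Spearman use the asymptotic tie-corrected test; Wilcoxon zeros are dropped
(classic convention) and the choice is recorded in the result object.

## Known limitations

* The point-to-breast aggregation rule (mean over four sites) is a
  convention; treating points as the analysis unit is available where it
  matters (dose correlations) but per-breast tables always use the mean.
* The feature set is the 18 GLCM features only — no run-length, size-zone
  or shape families, no multi-displacement GLCMs.
* The RM-ANOVA assumes a complete balanced grid; missing cells must be
  handled upstream (the pipeline excludes series without a baseline and
  logs them).
* Entropy-family deltas depend on the logarithm base; the natural log is
  pinned throughout.
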