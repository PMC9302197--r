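---
title: "CT-based lean body mass for SUL: models, calibration, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CT-based lean body mass for SUL: models, calibration, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sulct)
```

## The problem

The standardized uptake value (SUV) normalizes a PET tissue activity
concentration by the injected dose per kilogram of total body mass:

$$\mathrm{SUV} = \frac{C\ (\mathrm{kBq/ml})}{D\ (\mathrm{MBq}) / M\ (\mathrm{kg})}$$

with the convention that 1 ml of tissue weighs 1 g, so SUV carries units of
g/ml. FDG accumulates almost entirely in lean tissue, so two patients of
identical weight but different body composition receive the same injected
dose yet show different SUVs for the same physiology. Normalizing by lean
body mass instead (SUL = SUV x LBM / TBM) removes that dependence --
provided LBM itself is measured rather than predicted. Height-weight
prediction equations (James; Janmahasatian) were calibrated on young
healthy adults and systematically overestimate LBM in oncology cohorts,
whose composition ranges from cachexia to sarcopenic obesity.

A single axial CT slice at the third lumbar vertebra (L3), available for
free in every PET/CT study, supports a patient-specific alternative: the
skeletal muscle cross-sectional area (SMA) at L3 is linearly related to
whole-body lean mass as measured by DXA,

$$\mathrm{LBM}_{CT} = 0.30 \times \mathrm{SMA} + 6.06 \ \mathrm{kg},$$

and muscle is identified on CT by a fixed attenuation window of
$[-29, +150]$ HU (adipose tissue: $[-190, -30]$ HU).

This package implements that pipeline -- segmentation, LBM conversion, the
two prediction equations, SUV/SUL quantification, and the Bland-Altman
agreement analysis used to compare methods -- together with a synthetic
cohort-and-phantom generator so that every stage can be validated against
known ground truth.

## Key parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| muscle HU window | [-29, 150] | HU | closed threshold window for skeletal muscle |
| fat HU window | [-190, -30] | HU | conventional adipose window |
| SMA-to-LBM slope | 0.30 | kg/cm^2 | DXA calibration of the L3 regression |
| SMA-to-LBM intercept | 6.06 | kg | idem |
| VOI radius | 15 | mm | spherical liver reference region |
| half-life | 109.77 | min | F-18; configurable per nuclide |
| z | 1.96 | -- | limits-of-agreement quantile |
| conf | 0.95 | -- | CI level (Student t, n-1 df) |

The slope deserves a note. Printed statements of the L3 regression
sometimes carry the coefficient as 0.03, but only 0.30 kg/cm^2 is
consistent with the DXA calibration and with published cohort tables
(0.30 x 162.3 + 6.06 = 54.8 kg at the mean male SMA; 0.03 would imply a
10.9 kg lean mass for an 82 kg man). The default is therefore 0.30 and
both coefficients are user-configurable in `lbm_from_sma()` and
`study_config()`.

Both HU windows are closed intervals: a pixel at exactly -29 or +150 HU
counts as muscle. Thresholding is exact set membership, verified in the
test suite against a brute-force per-pixel oracle; connected-component
cleanup (8-connectivity) is available via `min_component_px` but disabled
by default, since in clinical practice stray components are removed by a
human editor, not a size filter.

## Units and conventions

`lbm_james()` takes height in centimetres and `lbm_janma()` needs metres
internally; the API accepts a single canonical height in centimetres and
converts, and a plausibility guard (100-250 cm) rejects metre-valued
heights outright -- the classic unit bug with these equations produces LBM
values off by an order of magnitude, and we prefer an error to a silently
absurd number.

The injected dose is decay-corrected to acquisition start
(`decay_correct()`, exact half-life law); residual syringe activity is
ignored. VOI extraction uses centre-in-sphere voxel inclusion with the
boundary included -- simple, standard, and testable against enumeration --
rather than partial-volume weighting.

Bland-Altman conventions: differences are test minus reference; the
limits of agreement use the fixed quantile z = 1.96; the standard error
of a limit of agreement is $SD\sqrt{1/n + z^2/(2(n-1))}$; and all
confidence intervals (bias and LOA) use a Student t quantile with n-1
degrees of freedom. This combination is the only one that reproduces,
cell for cell to within +-0.02 kg, the published agreement tables whose
(bias, SD, n) triples the acceptance tests replay. Sample SDs always use
the n-1 denominator. In ratio summaries (equation/CT), ratios exactly
equal to 1 belong to neither the over- nor the under-estimation partition
and are reported separately as ties, since strict inequalities leave them
undefined.

## The synthetic cohort

No patient-level data ships with the package; instead `simulate_cohort()`
draws cohorts calibrated to the per-sex summary statistics of a
consecutive adult oncology population:

* Height is truncated normal (men 175 +- 7 cm on 155-200; women 162 +- 7
  on 143-190). Heights are not part of the published summary; these are
  ordinary adult values chosen once.
* BMI is truncated normal (men 27.0 +- 5.4 kg/m^2 on 17.6-44.5; women
  26.0 +- 6.1 on 14.7-47.3) and weight is derived as BMI x height^2, which
  reproduces the published weight mean and range without inventing a
  joint height-weight distribution.
* SMA is drawn conditionally on weight through the bivariate-normal
  decomposition `SMA = a + bW + e` with `b = r sd_SMA / sd_W`, calibrated
  so the SMA marginal matches its published moments and the squared
  correlation with weight matches the published r^2 (0.32 men, 0.22
  women). This is the only correlation structure identifiable from
  marginals plus r^2.
* Fat cross-sectional area is drawn independently (no fat correlation is
  published), and injected activity is exactly 5.2 MBq/kg with a uniform
  50-70 min uptake interval.

Two numerical choices matter here. First, truncated-normal sampling is
*moment-matched*: `rtnorm_moments()` solves for the underlying location
and scale such that the *truncated* distribution has the configured mean
and SD. Plain truncation of N(mean, SD) would deliver an SD up to ~9%
too small when a bound sits within two SDs of the mean (the male BMI
lower bound does), and the calibration targets are statements about the
delivered moments. Sampling is by rejection, which preserves bit-level
determinism under a fixed seed. Second, the truncation bounds applied to
the conditional SMA draw are plausibility limits at mean +- 4 SD rather
than the published min-max: a published range is the sample range of
~100 patients, not distribution support, and truncating at it shrinks
the SD by ~7% and biases the correlation. With wide bounds, simulation
at n = 10^4 recovers every configured mean and SD within 2% and the male
SMA-weight r^2 within [0.29, 0.35].

## The phantoms

`generate_l3_phantom()` paints an elliptical body on an air background
with a vertebral bone disk, four muscle-group blobs grown to an *exact*
pixel count (`round(area / pixel_area)`, so painted area matches the
request to within one pixel's area), a subcutaneous fat ring, and
residual soft tissue deliberately placed in a -260 to -210 HU band so it
falls in neither tissue window. The geometry is schematic, not
anatomical: ground-truth labels are carried alongside the slice, so
segmentation accuracy is always assessed against known labels and no
claim rests on anatomical realism. What passing phantom tests *do* show
is that windowing, area conversion, and unit handling are exact; what
they do not show is robustness to partial-volume mixing, contrast,
motion, or anatomic ambiguity at the muscle-organ interface, which the
phantoms do not model.

`generate_liver_phantom()` builds an ellipsoidal liver (about 25,000
voxels at 2 mm spacing) at a target activity concentration with additive
Gaussian voxel noise over a zero background, truncated at zero because
concentrations are physical; at the default signal-to-noise (5.0 +- 0.5
kBq/ml) the truncation never triggers, so the mean-recovery check
(within 3 SEM of the target) is unbiased. PET acquisition physics --
randoms, scatter, attenuation, reconstruction -- is out of scope by
design.

## The end-to-end run

`run_study()` chains cohort -> phantom -> segmentation -> LBM -> SUV/SUL
-> agreement deterministically from one seed; per-patient sub-seeds are
drawn from a dedicated stream so adding a patient does not reshuffle the
others' phantoms. Patients whose segmentation stage fails are excluded
and counted (`n_input = n_analyzed + n_excluded` always), mirroring how
clinical cohorts exclude patients whose liver cannot be measured. Each
patient's true liver uptake is drawn around a configurable SUL-scale
level (default 2.0 +- 0.2, an ordinary normal-liver value) and converted
to an activity concentration through that patient's decay-corrected dose
and weight, so SUV recovery is an implicit cross-check of the whole
dose-weight-concentration bookkeeping.

The default phantom rasters in `run_study()` are 256 x 256 pixels at
2 mm (CT) and 48 x 48 x 40 voxels at 2 mm (PET). At 2 mm the painted-area
discretization error is at most 0.04 cm^2 -- two orders of magnitude
below the SD of any cohort SMA -- while a full ~200-patient study runs in
seconds. The test suite uses n = 10^4 draws for moment-recovery checks
and 100 random phantoms for the segmentation oracle; these sizes were
chosen so that every statistical tolerance (2% on moments, 3 SEM on
recoveries) is comfortably discriminating.

`equation_offset_kg` adds a known constant to both equation channels
before the agreement analysis. It exists purely for parameter recovery:
inject +6 kg, and the recovered Bland-Altman bias CI must cover it. This
is the package's strongest self-check, because it exercises cohort
generation, segmentation, the LBM regression, and the agreement engine
in one assertion.

## Degenerate inputs and tie-breaks

* An empty segmentation mask yields area 0 with a warning, not an error;
  an empty slice is an error.
* `bland_altman()` on identical vectors returns bias 0 and LOA [0, 0];
  fewer than 3 pairs is an error.
* `ratio_summary()` ties (ratio exactly 1) are reported separately.
* LBM above body weight triggers a warning in `sul()` but computes: the
  weakly coupled synthetic SMA-weight model can legitimately produce
  such patients, and real sarcopenic-obesity extremes make the guard a
  warning rather than an error.
* Between-sex p-values use Welch's two-sample t-test; published cohort
  tables rarely name their test, so these are provided for orientation,
  not reproduction.

## Known limitations

The phantoms are schematic (see above); the fat-mass-in-kg conversion
from fat area has no published calibration and is deliberately not
defaulted -- only fat cross-sectional area is reported. DICOM input is
not supported in this version (no rescale-calibrated DICOM reader
dependency); NIfTI and in-memory rasters are. Whether clinical SUVs are
decay-corrected to injection or acquisition time varies by site; the
half-life and elapsed-time arguments make either convention expressible,
with acquisition-start correction as the default.
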