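---
title: "Smartphone-style TLC densitometry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Smartphone-style TLC densitometry: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tlcscreen)
```

## The measurement model

On an F254 silica plate under short-wave UV, the fluorescent indicator
emits green light and a UV-absorbing analyte quenches it, so each spot
is a local deficit in the green channel of an RGB photograph. The
package models a cropped plate image as

green(r, c) = background + illumination gradient − Σ spots + noise,

and quantifies a spot by the sum of the inverted, min-max-normalized
green signal over its detected footprint (its AUC). Two quantities are
derived from the detected spots:

* **identity** — the retention factor Rf = d_spot / d_front, with both
  distances measured in pixel rows from the origin line to the spot's
  moment centroid and to the solvent front, respectively; a sample is
  accepted as the reference compound when its Rf deviates from the
  standard's by at most 10 % (relative, boundary inclusive);
* **quantity** — a straight-line calibration AUC = S·C + b fitted by
  ordinary least squares to a standard ladder, inverted as
  C = (AUC − b)/S, and scaled to per-tablet content by the dilution
  factor (125 mL by default: one tablet into 25 mL, then a 5-fold
  dilution to the 4 mg/mL working solution). Content within ±10 % of
  the label claim (450–550 mg for a 500 mg claim, boundaries inclusive)
  passes; otherwise the sample is substandard.

The model's key assumptions are that spots are approximately radially
symmetric (so the moment centroid estimates the migration distance),
that quench depth is proportional to the amount of analyte over the
calibrated range, and that every image being compared was cropped and
lit comparably (see *Normalization couples images*, below).

## The pixel pipeline and its parameters

`run_pipeline()` chains, in order: green-channel extraction (÷255),
min-max inversion, Gaussian smoothing, grayscale dilation, thresholding,
and 8-connected contour detection. The unusual order — dilation *before*
thresholding — follows the mobile-app chain this package mirrors; a
`dilate_before_threshold = FALSE` switch reorders it for
experimentation. AUC is always measured on the pre-blur
inverted-normalized image, so smoothing and dilation affect *where* a
spot is found, never *how much* signal it contains.

| parameter | default | units | role |
|---|---|---|---|
| `blur_kernel` | 5 | px | Gaussian kernel width (odd); suppresses sensor noise |
| `sigma` | 0 → 1.1 | px | 0 derives σ = 0.3·((k−1)/2 − 1) + 0.8 from the kernel width |
| `dilation_kernel` | 16 | px | moving-maximum window; merges a spot's speckled core into one component |
| `threshold_method` | `"otsu"` | — | `"otsu"`, `"fixed"`, or `"background"` |
| `background_offset` | 0.05 | signal | margin above the median for the `"background"` method |
| `max_foreground_frac` | 0.25 | — | sparsity guard: more foreground than this ⇒ featureless crop, empty mask |
| `min_spot_area` | 50 | px | noise-component floor at the reference height, scaled by (H/400)² |
| `standard_height` | 400 | rows | crops are resampled here so AUC units are stable across photographs |

Numerical conventions worth knowing:

* Coordinates are 1-based with row 1 at the top, matching R matrices;
  the solvent front row is therefore *smaller* than the origin row.
* The even 16×16 dilation window has no centre pixel; the window spans
  offsets −8..+7 around the anchor in both axes. Borders are replicated
  for dilation and mirrored (reflect-101) for smoothing.
* Thresholding is inclusive: pixels *equal to* the threshold are
  foreground.
* Otsu's threshold is selected by exhaustive maximization of
  between-class variance over 256 uniform bins; ties take the smallest
  candidate. On histograms with an empty gap between modes any
  threshold in the gap is equivalent — cross-checks against other
  implementations should compare classifications, not threshold values.
* Degenerate inputs are handled explicitly: a constant image
  min-max-normalizes to all zeros with a warning, Otsu on a flat image
  falls back to threshold 1.0 (empty mask), and an empty mask yields an
  empty spot list, which `analyze_plate()` reports as `identity_fail`
  rather than an error.
* The Rf identity test adds a 10⁻⁹ slack to the relative-deviation
  comparison so that a sample at exactly 110 % of the standard remains
  inside the inclusive boundary under floating-point rounding.
* Ties in principal-spot selection go to the larger AUC, then larger
  area, then the spot nearer the solvent front; spot lists are sorted
  by centroid column, then row.

## Why three threshold methods

Otsu's criterion is the parameter-free default and behaves well when
the spots on a crop have comparable intensity — the screening case,
where a standard and samples near the nominal concentration sit side by
side. It fails in a specific, reproducible way on crops whose spots span
a wide dynamic range, such as a 0.5–4 mg/mL calibration ladder: with a
tight background mode holding ~95 % of the pixels and spot intensities
spread over a decade, the between-class variance is maximized by a
threshold that sacrifices the faintest spots (on synthetic ladders it
lands near 0.35, dropping the 0.5 and 1 mg/mL lanes). The
`"background"` method addresses exactly that geometry: because spots
are sparse, the image median estimates the background floor, and the
threshold floor + `background_offset` retains every spot that clears
the noise band. Ladder-style crops (`calibrate_image()`, the
`calibrate --image` subcommand) therefore default to `"background"`;
`"fixed"` remains for full manual control.

Data-driven thresholds share one pathology: on a featureless crop they
will split the noise distribution and "find" structure covering roughly
half the image. The sparsity guard (`max_foreground_frac`) catches
this — real plates yield a few percent foreground, noise-only crops
~40 % — and returns an empty mask with a warning.

## Normalization couples images

Min-max normalization rescales every image by its own extremes, so the
AUC scale of a photograph depends on its darkest spot and on the
brightest noise excursion. Two consequences drive the package's
recommended workflow:

1. **Calibrate and measure on comparable images.** Absolute AUCs are
   only transferable between images whose content and noise are alike.
   The safest design — used throughout the tests — is per-plate
   self-calibration: spot the standard ladder beside the samples on the
   same plate, fit the calibration from the ladder lanes, and predict
   the sample lanes from the same pipeline run.
2. **The calibration intercept absorbs the baseline.** With noise, the
   global maximum sits a few noise SDs above the background mean, so
   every background pixel inside a contour contributes a small positive
   offset to the AUC. No local background subtraction is applied; the
   intercept of the fitted line absorbs this term, which is also why
   realistic calibrations here (and in the mobile app this mirrors)
   carry intercepts far from zero. The residual, area-dependent part of
   the baseline makes the response slightly concave, which is the main
   reason inverse predictions are most accurate near the top of the
   calibrated range — where screening samples live.

## Calibration statistics

`tlc_calibration()` is a classic fit-object interface (print, summary,
coef, predict, plot, residuals). The residual SD uses n − 2 degrees of
freedom (the regression residual variance), and the limits follow
LoD = 3.3·s_y/S, LoQ = 10·s_y/S, so LoQ/LoD = 10/3.3 by construction.
Inverse predictions below zero are clamped to zero with a warning;
predictions outside the calibrated range either warn (default) or are
rejected as out-of-calibration, per `extrapolation_policy`. All QC
statistics use the sample (n − 1) standard deviation, and the
two-method agreement test is a fixed-effects one-way ANOVA (equivalent
to a pooled two-sample t-test), with F defined as 0 when both groups
are constant and equal.

## What the synthetic plates emulate — and what they do not

`render_plate()` draws subtractive Gaussian quench spots (depth =
`amplitude`, spatial σ = `sigma_px`) on a uniform green background with
optional linear illumination gradient and i.i.d. Gaussian pixel noise,
then clips to [0, 1] and quantizes to 8 bits *before* the pipeline runs,
so tests exercise the same precision regime as real photographs. The
manifest records exact centroids, Rf and the analytic AUC
2π·amplitude·σ², both raw and divided by the plate's noiseless min-max
range (the convention of the normalized signal the pipeline integrates).

Defaults were fixed once as the study conditions: 640×400 px crops (the
pipeline's standard height), background green 0.70, spot σ 8 px, quench
amplitude 0.149 per mg/mL (gain 60 raw-AUC units per mg/mL across the
0.5–4 mg/mL ladder), pixel noise SD 0.01 — a realistic noise floor for
8-bit smartphone frames — and no gradient unless a test asks for one.
Sample lanes in end-to-end runs are drawn at 3.3–4.15 mg/mL, i.e.
tablets at 80–104 % of the label claim prepared at the nominal 4 mg/mL
working solution, matching the content range of a typical pharmacy
survey.

The renderer deliberately omits perspective distortion, lens vignetting,
JPEG artifacts, plate texture, band broadening with migration distance
(available but off), and tailing/fronting spot asymmetry. Passing tests
therefore demonstrate that the pipeline's geometry, normalization,
detection and calibration logic are correct under controlled optics;
they do not certify performance on poorly lit or skewed photographs,
which is why the CLI keeps per-stage debug images and a fixed-threshold
override for field material.

## Problem sizes in the tests and acceptance script

The test suite and `scripts/acceptance.R` were sized to be thorough yet
quick: oracle equivalence of dilation (brute-force windowed maximum) and
Otsu (exhaustive between-class-variance search) on 10–20 random 64×64
images; end-to-end recovery on 100 independently seeded ladder+sample
plates (observed: |Rf error| ≤ ~0.002 against a 0.02 requirement,
concentration error ≤ ~3.5 % against 5 %); 500 Monte-Carlo calibration
fits for slope bias (< 0.2 % observed against a 2 % bound); and exact
(to floating point) checks of the limit formulas and noiseless inverse
prediction. The whole suite runs in well under a minute on one CPU.

## Known limitations

* Global thresholding assumes roughly uniform illumination; strong
  gradients call for flat-field correction upstream, which is out of
  scope.
* Lanes are recovered by 1-D clustering of centroid columns, so
  severely overlapping lanes (gap below `gap_threshold`) merge.
* The AUC is threshold-dependent through the detected footprint; mixing
  threshold methods between calibration and measurement of the same
  material introduces a systematic offset and should be avoided.
* Quantitation warns, rather than refuses, below the LoQ; screening
  decisions near the limits deserve confirmation by an orthogonal
  method (the usual practice being HPLC).
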