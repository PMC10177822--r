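---
title: "Objective CT image quality: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Objective CT image quality: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctiq)
```

`ctiq` quantifies the image quality of a CT slice with three observer-independent
measurements — edge sharpness across a marked tissue border, local image noise,
and the derived SNR/CNR — plus radiation-dose normalization and the
reader-agreement statistics used alongside them in reading studies. This
vignette is the package's account of the underlying models, the tunable
parameters, the numerical choices, and the limits of what the synthetic
validation shows.

## The measurement model

A CT slice is a raster of Hounsfield units with isotropic pixel spacing
(`ct_slice`). Coordinates are in mm from the centre of the top-left pixel,
rows run downward, and angles are counter-clockwise from +x.

**Edge sharpness.** The object of interest is the gray-value transition across
a soft-tissue interface, modelled as a piecewise-linear profile: a bright
plateau (muscle, ~50 HU), a linear ramp, and a dark plateau (fat, ~-100 HU).
Given a border marking (`border_spec`: a segment plus a +/-4.5 mm lateral
scope), `extract_profiles()` places ten stations evenly along the segment and
samples the image by bilinear interpolation along each perpendicular. Profiles
are oriented bright-to-dark, so position 0 is on the marking and the brighter
tissue sits at negative positions; transition slopes are therefore negative.
Per profile, `estimate_baselines()` averages the outermost quarter of each
half-range (far from the transition), and `steepest_slope()` takes the most
negative least-squares slope over every window of three consecutive samples.
Medians over the ten profiles summarize the border; the median is used rather
than the mean because single profiles can be corrupted by local texture.

**Noise.** `detect_edges()` masks transition pixels by thresholding the
central-difference gradient magnitude (HU/mm). `build_noise_map()` slides a
5 mm x 5 mm window (stride one pixel) over the slice; windows containing a
masked pixel are skipped; in each remaining window a full second-order 2D
polynomial is fitted by least squares and subtracted — this removes
low-frequency drifts (shading, smooth anatomy) so only stochastic texture
remains — and the residual SD is recorded. `estimate_noise()` takes the
smallest value in the map as the image noise. `select_homogeneous_region()`
implements the complementary search for the most homogeneous raw-SD window;
it is used to localize the measurement near the profiles, while the noise
value itself always comes from the map minimum.

**Ratios.** SNR = upper baseline / noise and CNR = (upper - lower) / noise,
computed from the median baselines and the map-minimum noise by
`evaluate_image()`, which also carries the full provenance (border, parameters)
in its report.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `n_profiles` | 10 | — | stations along the marking |
| `half_range_mm` | 4.5 | mm | profile reach to each side |
| `step_mm` | spacing/2 | mm | profile sampling step; half the pixel pitch resolves the bilinear field everywhere (Nyquist-safe) |
| `plateau_fraction` | 0.25 | — | outer fraction of each half averaged as baseline; excludes the transition while keeping ~20+ samples |
| `gradient_threshold_hu_per_mm` | 50 | HU/mm | edge mask threshold: well below soft-tissue interface slopes (100–170), well above the gradient noise floor of a few-HU noise field at sub-mm spacing |
| `window_mm` | 5 | mm | noise window side; converted to `round(window_mm/spacing)` px, forced odd and >= 3 |
| `stride_px` | 1 | px | dense sliding evaluation |
| `dof_correct` | FALSE | — | residual SD denominator `n-1` (plain SD of detrended values) vs `n-6` (fit dof) |
| `reference_length_cm` | 25 | cm | DLP normalization length |
| `k` | 0.0058 | mSv/(mGy·cm) | head/neck effective-dose factor; `icrp_k_factors()` lists alternatives |

## Numerical and design choices

- **"Three points" slope.** The steepest slope is read over three consecutive
  resampled profile points via least squares; for equispaced points this is
  `(v3 - v1)/(2h)`. Three-point windows are the finest uniform reading of the
  transition and give an exact result on a linear ramp; the flip side is noise
  amplification (the per-window slope SD is `sigma/(h*sqrt(2))`), which biases
  the minimum over windows steeper. On phantoms with 5 HU noise the median
  bias stays under 15%, and it cancels in comparative use (the steeper edge
  always measures steeper; tested over paired seeds).
- **Distance.** The signed span of the winning three-point window (`-2h`) is
  reported as the transition distance, negative like the slope. Ties between
  equal minimum slopes resolve to the window centre nearest the marking, then
  first occurrence, so results are deterministic.
- **Minimum-of-map noise.** The minimum over thousands of overlapping window
  SDs is a biased-low estimator of sigma: on 200 x 200 px white-noise fields it
  averages ~0.74 sigma (and ranges roughly 0.65–0.78 over seeds). The package
  keeps the minimum as the headline value because that is the established
  reading of the noise-map procedure, and exposes the spread via
  `noise_bias_note()` (map median and 90th percentile next to the minimum).
  Consequently SNR/CNR computed from the map minimum overshoot the analytic
  `signal/sigma` ratios by the inverse factor; comparisons between images
  processed identically are unaffected.
- **Residual SD denominator.** The default `n-1` denominator is a plain SD of
  the detrended gray values and under-corrects for the 6 fitted coefficients
  (about 2% low for an 11 x 11 window); `dof_correct = TRUE` switches to `n-6`.
- **Rasterization limit.** A raster cannot represent an edge steeper than its
  pixel pitch allows: when the true transition width falls below two pixels,
  the recoverable slope saturates at `contrast/(2*spacing)` (e.g. -159.9 HU/mm
  at 0.469 mm spacing for a 150 HU contrast). Recovery is exact in every
  resolved configuration; the saturation is a property of the sampling, not of
  the estimator.
- **Degenerate inputs.** A noise-free image produces a numerically zero map
  minimum (below 1e-9 HU); `evaluate_image()` raises a degenerate-input error
  rather than returning an infinite SNR. Constant profiles are flagged
  `no_transition`, profiles whose bright side is not brighter are flagged
  `inverted_or_flat`, zero between-item variance flags the ICC as undefined,
  and two constant identical raters flag kappa as undefined (p_e = 1).
- **ICC form.** "Two-way mixed effects, consistency" is implemented as the
  single-rater ICC(3,1); the average-measure ICC(3,k) is available via
  `average = TRUE`. The printed agreement bands leave the 0.75–0.76 gap
  ambiguous; the package resolves it as good iff ICC >= 0.755. The ANOVA
  mean squares are computed by direct summation and are cross-checked against
  `stats::aov` in the tests to 1e-10.
- **Mann–Whitney.** Exact enumeration of all group assignments (ties included)
  when both samples have at most 8 observations, tie-corrected normal
  approximation otherwise, two-sided via the symmetric distance from the null
  mean. The package also notes that for paired reading scores a signed-rank
  test would be the matching design; the unpaired form is provided because it
  is the one conventionally reported alongside these image-quality tables.
- **KS normality.** The screen tests against a normal with the sample's own
  mean and SD, which makes the classical p-value conservative (Lilliefors
  effect); `ks_normality(x, method = "lilliefors")` applies the corrected
  test. `describe_sample()` reports both mean±SD and median/[Q1, Q3]
  (type-7 linear-interpolation quantiles) plus which one the screen selects.
- **Dose arithmetic.** `normalize_dlp()` recomputes DLP at a reference length
  (`CTDIvol x L_ref`), `effective_dose()` applies k, and reported values are
  rounded half away from zero only at output (`round_half_up()`), reproducing
  printed tables from exact arithmetic: CTDIvol 10 mGy at 25 cm gives
  250 mGy·cm and 1.45 mSv; 349.8 mGy·cm gives 2.03 mSv; the reduction from
  2.03 to 1.45 mSv rounds to 29%.

## What the phantoms emulate — and what they do not

`generate_edge_phantom()` emulates exactly the structure the estimators
assume: two homogeneous plateaus, a linear ramp of known slope, an optional
smooth second-order background drift, and i.i.d. Gaussian noise, rasterized by
evaluating the template at pixel centres (no area averaging). The interface
passes through the pixel centre nearest the raster centre so that, for
axis-aligned edges, the template knots land on the sampling lattice and
noiseless profile extraction is exact to interpolation tolerance — which is
what makes slope recovery an exact test rather than an approximate one.

Real CT slices differ in ways the phantom deliberately omits: noise is not
white (reconstruction kernels and deep-learning denoisers correlate it and
make it non-stationary), edges follow point-spread functions rather than ideal
ramps, anatomy adds structured texture that the second-order detrend only
partly removes, and partial-volume averaging smooths pixel values. Passing the
synthetic suite therefore demonstrates that the estimators are correct for
their stated model and calibrated under white noise; it does not certify
absolute accuracy on scanner data, where the noise-map minimum and the
three-point slope should be read as comparative, same-pipeline measurements.
Beam-hardening and streak artifacts, anatomical realism and 3D volumes are
out of scope.

## Problem sizes and reproducibility

The validation suite runs phantoms of 30–40 mm at 0.234–0.5 mm spacing
(64–170 px square), 100-seed Monte-Carlo loops for noise calibration on
200 x 200 px fields, and 50-seed paired ensembles for the slope-ordering
check; these sizes give Monte-Carlo errors well inside the asserted bounds
while keeping the full suite under a couple of minutes. All generators are
deterministic given their seed (`withr::with_seed`), and
`scripts/acceptance.R --seed N --out path` re-derives every headline quantity
from scratch.

## File formats

Slices travel as a raster plus a JSON sidecar carrying pixel spacing and the
linear HU mapping (the same rescale-slope/intercept convention DICOM uses).
The default `"raw"` raster is a float64 dump and round-trips bit-exactly; the
`"png"` option writes a viewable 8-bit export quantized to `hu_slope` HU per
stored unit. DICOM itself is not read or written. Rater scores and dose
records travel as header-validated CSV; reports as JSON with a configuration
hash for provenance.
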