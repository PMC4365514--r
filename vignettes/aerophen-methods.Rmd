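---
title: "aerophen: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{aerophen: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`aerophen` turns multi-sensor aerial frames of a maize trial — RGB, a
modified blue + near-infrared (B+NIR) vegetation camera, and thermal
infrared — into per-plot trait tables and trial-level statistics. This
vignette explains each processing stage, the assumptions behind it, the
parameters a user may need to touch, and the design decisions that were
genuinely open; the companion README shows the user-facing workflow.

## Coordinate conventions

All rasters are `H x W (x C)` arrays in (row, col, channel) order with
pixel centers at **integer 1-based (row, col) coordinates** — the
idiomatic R convention, used consistently across detection, homography
fitting, warping and plot rasterization. Rectangles and plot polygons are
half-open: a pixel belongs to a plot when its center lies strictly inside
the polygon. Optical channels are digital numbers rescaled to [0, 1]
(16-bit DN / 65535); thermal pixels are degrees Celsius. Pixels without a
valid pre-image after warping are `NA` and excluded from every downstream
statistic.

## Marker detection and co-registration

The field markers are round dark metal plates (Ø 0.70 m) on 2 m poles
around each field sub-array; in the thermal band they read *warmer* than
plants and soil, so detection runs with `polarity = "dark"` on the blue
channel of the optical sensors and `polarity = "bright"` on the thermal
channel.

Detection is threshold-based: blobs are extracted by intensity
thresholding, labelled (`EBImage::bwlabel`) and filtered by area (from
the expected marker radius), circularity (`4*pi*A/P^2 >= 0.6`, with the
perimeter counted as blob pixels having a 4-neighbour outside) and
solidity (area over convex-hull area, `>= 0.8`). The default threshold is
the *midpoint between the extreme-quantile intensity and the image
median*: the extreme quantile (sized by the area of one smallest expected
marker) lands inside the marker intensity population, the median
represents background, and their midpoint stays clear of background noise
tails — a pure quantile threshold can land inside the warm-soil noise
tail of a thermal frame and corrupt blob shapes. An explicit
`threshold_quantile` argument restores plain quantile thresholding.
Accepted blobs get sub-pixel centers from the contrast-weighted centroid,
which is exact for symmetric disks.

Detections are matched to the known AoI marker layout by cyclic order:
both point sets are centered, scale-normalized and sorted by angle, and
the cyclic shift with the smallest summed squared distance wins. This is
valid because the markers sit on the field perimeter and a mild projective
distortion cannot change their cyclic order; it would fail for markers in
general position, which the layout never produces.

The sensor-to-AoI homography is fitted by the normalized direct linear
transform (Hartley normalization, null vector of the normal matrix
`A'A`), exact for four correspondences and total-least-squares for more.
Three collinear points are rejected as degenerate only when exactly four
correspondences are supplied: with eight perimeter markers, collinear
triples along each field edge are *expected* and harmless, and a
conditioning check on the normal-matrix spectrum catches truly
rank-deficient sets. `warp_to_aoi()` inverse-maps the output grid through
`H` and resamples with the classical bicubic kernel (Keys, a = −0.5);
thermal frames are first up-scaled to the optical resolution with
corner-aligned bilinear interpolation, which preserves constants exactly
and linear ramps to machine precision.

Normalized cross-correlation (`refine_by_ncc`) relocates a marker from a
template image in a search image by exhaustive integer-offset search;
ties break by smallest offset magnitude, then row-major order, and
zero-variance windows raise an undefined-correlation error. In the
orchestrated pipeline NCC serves as a *cross-sensor consistency check*
(B+NIR template vs RGB, warning above 3 px) rather than replacing
detections: the centroid detector is already sub-pixel accurate, and an
integer-offset relocation would discard that precision. Registration can
also be driven from a manual override CSV
(`campaign, sensor, marker_id, row, col`), the fallback when automatic
detection fails on a real frame.

## Segmentation

The vegetation camera defines a blue-band NDVI,
`(NIR − B)/(NIR + B)`, computed per pixel; pixels with `NIR + B = 0` are
invalid. Plant/soil separation is a two-step threshold: `NDVI > 0.1`
(strict — ties are soil) *and* grey reflection intensity (mean of the
rescaled B and NIR digital numbers) above a per-campaign threshold that
removes heavily shaded areas. The NDVI threshold of 0.1 is deliberately
permissive so that senescent leaves still count as plant; the band
`0.1 < NDVI <= 0.2` (`senescence_band()`) isolates predominantly
senescent material. The intensity threshold depends on the radiation
conditions of each flight and therefore has **no default**: the
configuration must state it per campaign (the simulator's default scenes
are calibrated for 0.2 on the [0, 1] intensity scale). For RGB frames an
HSB alternative thresholds hue, saturation and brightness jointly, with
brightness = max(R, G, B), hue in degrees and circular hue intervals.

## Per-plot traits

Plot polygons are rasterized by pixel-center containment; overlapping
polygons are an error naming the pair. Per plot: `cc` = plant fraction
among valid pixels; `ndvi_plot` / `ndvi_plant` = median NDVI over valid /
plant pixels (even-sized medians take the midpoint of the central pair;
the mean is available behind `aggregate = "mean"`); skewness uses
population moments exactly, `m₃/m₂^{3/2}`, errors on zero variance and is
recorded as `NA` per plot in that case. `t_c` is the median thermal
signal over *all* valid plot pixels — no thermal segmentation is
attempted because at 0.1 m ground pixels single leaves cannot be
resolved, so the plot signal is inherently a plant/soil mixture —
and `dt = t_c − air_temp` uses the single weather-station reading of the
campaign (no spatial interpolation; one on-site station). Plots warped
partially outside a source image keep their traits but are flagged
`low_coverage` below 80% valid pixels; zero-valid-pixel plots produce an
error record and the run continues.

## Trial statistics

For a balanced genotype × block stratum (one observation per cell) the
variance components come from the exact ANOVA method of moments with
block fixed and genotype random: `σ²_ε` is the residual mean square,
`σ²_gen = (MS_gen − MS_ε)/r` clamped at zero, and repeatability is
`h² = σ²_gen/(σ²_gen + σ²_ε/r)` with `r` the number of blocks found in
the data (4 in the reference design). For balanced data this matches the
REML mixed-model estimate in expectation while avoiding a heavyweight
dependency; unbalanced layouts are rejected with an explicit error rather
than silently approximated. Note that the *estimator mean* sits below the
plug-in ratio at small `σ²_gen/σ²_ε` (the clamp and the nonlinearity of
the ratio): direct sampling of the balanced mean squares puts the mean at
0.443 when the plug-in value is 0.5 (g = 16, r = 4, ratio 0.25) — the
test suite freezes those sampled expectations rather than the plug-in
values. `repeatability_profile()` applies the estimator per
campaign × plot-size stratum, omitting failing strata with a warning.

Pearson correlations use the t-distribution on n − 2 df with the
conventional significance codes (`***` < 0.001, `**` < 0.01, `*` < 0.05,
`ns`); the Tukey HSD is `q(1 − α, g, df_err) · sqrt(MS_err/r)` at
α = 0.05 with a compact letter display built by the insert-absorb rule on
decreasingly sorted means. With `σ²_ε = 0` the HSD degenerates to 0 and
every distinct pair separates, which is the intended limit.

## The synthetic scene generator

The simulator is the package's test bed and defines the study conditions:

* **Design**: 16 genotypes (6 hybrids, 5 dent and 5 flint inbreds,
  randomized in separate sub-blocks), the number of rows per plot (1–4)
  as whole-plot factor, 4 replicate blocks — 256 plots of 4 m length at
  0.75 m row spacing, laid out in three field sub-arrays (blocks 1+2, 3,
  4), each ringed by 8 markers.
* **Seasonal curves**: canopy cover rises logistically (hybrids close
  earlier and more completely than inbreds; closure near flowering at
  540 °Cd) and declines linearly after the senescence onset at 892 °Cd;
  plant NDVI follows the same shape at genotype-specific levels; `dT` is
  negative through the transpiring phase (−1 to −2 °C between 612 and
  940 °Cd) and positive at advanced senescence (1275 °Cd).
* **Variances**: per-trait genotypic and residual components, the
  residual divided by the plot row count — this 1/rows scaling is the
  generator's *modelling choice* for reproducing the observed
  plot-size → repeatability effect, not an empirical law.
* **Rendering**: each plot's canopy covers the leading `cc` fraction of
  the row length, with bare soil accumulating at the far plot end the way
  emergence gaps do along real rows. This choice keeps every soil feature
  several pixels wide at any `cc ≤ 0.97`; rendering the canopy as strips
  of width `cc × 0.75 m` instead leaves sub-pixel soil slivers at
  mid-season cover that bicubic warping washes out, biasing recovered
  cover beyond what threshold segmentation itself causes. Plant and soil
  NDVI draw from Normal(level, 0.05) and Normal(−0.05, 0.03); digital
  numbers are back-computed (`B = s(1−v)/2, NIR = s(1+v)/2`) so NDVI
  recovery is exact by construction. Ground pixels default to the sensor
  optics at 300 m altitude: 0.0285 m (RGB), 0.026 m (B+NIR, also the
  common AoI resolution) and 0.1 m (thermal). Each sensor image is
  displaced by a known random projective transform (≤ 0.5° rotation,
  ~1–2% trapeze) whose exact matrix is retained as ground truth.
* **Determinism**: one master seed; every module, campaign and sensor
  derives its own stream (`derive_seed`), so adding a campaign never
  perturbs earlier draws, and identical configuration reproduces
  bit-identical rasters, tables and output files.

What the generator does *not* emulate — and what passing tests therefore
do not demonstrate about real imagery: radiometric miscalibration and
exposure drift between campaigns, vignetting, motion blur, tassels
overlaying leaves (the mid-season cover dip), lens distortion beyond a
homography, soil moisture patterns, and marker soiling. The pipeline's
recovery accuracy on synthetic scenes is an upper bound, not a field
guarantee.

## Numerical choices and edge cases

* Boundary positions within 1e−6 px of the raster edge are clamped, not
  invalidated, so numerically-identity transforms reproduce their input
  exactly.
* The bicubic kernel uses a = −0.5 (Keys); border neighbourhoods clamp
  edge pixels.
* `fit_projective` normalizes both point sets to centroid 0 / mean radius
  √2 before the DLT; the homography is reported with `H[3,3] = 1` and a
  target-frame reprojection `rmse`.
* Marker scores are circularity values clipped to [0, 1]; detections sort
  by score, then blob contrast.
* Sixteen-bit quantization of rendered digital numbers (≤ 1/65535)
  propagates to NDVI errors below 1e−4 and is ignored.
* The thermal TIFF convention stores `(T + 50)/150` as 32-bit float
  (libtiff float samples outside [0, 1] are undefined in the writer
  used); two-channel B+NIR files are padded to three channels on disk
  because gray+alpha TIFFs are widely misread.
* Degenerate inputs error loudly and early: < 4 markers
  (`aerophen_registration_infeasible`, carrying the partial detection
  list for the manual-override path), zero-variance NCC windows,
  collinear 4-point sets, non-invertible transforms, unbalanced ANOVA
  layouts, `t_max < t_min` weather rows.

## Problem sizes used in the test suite

The suite exercises the full-resolution study conditions (0.026 m common
frame; sub-arrays of roughly 1960 × 820 to 1960 × 1540 px): unit tests
run on one sub-array, and the end-to-end acceptance path processes one
complete thermal campaign (three sub-arrays, 256 plots) twice to verify
byte-identical manifests. Statistical calibrations use 200–500 simulated
trials per case. On one CPU the whole suite completes in a few minutes.

## Known limitations

* The repeatability estimator is restricted to balanced strata by design;
  real trials with missing plots need a REML mixed model, which is out of
  scope here.
* Thermal traits are mixture signals; comparisons across genotypes with
  very different cover confound temperature and cover, which is why the
  trait table carries `cc` alongside `t_c` and `dt`.
* The marker matcher assumes perimeter placement; markers in the field
  interior could break the cyclic-order assumption.
* Per-campaign intensity thresholds must be supplied by the user for real
  data; no radiometric auto-calibration is attempted.
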