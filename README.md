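# aerophen

Aerial multi-sensor phenotyping of maize field trials in R.

Breeding research needs trait measurements on hundreds of field plots many
times per season, and aerial imaging is the only practical way to get them.
A low-altitude platform carrying an RGB camera, a modified blue +
near-infrared (B+NIR) "vegetation" camera and a thermal infrared camera can
photograph a whole trial in seconds — but turning those frames into
per-plot numbers requires a processing chain: finding the circular field
markers in every sensor's image, warping all sensors into one common
coordinate frame, separating plant from soil pixels, clipping out each
experimental plot, and summarizing the result per plot and campaign.
`aerophen` implements that chain end to end, together with the trial-level
statistics used to judge it and a seeded scene simulator that provides
pixel-level ground truth for validation.

## Method at a glance

* **Co-registration.** Dark circular markers (diameter 0.70 m, on 2 m
  poles around the field) are detected in the blue channel of the optical
  sensors and — because the metal plates emit more heat than plants or
  soil — as bright disks in the thermal image. Detected centers are
  matched to the known marker layout and a projective transform `H`
  (fitted by the normalized direct linear transform) maps each sensor into
  the common area-of-interest (AoI) frame using bicubic interpolation.
  Thermal frames are up-scaled to the optical resolution first. Normalized
  cross-correlation (NCC), with the B+NIR image as template, cross-checks
  marker consistency between sensors.
* **Segmentation.** The vegetation camera yields a blue-band NDVI per
  pixel, `NDVI = (NIR − B)/(NIR + B)`. A pixel is plant when
  `NDVI > 0.1` *and* its grey reflection intensity exceeds a per-campaign
  threshold (removing deep shade); the two masks are combined by
  multiplication. An HSB colour-space alternative is provided for RGB.
* **Per-plot traits.** Canopy cover `CC` (plant-pixel fraction),
  `NDVI_Plot` (median over all plot pixels) and `NDVI_Plant` (median over
  plant pixels only), the skewness of the pixel distribution
  `s = m₃ / m₂^{3/2}` (population moments), the canopy temperature `T_C`
  (median thermal signal — at 0.1 m ground pixels the thermal plot signal
  is an unsegmentable plant/soil mixture) and `dT = T_C − T_A` against the
  weather-station air temperature (negative `dT` = transpiration cooling).
* **Trial statistics.** For the balanced split-plot design (16 genotypes ×
  1–4-row plots × 4 blocks) repeatability is estimated per plot size as
  `h² = σ²_gen / (σ²_gen + σ²_ε / r)` with variance components from the
  exact balanced-ANOVA method of moments (block fixed, genotype random),
  plus Pearson correlations with `***`/`**`/`*`/`ns` codes and Tukey HSD
  genotype comparisons with compact letter displays.
* **Support calculations.** Sensor optics (IFoV = pixel pitch × altitude /
  focal length, ground footprint, motion blur, survey throughput) and
  weather quantities (thermal time above 8 °C, saturation vapour pressure,
  VPD, LAI from specific leaf weight).
* **Simulator.** `scene_config()` / `generate_design()` /
  `simulate_traits()` / `render_scene()` build a deterministic synthetic
  trial — genotype-specific seasonal curves, marker disks, known per-sensor
  projective distortions, per-pixel truth — on which the full pipeline is
  exercised and measured.

## Worked example

```r
library(aerophen)

# ground pixel of the B+NIR camera at 300 m altitude
compute_ifov(nir_sensor_spec(), 300)
#> [1] 0.02592247          # metres; 0.026 m after rounding

# thermal smear at 20 km/h with a 50 ms shutter and 0.1 m pixels
compute_motion_blur(flight_params(300, 20), 50, 0.1)
#> $blur_distance 0.278    # metres
#> $blur_pixels   3

# repeatability of a balanced 16-genotype x 4-block trial
d <- simulate_balanced_trait(16, 4, sigma2_gen = 3, sigma2_eps = 1, seed = 1)
estimate_components(d)
#> <variance_components> sigma2_gen 2.775, sigma2_eps 0.9556 (g=16, r=4), h2 = 0.921

hsd_compare(d)$hsd
#> [1] 2.506
```

`h2 = 0.921` says that 92% of the variance among genotype means is
genotypic — the criterion the pipeline uses to decide how many rows a plot
needs. The full image chain runs as:

```r
cfg <- scene_config(seed = 42)
res <- run_pipeline(cfg, out_dir = "run", campaigns = "c4")  # ~1 min
res$records                      # 256 plots x traits at flowering
```

A thin command-line wrapper with `geometry`, `simulate`, `run`, `env` and
`stats` verbs is installed at `inst/cli/aerophen.R`.

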