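#' Blue-band normalized difference vegetation index
#'
#' `NDVI = (NIR - B) / (NIR + B)` computed per pixel from the blue and
#' near-infrared channels of the vegetation camera. Pixels where
#' `NIR + B = 0` (or either channel is `NA`) are marked invalid (`NA`).
#' The index is invariant to a common positive rescaling of both channels,
#' so it can be computed on raw or rescaled digital numbers alike.
#'
#' @param b,nir Numeric matrices of non-negative digital numbers, same
#'   shape.
#' @param campaign_id Campaign label carried along.
#' @return An object of class `ndvi_raster`: list with `values` (matrix in
#'   `[-1, 1]` with `NA` sentinel) and `campaign_id`.
#' @export
compute_ndvi <- function(b, nir, campaign_id = "c1") {
  if (!all(dim(b) == dim(nir)))
    stop("blue and NIR rasters differ in shape", call. = FALSE)
  denom <- nir + b
  v <- (nir - b) / denom
  v[!is.finite(v) | denom <= 0] <- NA_real_
  structure(list(values = v, campaign_id = campaign_id),
            class = "ndvi_raster")
}

#' @export
print.ndvi_raster <- function(x, ...) {
  cat(sprintf("<ndvi_raster> %d x %d px, %.1f%% valid, campaign %s\n",
              nrow(x$values), ncol(x$values),
              100 * mean(is.finite(x$values)), x$campaign_id))
  invisible(x)
}

#' Segmentation configuration
#'
#' @param ndvi_threshold NDVI above which a pixel counts as plant
#'   (strictly greater; default 0.1, chosen so that green and senescent
#'   plant material are both included while soil is excluded).
#' @param intensity_threshold Grey-intensity threshold in `[0, 1]` used to
#'   drop heavily shaded pixels; radiation-dependent, so it is set per
#'   campaign.
#' @param hsb_ranges List with elements `h`, `s`, `b`, each `c(lo, hi)`
#'   (hue in degrees, may wrap past 360; saturation/brightness in
#'   `[0, 1]`), for the RGB colour-space alternative.
#' @param mode `"ndvi"` or `"hsb"`.
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(ndvi_threshold = 0.1,
                                intensity_threshold = NULL,
                                hsb_ranges = NULL,
                                mode = c("ndvi", "hsb")) {
  mode <- match.arg(mode)
  if (!is.finite(ndvi_threshold) || ndvi_threshold <= -1 || ndvi_threshold >= 1)
    stop("ndvi_threshold must lie in (-1, 1)", call. = FALSE)
  if (!is.null(hsb_ranges)) {
    stopifnot(all(c("h", "s", "b") %in% names(hsb_ranges)))
    for (nm in c("s", "b"))
      if (hsb_ranges[[nm]][1] > hsb_ranges[[nm]][2])
        stop(sprintf("hsb range '%s' has unordered bounds", nm), call. = FALSE)
  }
  structure(list(ndvi_threshold = ndvi_threshold,
                 intensity_threshold = intensity_threshold,
                 hsb_ranges = hsb_ranges, mode = mode),
            class = "segmentation_config")
}

new_segmentation_mask <- function(plant, valid, cfg) {
  plant[!valid] <- FALSE
  structure(list(plant = plant, valid = valid, config_used = cfg),
            class = "segmentation_mask")
}

#' @export
print.segmentation_mask <- function(x, ...) {
  cat(sprintf("<segmentation_mask> %d x %d px, plant fraction %.3f (%s mode)\n",
              nrow(x$plant), ncol(x$plant),
              sum(x$plant) / max(1, sum(x$valid)), x$config_used$mode))
  invisible(x)
}

#' Two-step plant/soil segmentation from NDVI and grey intensity
#'
#' A pixel is plant when its NDVI strictly exceeds the NDVI threshold
#' *and* its grey (reflection) intensity exceeds the per-campaign
#' intensity threshold; the two binary masks are combined by
#' multiplication. The intensity step removes heavily shaded areas whose
#' NDVI is unreliable. Invalid (`NA`) pixels are never plant.
#'
#' @param ndvi An `ndvi_raster` from [compute_ndvi()].
#' @param intensity Numeric matrix in `[0, 1]`: the monochrome reflection
#'   intensity, here the mean of the rescaled B and NIR digital numbers.
#' @param cfg A [segmentation_config()] with `mode = "ndvi"` and a set
#'   `intensity_threshold`.
#' @return A `segmentation_mask`: logical rasters `plant` and `valid` plus
#'   the config used.
#' @export
segment_ndvi <- function(ndvi, intensity, cfg = segmentation_config()) {
  stopifnot(inherits(ndvi, "ndvi_raster"), inherits(cfg, "segmentation_config"))
  if (cfg$mode != "ndvi")
    stop("segment_ndvi requires cfg$mode == 'ndvi'", call. = FALSE)
  if (is.null(cfg$intensity_threshold))
    stop(sprintf(
      "no intensity threshold configured for campaign '%s' (radiation-dependent, must be set per campaign)",
      ndvi$campaign_id), call. = FALSE)
  if (!all(dim(intensity) == dim(ndvi$values)))
    stop("intensity raster shape mismatch", call. = FALSE)
  valid <- is.finite(ndvi$values) & is.finite(intensity)
  plant <- valid & (ndvi$values > cfg$ndvi_threshold) &
    (intensity > cfg$intensity_threshold)
  plant[is.na(plant)] <- FALSE
  new_segmentation_mask(plant, valid, cfg)
}

#' Convert an RGB raster to hue, saturation, brightness
#'
#' HSB with brightness `= max(R, G, B)`, saturation `= (max - min)/max`
#' and hue in degrees `[0, 360)` (the common HSB/HSV convention).
#'
#' @param rgb `H x W x 3` array in `[0, 1]`.
#' @return List of matrices `h` (degrees), `s`, `b`.
#' @export
rgb_to_hsb <- function(rgb) {
  stopifnot(length(dim(rgb)) == 3, dim(rgb)[3] == 3)
  r <- rgb[, , 1]; g <- rgb[, , 2]; b <- rgb[, , 3]
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  d <- mx - mn
  h <- matrix(0, nrow(r), ncol(r))
  i <- d > 0 & mx == r
  h[i] <- 60 * (((g - b) / d)[i] %% 6)
  i <- d > 0 & mx == g & mx != r
  h[i] <- 60 * (((b - r) / d)[i] + 2)
  i <- d > 0 & mx == b & mx != r & mx != g
  h[i] <- 60 * (((r - g) / d)[i] + 4)
  s <- ifelse(mx > 0, d / mx, 0)
  list(h = h, s = s, b = mx)
}

#' HSB colour-space plant segmentation for RGB images
#'
#' The alternative to NDVI thresholding: a pixel is plant when hue,
#' saturation and brightness each fall inside the configured interval.
#' The hue interval is treated circularly, so it may wrap past 360
#' degrees (e.g. `c(330, 30)` selects reds).
#'
#' @param rgb `H x W x 3` array in `[0, 1]`.
#' @param cfg A [segmentation_config()] with `mode = "hsb"` and set
#'   `hsb_ranges`.
#' @param campaign_id Campaign label.
#' @return A `segmentation_mask`.
#' @export
segment_hsb <- function(rgb, cfg, campaign_id = "c1") {
  stopifnot(inherits(cfg, "segmentation_config"))
  if (cfg$mode != "hsb")
    stop("segment_hsb requires cfg$mode == 'hsb'", call. = FALSE)
  if (is.null(cfg$hsb_ranges))
    stop("hsb_ranges not configured", call. = FALSE)
  hsb <- rgb_to_hsb(rgb)
  rng <- cfg$hsb_ranges
  hlo <- rng$h[1] %% 360; hhi <- rng$h[2] %% 360
  hue_in <- if (hlo <= hhi) hsb$h >= hlo & hsb$h <= hhi
  else hsb$h >= hlo | hsb$h <= hhi
  valid <- is.finite(hsb$h) & is.finite(hsb$s) & is.finite(hsb$b)
  plant <- valid & hue_in &
    hsb$s >= rng$s[1] & hsb$s <= rng$s[2] &
    hsb$b >= rng$b[1] & hsb$b <= rng$b[2]
  plant[is.na(plant)] <- FALSE
  new_segmentation_mask(plant, valid, cfg)
}

#' Senescent-material NDVI band
#'
#' Pixels with `0.1 < NDVI <= 0.2`: included by the permissive plant
#' threshold of 0.1 but excluded by the stricter 0.2 threshold, i.e. the
#' band dominated by senescent plant material.
#'
#' @param ndvi An `ndvi_raster`.
#' @param lower,upper Band limits (defaults 0.1 and 0.2).
#' @return Logical matrix (`NA` pixels are `FALSE`).
#' @export
senescence_band <- function(ndvi, lower = 0.1, upper = 0.2) {
  stopifnot(inherits(ndvi, "ndvi_raster"))
  m <- is.finite(ndvi$values) & ndvi$values > lower & ndvi$values <= upper
  m[is.na(m)] <- FALSE
  m
}
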