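# shared in-code fixtures for the suite

# textured background with dark disks of given radius at known sub-pixel
# centers; returns the sensor_image and the true centers
make_disk_image <- function(centers, radius = 6, size = c(512, 512),
                            bg = c(0.4, 0.7), disk = c(0.01, 0.05),
                            channel = "B", seed = 11) {
  set.seed(seed)
  img <- matrix(stats::runif(prod(size), bg[1], bg[2]), size[1], size[2])
  centers <- rbind(centers)
  pad <- ceiling(radius) + 2
  for (i in seq_len(nrow(centers))) {
    rr <- round(centers[i, 1]); cc <- round(centers[i, 2])
    for (dr in -pad:pad) for (dc in -pad:pad) {
      if ((rr + dr - centers[i, 1])^2 + (cc + dc - centers[i, 2])^2 <= radius^2)
        img[rr + dr, cc + dc] <- stats::runif(1, disk[1], disk[2])
    }
  }
  list(image = sensor_image(img, channel), centers = centers)
}

# distance from each true center to its nearest detection
detection_errors <- function(detections, centers) {
  dc <- t(vapply(detections, `[[`, numeric(2), "center"))
  vapply(seq_len(nrow(centers)), function(i) {
    min(sqrt(rowSums((dc - matrix(centers[i, ], nrow(dc), 2,
                                  byrow = TRUE))^2)))
  }, 0)
}

# small two-class NDVI scene with exact ground truth: plant_frac of the
# pixels draw from the plant NDVI distribution, the rest from soil
make_gaussian_scene <- function(n = 200, plant_frac = 0.37,
                                plant = c(0.6, 0.05), soil = c(-0.05, 0.03),
                                seed = 1) {
  set.seed(seed)
  npix <- n * n
  is_plant <- seq_len(npix) <= round(plant_frac * npix)
  is_plant <- sample(is_plant)
  v <- numeric(npix)
  v[is_plant] <- stats::rnorm(sum(is_plant), plant[1], plant[2])
  v[!is_plant] <- stats::rnorm(sum(!is_plant), soil[1], soil[2])
  v <- pmin(1, pmax(-1, v))
  s <- rep(0.7, npix)
  b <- matrix(s * (1 - v) / 2, n, n)
  nir <- matrix(s * (1 + v) / 2, n, n)
  list(b = b, nir = nir, truth_plant = matrix(is_plant, n, n),
       plant = plant, soil = soil, plant_frac = mean(is_plant))
}

# analytic accuracy of thresholding two clipped-free Gaussians at thr
two_gaussian_threshold_accuracy <- function(thr, plant_frac, plant, soil) {
  p_correct_plant <- 1 - stats::pnorm(thr, plant[1], plant[2])
  p_correct_soil <- stats::pnorm(thr, soil[1], soil[2])
  plant_frac * p_correct_plant + (1 - plant_frac) * p_correct_soil
}

# cached design/truth under the default study conditions (seed 42)
scene_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- scene_config(seed = 42)
      design <- generate_design(cfg)
      profiles <- genotype_profiles(cfg)
      truth <- simulate_traits(design, profiles, cfg)
      cache <<- list(cfg = cfg, design = design, profiles = profiles,
                     truth = truth)
    }
    cache
  }
})
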