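#' Derive a reproducible sub-stream seed
#'
#' Mixes a master seed with up to three stream indices so that every
#' module, campaign and sensor draws from its own stream: adding a
#' campaign or sensor never perturbs draws made for earlier ones. The
#' result always fits a 32-bit integer.
#'
#' @param seed Master seed (integer).
#' @param ... Up to three non-negative integer stream indices.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, ...) {
  ix <- c(...)
  primes <- c(7919, 104729, 611953)
  s <- as.double(seed) %% 2147483647
  for (i in seq_along(ix)) {
    s <- (s * 31 + as.double(ix[i]) * primes[i]) %% 2147483647
  }
  as.integer(s)
}

#' Default flight campaigns
#'
#' The seasonal acquisition series used by the simulator: thermal time
#' (deg C d after sowing), instantaneous air temperature at capture for
#' the thermal flights, and which flights carried the thermal camera.
#'
#' @return Data frame: `campaign_id`, `tt`, `air_temp`, `has_ir`.
#' @export
default_campaigns <- function() {
  data.frame(
    campaign_id = paste0("c", 1:9),
    tt = c(371, 540, 612, 727, 793, 893, 940, 1275, 1366),
    air_temp = c(NA, NA, 25.95, 24.40, 27.52, 24.40, 24.01, 21.71, NA),
    has_ir = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
}

#' Synthetic scene configuration
#'
#' All tunable knobs of the simulator, with defaults reproducing the
#' reference trial conditions: a split-plot design of 16 genotypes x
#' 1-4-row plots x 4 blocks (4 m plots, 0.75 m row spacing), eight dark
#' circular markers (0.7 m diameter) around each field sub-array, and
#' per-sensor ground pixels of 0.0285 m (RGB), 0.026 m (B+NIR) and
#' 0.1 m (thermal) matching the sensor optics at 300 m altitude. The
#' common AoI frame uses the B+NIR ground pixel.
#'
#' @param seed Master seed; fixes all randomness of the generator.
#' @param ground_pixel Named numeric: metres per pixel for `rgb`, `bnir`,
#'   `ir`.
#' @param plant_ndvi_sd,soil_ndvi_mean,soil_ndvi_sd Pixel NDVI
#'   distributions: plant pixels draw around the plot's true plant NDVI,
#'   soil pixels around `soil_ndvi_mean`.
#' @param plant_intensity,soil_intensity,intensity_sd,shade_fraction,shade_intensity
#'   Reflection-intensity (sum of B and NIR digital numbers, 0-1 scale)
#'   distributions; `shade_fraction` of plant pixels are rendered heavily
#'   shaded.
#' @param intensity_threshold Per-campaign grey-intensity segmentation
#'   threshold appropriate for these illumination settings (on the
#'   mean-of-B-and-NIR scale).
#' @param soil_dt Soil surface excess temperature over air (deg C).
#' @param thermal_noise_sd,soil_thermal_sd Pixel temperature noise.
#' @param marker_diameter,marker_dn,marker_temp Marker size (m), optical
#'   digital number and emitted temperature (deg C).
#' @param sensor_margin Linear oversize factor of each sensor image
#'   relative to the AoI, leaving room for the projective distortion.
#' @param perspective_mag,rotation_mag_deg Magnitude of the random true
#'   projective distortion per sensor.
#' @param variance Per-trait variance parameters: list with elements
#'   `cc`, `ndvi_plant`, `t_c`, each `c(gen = ..., eps = ...)`. The
#'   residual component is divided by the plot row count, the mechanism
#'   producing the plot-size repeatability effect.
#' @param campaigns Campaign data frame (see [default_campaigns()]).
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(seed = 1L,
                         ground_pixel = c(rgb = 0.0285, bnir = 0.026, ir = 0.1),
                         plant_ndvi_sd = 0.05,
                         soil_ndvi_mean = -0.05, soil_ndvi_sd = 0.03,
                         plant_intensity = 0.8, soil_intensity = 0.6,
                         intensity_sd = 0.04,
                         shade_fraction = 0, shade_intensity = 0.25,
                         intensity_threshold = 0.2,
                         soil_dt = 6,
                         thermal_noise_sd = 0.3, soil_thermal_sd = 0.5,
                         marker_diameter = 0.7, marker_dn = 0.02,
                         marker_temp = 45,
                         sensor_margin = 1.12,
                         perspective_mag = 0.03, rotation_mag_deg = 0.5,
                         variance = list(cc = c(gen = 9e-4, eps = 4e-4),
                                         ndvi_plant = c(gen = 4e-4, eps = 2.5e-4),
                                         t_c = c(gen = 0.09, eps = 0.36)),
                         campaigns = default_campaigns()) {
  stopifnot(all(c("rgb", "bnir", "ir") %in% names(ground_pixel)),
            ground_pixel["ir"] > ground_pixel["bnir"])
  structure(list(seed = as.integer(seed), ground_pixel = ground_pixel,
                 plant_ndvi_sd = plant_ndvi_sd,
                 soil_ndvi_mean = soil_ndvi_mean, soil_ndvi_sd = soil_ndvi_sd,
                 plant_intensity = plant_intensity,
                 soil_intensity = soil_intensity, intensity_sd = intensity_sd,
                 shade_fraction = shade_fraction,
                 shade_intensity = shade_intensity,
                 intensity_threshold = intensity_threshold,
                 soil_dt = soil_dt, thermal_noise_sd = thermal_noise_sd,
                 soil_thermal_sd = soil_thermal_sd,
                 marker_diameter = marker_diameter, marker_dn = marker_dn,
                 marker_temp = marker_temp, sensor_margin = sensor_margin,
                 perspective_mag = perspective_mag,
                 rotation_mag_deg = rotation_mag_deg,
                 variance = variance, campaigns = campaigns),
            class = "scene_config")
}

# fixed layout constants of the trial
.layout_const <- list(plot_length = 4, row_spacing = 0.75, margin = 1.5,
                      strip_gap = 0.75, block_gap = 1.5)

#' Generate the split-plot trial design
#'
#' 16 genotypes (six hybrids, five dent and five flint inbred lines) x
#' four row-count whole plots (1-4 rows) x four replicate blocks = 256
#' plots, laid out in three field sub-arrays (blocks 1+2, 3, 4), each
#' ringed by eight circular markers. Hybrids and inbreds are randomized
#' in separate sub-blocks within every whole plot. Plot length is 4 m,
#' row spacing 0.75 m; a 2-row plot therefore covers 2 x 0.75 x 4 = 6 m2.
#' Deterministic given the config seed.
#'
#' @param cfg A [scene_config()].
#' @return Data frame of 256 plots (`plot_id`, `genotype`, `type`,
#'   `rows`, `block`, `sub_array`, `polygon` in sub-array-local metres)
#'   with attributes `layout` (geometry constants, per-sub-array sizes,
#'   marker positions, position lookup) used by the renderer.
#' @export
generate_design <- function(cfg = scene_config()) {
  L <- .layout_const
  genos <- sprintf("g%02d", 0:15)
  gtype <- c(rep("hybrid", 6), rep("dent", 5), rep("flint", 5))
  sa_of_block <- c(1L, 1L, 2L, 3L)
  strip_h <- L$plot_length + L$strip_gap               # 4.75 m
  block_h <- 4 * L$plot_length + 3 * L$strip_gap       # 18.25 m
  width <- 2 * L$margin + 16 * 4 * L$row_spacing       # widest strip: 48 m
  sub_arrays <- list()
  for (sa in 1:3) {
    blocks_here <- which(sa_of_block == sa)
    nb <- length(blocks_here)
    height <- 2 * L$margin + nb * block_h + (nb - 1) * L$block_gap
    y0 <- L$margin + (seq_len(nb) - 1) * (block_h + L$block_gap)
    mk <- rbind(c(0.75, 0.75), c(width / 2, 0.75), c(width - 0.75, 0.75),
                c(width - 0.75, height / 2), c(width - 0.75, height - 0.75),
                c(width / 2, height - 0.75), c(0.75, height - 0.75),
                c(0.75, height / 2))
    colnames(mk) <- c("x", "y")
    sub_arrays[[sa]] <- list(width = width, height = height,
                             blocks = data.frame(block = blocks_here, y0 = y0),
                             markers = mk)
  }
  order_idx <- array(NA_integer_, c(4, 4, 16))  # block, strip(rows), position
  rows_list <- list()
  idx <- 0L
  for (b in 1:4) {
    sa <- sa_of_block[b]
    binfo <- sub_arrays[[sa]]$blocks
    by0 <- binfo$y0[binfo$block == b]
    for (s in 1:4) {  # rows per plot
      set.seed(derive_seed(cfg$seed, 1L, b, s))
      ord <- c(sample(1:6), sample(7:16))  # hybrids | inbreds sub-blocks
      w <- s * L$row_spacing
      for (k in 1:16) {
        gi <- ord[k]
        idx <- idx + 1L
        order_idx[b, s, k] <- idx
        x0 <- L$margin + (k - 1) * w
        y0 <- by0 + (s - 1) * strip_h
        poly <- rbind(c(x0, y0), c(x0 + w, y0),
                      c(x0 + w, y0 + L$plot_length), c(x0, y0 + L$plot_length))
        rows_list[[idx]] <- data.frame(
          plot_id = sprintf("b%d_r%d_%s", b, s, genos[gi]),
          genotype = genos[gi], type = gtype[gi], rows = s,
          block = paste0("b", b), sub_array = sa,
          polygon = format_polygon(poly), stringsAsFactors = FALSE)
      }
    }
  }
  design <- do.call(rbind, rows_list)
  attr(design, "layout") <- c(L, list(strip_h = strip_h, block_h = block_h,
                                      sub_arrays = sub_arrays,
                                      order_idx = order_idx,
                                      sa_of_block = sa_of_block))
  design
}

#' Genotype profiles driving the seasonal trait curves
#'
#' Seeded draw of per-genotype parameters: maximal canopy cover and
#' canopy-closure timing (hybrids close earlier and more completely than
#' inbred lines), a senescence rate applied after 892 deg C d, a plant
#' NDVI level, and a genotype canopy-temperature offset. The spread of
#' these parameters is the genotypic variance seen downstream.
#'
#' @param cfg A [scene_config()].
#' @return List of 16 profile lists, one per genotype.
#' @export
genotype_profiles <- function(cfg = scene_config()) {
  set.seed(derive_seed(cfg$seed, 0L))
  profs <- list()
  for (i in 1:16) {
    hybrid <- i <= 6
    profs[[i]] <- list(
      genotype = sprintf("g%02d", i - 1),
      cc_max = if (hybrid) stats::runif(1, 0.96, 1.0) else stats::runif(1, 0.86, 0.94),
      t50 = if (hybrid) stats::rnorm(1, 180, 15) else stats::rnorm(1, 250, 20),
      slope = 60,
      sen_cc = if (hybrid) stats::runif(1, 3e-4, 5e-4) else stats::runif(1, 6e-4, 9e-4),
      ndvi_level = if (hybrid) stats::rnorm(1, 0.47, 0.02) else stats::rnorm(1, 0.42, 0.02),
      sen_ndvi = if (hybrid) stats::runif(1, 4e-4, 6e-4) else stats::runif(1, 6e-4, 9e-4),
      dt_offset = stats::rnorm(1, 0, sqrt(cfg$variance$t_c["gen"])))
  }
  names(profs) <- vapply(profs, `[[`, "", "genotype")
  profs
}

# seasonal curves: logistic rise to a plateau, linear decline after the
# senescence onset at 892 deg C d
cc_curve <- function(prof, tt) {
  rise <- prof$cc_max * stats::plogis((tt - prof$t50) / prof$slope)
  rise * pmax(0.3, 1 - prof$sen_cc * pmax(0, tt - 892))
}

ndvi_curve <- function(prof, tt) {
  rise <- prof$ndvi_level * stats::plogis((tt - prof$t50) / prof$slope)
  rise * pmax(0.5, 1 - prof$sen_ndvi * pmax(0, tt - 892))
}

# canopy-air temperature difference: negative while the canopy
# transpires (612-940 deg C d), positive at advanced senescence
dt_base <- function(tt) {
  stats::approx(x = c(0, 371, 540, 612, 727, 793, 893, 940, 1100, 1275, 1500),
                y = c(-0.5, -0.8, -1.2, -1.2, -1.8, -1.0, -1.5, -1.6, 0, 1.0, 1.2),
                xout = tt, rule = 2)$y
}

#' Simulate the per-plot ground-truth trait table
#'
#' True canopy cover, plant NDVI and canopy temperature per plot and
#' campaign: genotype curve value plus a residual whose variance is the
#' configured `eps` component divided by the plot row count (larger plots
#' average over more rows, which is what drives repeatability up with
#' plot size). Canopy temperature is `air_temp + dT(tt) + genotype offset
#' + residual` and only exists for thermal campaigns.
#'
#' @param design From [generate_design()].
#' @param profiles From [genotype_profiles()].
#' @param cfg A [scene_config()]; its `campaigns` and `variance` entries
#'   are used.
#' @return Data frame: one row per plot x campaign with true `cc`,
#'   `ndvi_plant`, `t_c`, `dt` plus design columns.
#' @export
simulate_traits <- function(design, profiles, cfg = scene_config()) {
  # force arguments now: a lazily evaluated genotype_profiles() call would
  # otherwise reset the RNG inside the seeded campaign loop below
  force(design); force(profiles); force(cfg)
  camps <- cfg$campaigns
  out <- vector("list", nrow(camps))
  for (ci in seq_len(nrow(camps))) {
    set.seed(derive_seed(cfg$seed, 2L, ci))
    tt <- camps$tt[ci]
    n <- nrow(design)
    pr <- profiles[design$genotype]
    cc_mu <- vapply(pr, cc_curve, 0, tt = tt)
    nd_mu <- vapply(pr, ndvi_curve, 0, tt = tt)
    sd_cc <- sqrt(cfg$variance$cc["eps"] / design$rows)
    sd_nd <- sqrt(cfg$variance$ndvi_plant["eps"] / design$rows)
    cc <- pmin(1, pmax(0.02, cc_mu + stats::rnorm(n, 0, sd_cc)))
    nd <- pmin(0.9, pmax(0.05, nd_mu + stats::rnorm(n, 0, sd_nd)))
    if (isTRUE(camps$has_ir[ci]) && is.finite(camps$air_temp[ci])) {
      off <- vapply(pr, `[[`, 0, "dt_offset")
      sd_t <- sqrt(cfg$variance$t_c["eps"] / design$rows)
      t_c <- camps$air_temp[ci] + dt_base(tt) + off + stats::rnorm(n, 0, sd_t)
      dt <- t_c - camps$air_temp[ci]
    } else {
      t_c <- rep(NA_real_, n); dt <- rep(NA_real_, n)
    }
    out[[ci]] <- data.frame(design[, c("plot_id", "genotype", "type", "rows",
                                       "block", "sub_array")],
                            campaign_id = camps$campaign_id[ci], tt = tt,
                            air_temp = camps$air_temp[ci],
                            cc = cc, ndvi_plant = nd, t_c = t_c, dt = dt,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate a balanced genotype x block trait table
#'
#' Minimal generator for exercising the variance-component estimator:
#' genotype effects `N(0, sigma2_gen)`, block effects `N(0, sigma2_gen)`
#' (fixed in the analysis, so their size is immaterial) and residuals
#' `N(0, sigma2_eps)`, one observation per cell.
#'
#' @param g,r Numbers of genotypes and blocks.
#' @param sigma2_gen,sigma2_eps True variance components.
#' @param rows_per_plot Row count tag attached to every observation.
#' @param seed Seed.
#' @param trait Trait label.
#' @return Long trait table usable with [estimate_components()].
#' @export
simulate_balanced_trait <- function(g = 16, r = 4, sigma2_gen = 3,
                                    sigma2_eps = 1, rows_per_plot = 4L,
                                    seed = 1L, trait = "y") {
  set.seed(seed)
  geff <- stats::rnorm(g, 0, sqrt(sigma2_gen))
  beff <- stats::rnorm(r, 0, sqrt(sigma2_gen))
  d <- expand.grid(genotype = sprintf("g%02d", seq_len(g) - 1),
                   block = paste0("b", seq_len(r)),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d$rows <- rows_per_plot
  d$campaign_id <- "c1"
  d$tt <- 0
  d$trait <- trait
  d$value <- geff[match(d$genotype, unique(d$genotype))] +
    beff[match(d$block, unique(d$block))] +
    stats::rnorm(nrow(d), 0, sqrt(sigma2_eps))
  d
}

# vectorized scene lookup: field class and plot index at local metre
# coordinates (x along columns, y along rows) of one sub-array
scene_eval <- function(design, cc_by_plot, layout, sa, x, y) {
  L <- layout
  info <- L$sub_arrays[[sa]]
  n <- length(x)
  plot_idx <- integer(n)
  plant <- logical(n)
  for (bi in seq_len(nrow(info$blocks))) {
    b <- info$blocks$block[bi]
    yb <- y - info$blocks$y0[bi]
    inb <- yb >= 0 & yb < L$block_h
    if (!any(inb)) next
    s <- pmin(4L, pmax(1L, floor(yb / L$strip_h) + 1L))
    inplot_y <- inb & (yb - (s - 1) * L$strip_h) < L$plot_length &
      (yb - (s - 1) * L$strip_h) >= 0
    w <- s * L$row_spacing
    xb <- x - L$margin
    k <- floor(xb / w) + 1L
    ok <- inplot_y & xb >= 0 & k >= 1L & k <= 16L
    if (!any(ok)) next
    idx <- L$order_idx[cbind(b, s[ok], k[ok])]
    plot_idx[ok] <- idx
    # canopy occupies the first cc fraction of the 4 m row length; the
    # bare remainder (emergence gaps accumulate at the far plot end)
    # realizes the plot's true canopy cover as an area fraction
    ly <- yb[ok] - (s[ok] - 1) * L$strip_h
    plant[ok] <- ly <= cc_by_plot[idx] * L$plot_length
  }
  marker <- logical(n)
  r2 <- (attr(cc_by_plot, "marker_radius") %||% 0.35)^2
  for (m in seq_len(nrow(info$markers))) {
    marker <- marker | ((x - info$markers[m, 1])^2 +
                          (y - info$markers[m, 2])^2 <= r2)
  }
  plant[marker] <- FALSE
  plot_idx[marker] <- 0L
  list(plot_idx = plot_idx, plant = plant, marker = marker)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random true sensor->AoI homography: scale + slight rotation + mild
# perspective, centered so the AoI sits inside the sensor frame
make_true_homography <- function(sensor_shape, aoi_shape, g_ratio, seed,
                                 perspective_mag, rotation_mag_deg) {
  set.seed(seed)
  th <- stats::runif(1, -1, 1) * rotation_mag_deg * pi / 180
  p <- stats::runif(2, -1, 1) * perspective_mag / max(sensor_shape)
  ctr_s <- (sensor_shape + 1) / 2
  ctr_c <- (aoi_shape + 1) / 2
  T1 <- matrix(c(1, 0, -ctr_s[1], 0, 1, -ctr_s[2], 0, 0, 1), 3, 3, byrow = TRUE)
  P <- matrix(c(1, 0, 0, 0, 1, 0, p[1], p[2], 1), 3, 3, byrow = TRUE)
  S <- matrix(c(g_ratio * cos(th), -g_ratio * sin(th), 0,
                g_ratio * sin(th), g_ratio * cos(th), 0,
                0, 0, 1), 3, 3, byrow = TRUE)
  T2 <- matrix(c(1, 0, ctr_c[1], 0, 1, ctr_c[2], 0, 0, 1), 3, 3, byrow = TRUE)
  H <- T2 %*% S %*% P %*% T1
  H / H[3, 3]
}

#' Render one campaign of one field sub-array
#'
#' Draws the three sensor images for a campaign: each plot's canopy as a
#' block covering the leading fraction of the row length equal to the
#' plot's true canopy cover (bare soil accumulating at the far plot end,
#' as emergence gaps do along real rows), soil background, dark circular
#' markers in the optical images and warm
#' markers in the thermal image. Each sensor image is generated in its own
#' pixel grid, displaced from the common AoI frame by a known ("true")
#' projective transform. Per-pixel class truth is retained in the common
#' frame. Fully deterministic given the config seed.
#'
#' @param design From [generate_design()].
#' @param truth From [simulate_traits()].
#' @param campaign_id Campaign to render.
#' @param cfg A [scene_config()].
#' @param sub_array Which sub-array (1-3).
#' @return List: `images` (named list of [sensor_image()]: `rgb`, `bnir`
#'   and `ir` when the campaign is thermal), `h_true` (true sensor->AoI
#'   homographies), `truth` (`labels`, `plant`, `marker` rasters in the
#'   common frame plus the `plot_ids` indexing `labels`),
#'   `markers_aoi` (8 x 2 matrix of marker (row, col) AoI positions),
#'   `aoi_shape`, `ground_pixel`.
#' @export
render_scene <- function(design, truth, campaign_id, cfg = scene_config(),
                         sub_array = 1L) {
  L <- attr(design, "layout")
  info <- L$sub_arrays[[sub_array]]
  g0 <- unname(cfg$ground_pixel["bnir"])
  aoi_shape <- unname(c(ceiling(info$height / g0), ceiling(info$width / g0)))
  camps <- cfg$campaigns
  ci <- match(campaign_id, camps$campaign_id)
  if (is.na(ci)) stop("unknown campaign ", campaign_id, call. = FALSE)
  tr <- truth[truth$campaign_id == campaign_id, ]
  tr <- tr[match(design$plot_id, tr$plot_id), ]
  cc_by_plot <- tr$cc
  attr(cc_by_plot, "marker_radius") <- cfg$marker_diameter / 2
  if (any(info$markers[, 1] > info$width | info$markers[, 2] > info$height |
          info$markers < 0))
    stop("marker outside the sub-array AoI", call. = FALSE)

  # common-frame truth at pixel centers
  gr <- rep(seq_len(aoi_shape[1]), times = aoi_shape[2])
  gc <- rep(seq_len(aoi_shape[2]), each = aoi_shape[1])
  ev <- scene_eval(design, cc_by_plot, L, sub_array,
                   (gc - 0.5) * g0, (gr - 0.5) * g0)
  labels <- matrix(ev$plot_idx, aoi_shape[1], aoi_shape[2])
  attr(labels, "plot_ids") <- design$plot_id
  truth_r <- list(labels = labels,
                  plant = matrix(ev$plant, aoi_shape[1], aoi_shape[2]),
                  marker = matrix(ev$marker, aoi_shape[1], aoi_shape[2]))
  rm(ev, gr, gc)

  sensors <- c("rgb", "bnir", if (isTRUE(camps$has_ir[ci])) "ir")
  images <- list(); h_true <- list()
  for (sn in sensors) {
    gs <- unname(cfg$ground_pixel[sn])
    shp <- ceiling(aoi_shape * (g0 / gs) * cfg$sensor_margin)
    si <- match(sn, c("rgb", "bnir", "ir"))
    H <- make_true_homography(shp, aoi_shape, as.numeric(gs / g0),
                              derive_seed(cfg$seed, 3L, ci * 16L + si,
                                          sub_array),
                              cfg$perspective_mag, cfg$rotation_mag_deg)
    h_true[[sn]] <- H
    pr <- rep(seq_len(shp[1]), times = shp[2])
    pc <- rep(seq_len(shp[2]), each = shp[1])
    aoi <- apply_homography(H, cbind(pr, pc))
    ev <- scene_eval(design, cc_by_plot, L, sub_array,
                     (aoi[, 2] - 0.5) * g0, (aoi[, 1] - 0.5) * g0)
    rm(aoi, pr, pc)
    n <- prod(shp)
    set.seed(derive_seed(cfg$seed, 4L, ci * 16L + si, sub_array))
    pl <- ev$plant; mk <- ev$marker
    idx <- ev$plot_idx
    if (sn %in% c("rgb", "bnir")) {
      v <- stats::rnorm(n, cfg$soil_ndvi_mean, cfg$soil_ndvi_sd)
      v[pl] <- tr$ndvi_plant[idx[pl]] +
        stats::rnorm(sum(pl), 0, cfg$plant_ndvi_sd)
      v <- pmin(0.95, pmax(-0.95, v))
      s <- stats::rnorm(n, cfg$soil_intensity, cfg$intensity_sd)
      s[pl] <- stats::rnorm(sum(pl), cfg$plant_intensity, cfg$intensity_sd)
      if (cfg$shade_fraction > 0) {
        sh <- pl & stats::runif(n) < cfg$shade_fraction
        s[sh] <- stats::rnorm(sum(sh), cfg$shade_intensity, 0.02)
      }
      s <- pmin(1, pmax(0.02, s))
      if (sn == "bnir") {
        B <- s * (1 - v) / 2
        NIR <- s * (1 + v) / 2
        B[mk] <- cfg$marker_dn; NIR[mk] <- cfg$marker_dn
        px <- array(c(B, NIR), c(shp, 2))
        images[[sn]] <- sensor_image(px, c("B", "NIR"), campaign_id)
      } else {
        R <- stats::rnorm(n, 0.45, 0.02)
        G <- stats::rnorm(n, 0.38, 0.02)
        Bl <- stats::rnorm(n, 0.30, 0.02)
        R[pl] <- stats::rnorm(sum(pl), 0.18, 0.02)
        G[pl] <- 0.30 + 0.4 * v[pl] + stats::rnorm(sum(pl), 0, 0.02)
        Bl[pl] <- stats::rnorm(sum(pl), 0.12, 0.02)
        R[mk] <- cfg$marker_dn; G[mk] <- cfg$marker_dn; Bl[mk] <- cfg$marker_dn
        px <- array(pmin(1, pmax(0, c(R, G, Bl))), c(shp, 3))
        images[[sn]] <- sensor_image(px, c("R", "G", "B"), campaign_id)
      }
    } else {
      ta <- camps$air_temp[ci]
      tv <- stats::rnorm(n, ta + cfg$soil_dt, cfg$soil_thermal_sd)
      tv[pl] <- tr$t_c[idx[pl]] + stats::rnorm(sum(pl), 0, cfg$thermal_noise_sd)
      tv[mk] <- cfg$marker_temp + stats::rnorm(sum(mk), 0, 0.2)
      px <- array(tv, c(shp, 1))
      images[[sn]] <- sensor_image(px, "T", campaign_id, units = "celsius")
    }
    rm(ev)
  }
  markers_aoi <- cbind(info$markers[, "y"] / g0 + 0.5,
                       info$markers[, "x"] / g0 + 0.5)
  colnames(markers_aoi) <- c("row", "col")
  list(images = images, h_true = h_true, truth = truth_r,
       markers_aoi = markers_aoi, aoi_shape = aoi_shape,
       ground_pixel = g0)
}
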