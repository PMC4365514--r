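test_that("rasterization labels exactly the pixel centers inside polygons", {
  g <- 0.5  # metres per pixel; centers at (c-0.5)*g, (r-0.5)*g
  map <- data.frame(plot_id = "p1",
                    polygon = format_polygon(rbind(c(1, 1), c(4, 1),
                                                   c(4, 3), c(1, 3))))
  lab <- rasterize_plot_map(map, c(10, 12), g)
  # brute-force oracle over every pixel center
  want <- matrix(0L, 10, 12)
  for (r in 1:10) for (c in 1:12) {
    x <- (c - 0.5) * g; y <- (r - 0.5) * g
    if (x > 1 && x < 4 && y > 1 && y < 3) want[r, c] <- 1L
  }
  expect_equal(unclass(lab), want, ignore_attr = TRUE)
  expect_gt(sum(lab), 0)
})

test_that("empty maps and overlapping polygons are handled", {
  empty <- rasterize_plot_map(data.frame(plot_id = character(0),
                                         polygon = character(0)),
                              c(5, 5), 1)
  expect_true(all(empty == 0L))
  two <- data.frame(plot_id = c("a", "b"),
                    polygon = c(format_polygon(rbind(c(0, 0), c(3, 0),
                                                     c(3, 3), c(0, 3))),
                                format_polygon(rbind(c(2, 2), c(5, 2),
                                                     c(5, 5), c(2, 5)))))
  expect_error(rasterize_plot_map(two, c(10, 10), 0.5), "overlapping.*a.*b")
})

test_that("skewness implements population moments exactly", {
  expect_equal(skewness(c(1, 2, 3)), 0)
  expect_equal(skewness(c(-5, 0, 5, 10, -10)), 0)  # symmetric sample
  expect_equal(skewness(c(0, 0, 1)), 1 / sqrt(2))
  expect_equal(skewness(c(0, 1, 1)), -1 / sqrt(2))
  expect_error(skewness(c(5, 5, 5)), "zero variance")
  expect_error(skewness(7), "at least 2")
  # agreement with a direct evaluation on random data
  set.seed(12)
  x <- stats::rexp(500)
  m <- mean(x)
  expect_equal(skewness(x),
               mean((x - m)^3) / sqrt(mean((x - m)^2))^3,
               tolerance = 1e-12)
})

test_that("per-plot traits match brute-force recomputation", {
  # 10 x 10 plot: 60 plant pixels at NDVI 0.8, 40 soil at 0.0
  v <- matrix(0, 10, 10)
  v[1:6, ] <- 0.8
  nd <- compute_ndvi(0.5 * (1 - v), 0.5 * (1 + v))
  mask <- segment_ndvi(nd, matrix(0.5, 10, 10),
                       segmentation_config(0.1, intensity_threshold = 0.2))
  lab <- matrix(1L, 10, 10)
  attr(lab, "plot_ids") <- "p1"
  rec <- extract_plot_traits(nd, mask, lab)
  expect_equal(rec$cc, 0.60)
  expect_equal(rec$n_pixels, 100L)
  expect_equal(rec$n_plant_pixels, 60L)
  expect_equal(rec$ndvi_plot, stats::median(v))
  expect_equal(rec$ndvi_plant, 0.8)
  expect_equal(rec$skew_plot, skewness(as.numeric(v)))
  expect_true(is.na(rec$skew_plant))  # constant plant NDVI: undefined

  # balanced mixture: median is the tie-midpoint
  v2 <- matrix(rep(c(0, 0.8), each = 50), 10, 10)
  nd2 <- compute_ndvi(0.5 * (1 - v2), 0.5 * (1 + v2))
  mask2 <- segment_ndvi(nd2, matrix(0.5, 10, 10),
                        segmentation_config(0.1, intensity_threshold = 0.2))
  rec2 <- extract_plot_traits(nd2, mask2, lab)
  expect_equal(rec2$cc, 0.5)
  expect_equal(rec2$ndvi_plot, 0.4)
  expect_equal(rec2$ndvi_plant, 0.8)
})

test_that("canopy temperature and dT follow the sign convention", {
  nd <- compute_ndvi(matrix(0.3, 6, 6), matrix(0.7, 6, 6))
  mask <- segment_ndvi(nd, matrix(0.5, 6, 6),
                       segmentation_config(0.1, intensity_threshold = 0.2))
  lab <- matrix(1L, 6, 6)
  attr(lab, "plot_ids") <- "p1"
  rec <- extract_plot_traits(nd, mask, lab,
                             thermal = matrix(22.6, 6, 6), air_temp = 24.4)
  expect_equal(rec$t_c, 22.6)
  expect_equal(rec$dt, -1.8)  # cooler canopy: negative dT
})

test_that("plot NDVI skewness is positive at sparse cover and ~0 when closed", {
  set.seed(91)
  make_plot <- function(cc) {
    n <- 2500
    plant <- seq_len(n) <= cc * n
    v <- ifelse(plant, stats::rnorm(n, 0.6, 0.05), stats::rnorm(n, -0.05, 0.03))
    nd <- compute_ndvi(matrix(0.5 * (1 - v), 50, 50),
                       matrix(0.5 * (1 + v), 50, 50))
    lab <- matrix(1L, 50, 50)
    attr(lab, "plot_ids") <- "p"
    mask <- segment_ndvi(nd, matrix(0.5, 50, 50),
                         segmentation_config(0.1, intensity_threshold = 0.2))
    extract_plot_traits(nd, mask, lab)
  }
  expect_gt(make_plot(0.3)$skew_plot, 0.5)
  expect_lt(abs(make_plot(1.0)$skew_plot), 0.2)
})

test_that("plant NDVI bounds follow from the segmentation threshold", {
  set.seed(71)
  v <- matrix(stats::rnorm(400, 0.3, 0.3), 20, 20)
  nd <- compute_ndvi(0.5 * (1 - pmin(0.9, pmax(-0.9, v))),
                     0.5 * (1 + pmin(0.9, pmax(-0.9, v))))
  mask <- segment_ndvi(nd, matrix(0.5, 20, 20),
                       segmentation_config(0.1, intensity_threshold = 0.2))
  lab <- matrix(1L, 20, 20)
  attr(lab, "plot_ids") <- "p1"
  rec <- extract_plot_traits(nd, mask, lab)
  expect_gte(rec$ndvi_plant, 0.1)      # all plant pixels exceed the threshold
  expect_gte(rec$ndvi_plant, rec$ndvi_plot)  # soil below plant pulls the plot median down
})

test_that("pixel conservation holds over the rasterized design", {
  fx <- scene_fixture()
  sub <- fx$design[fx$design$sub_array == 3, ]
  shape <- c(820, 1962)
  lab <- rasterize_plot_map(sub, shape, fx$cfg$ground_pixel["bnir"])
  nd <- compute_ndvi(matrix(0.3, shape[1], shape[2]),
                     matrix(0.7, shape[1], shape[2]))
  mask <- segment_ndvi(nd, matrix(0.5, shape[1], shape[2]),
                       segmentation_config(0.1, intensity_threshold = 0.2))
  rec <- extract_plot_traits(nd, mask, lab)
  expect_equal(sum(rec$n_pixels), sum(lab > 0))
  expect_equal(nrow(rec), 64)  # one block: 16 genotypes x 4 row counts
  # a 2-row plot spans 2 x 0.75 m x 4 m = 6 m^2 of labelled area
  two_row <- rec$n_pixels[match(sub$plot_id[sub$rows == 2], rec$plot_id)]
  area <- two_row * fx$cfg$ground_pixel["bnir"]^2
  expect_true(all(abs(area - 6) < 0.1))
})

test_that("the seasonal table joins design and campaigns in long format", {
  fx <- scene_fixture()
  camps <- data.frame(campaign_id = c("c1", "c2"), tt = c(371, 540))
  recs <- do.call(rbind, lapply(camps$campaign_id, function(cid) {
    data.frame(plot_id = fx$design$plot_id, campaign_id = cid,
               cc = stats::runif(256), ndvi_plot = 0.3, ndvi_plant = 0.5,
               skew_plot = 0.1, t_c = NA_real_, dt = NA_real_,
               stringsAsFactors = FALSE)
  }))
  long <- seasonal_table(recs, fx$design, camps,
                         traits = c("cc", "ndvi_plot", "ndvi_plant",
                                    "skew_plot", "t_c", "dt"))
  expect_equal(nrow(long), 256 * 2 * 6)
  expect_setequal(unique(long$trait),
                  c("cc", "ndvi_plot", "ndvi_plant", "skew_plot", "t_c", "dt"))
  expect_true(all(long$tt[long$campaign_id == "c2"] == 540))
  # unknown campaign is refused
  bad <- recs; bad$campaign_id[1] <- "c99"
  expect_error(seasonal_table(bad, fx$design, camps), "unknown campaign")
  # empty in, empty out
  expect_equal(nrow(seasonal_table(recs[0, ], fx$design, camps)), 0)
})

test_that("genotype means of canopy cover decline through late senescence", {
  fx <- scene_fixture()
  tr <- fx$truth
  late <- c("c6", "c7", "c8", "c9")  # 893 to 1366 degree days
  gm <- sapply(late, function(cid)
    tapply(tr$cc[tr$campaign_id == cid], tr$genotype[tr$campaign_id == cid],
           mean))
  expect_true(all(diff(t(gm)) < 0))
})
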