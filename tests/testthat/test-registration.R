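test_that("markers are detected at sub-pixel accuracy on textured scenes", {
  set.seed(21)
  centers <- cbind(c(50, 50, 50, 250, 250, 450, 450, 450),
                   c(60, 250, 440, 60, 440, 60, 250, 440)) +
    matrix(stats::runif(16, -0.4, 0.4), 8, 2)
  fx <- make_disk_image(centers, radius = 6)
  det <- detect_markers(fx$image, "dark", expected_radius_px = c(4, 9),
                        max_markers = 10)
  expect_length(det, 8)
  expect_true(all(detection_errors(det, fx$centers) < 0.5))
  # detections are score-sorted
  scores <- vapply(det, `[[`, 0, "score")
  expect_true(all(diff(scores) <= 0))
})

test_that("a single centered disk is found within half a pixel", {
  fx <- make_disk_image(cbind(256.3, 255.8), radius = 6, seed = 5)
  err <- tryCatch(detect_markers(fx$image, "dark",
                                 expected_radius_px = c(4, 9)),
                  error = function(e) e)
  # fewer than four markers: infeasible, but the one disk is in the
  # partial list at sub-pixel accuracy (manual-override entry point)
  expect_s3_class(err, "aerophen_registration_infeasible")
  expect_length(err$markers, 1)
  expect_lt(sqrt(sum((err$markers[[1]]$center - c(256.3, 255.8))^2)), 0.5)
})

test_that("featureless images raise a registration-infeasible error", {
  flat <- sensor_image(matrix(0.5, 64, 64), "B")
  expect_error(detect_markers(flat, "dark", expected_radius_px = c(3, 8)),
               class = "aerophen_registration_infeasible")
})

test_that("bright-polarity detection finds warm markers in thermal frames", {
  set.seed(9)
  img <- matrix(stats::rnorm(300 * 300, 25, 0.8), 300, 300)
  centers <- cbind(c(40, 40, 260, 260), c(40, 260, 40, 260))
  for (i in 1:4) {
    for (dr in -9:9) for (dc in -9:9)
      if (dr^2 + dc^2 <= 49)
        img[centers[i, 1] + dr, centers[i, 2] + dc] <- stats::rnorm(1, 45, 0.2)
  }
  det <- detect_markers(sensor_image(img, "T", units = "celsius"), "bright",
                        expected_radius_px = c(5, 10))
  expect_length(det, 4)
  expect_true(all(detection_errors(det, centers) < 0.5))
})

test_that("NCC self-correlation is exactly one and zero offset", {
  fx <- make_disk_image(cbind(40.2, 41.7), radius = 5, size = c(80, 80),
                        seed = 2)
  marker <- list(center = c(40.2, 41.7), radius = 5, score = 1,
                 source_channel = "B")
  res <- refine_by_ncc(fx$image, fx$image, marker, window_px = 8,
                       slack_px = 5)
  expect_equal(res$score, 1.0)
  expect_equal(res$center, round(c(40.2, 41.7)))
})

test_that("NCC recovers a planted offset exactly, matching the exhaustive oracle", {
  set.seed(31)
  tm <- matrix(stats::runif(41 * 41), 41, 41)
  tmpl_img <- sensor_image(tm, "B")
  big <- matrix(stats::runif(120 * 120), 120, 120)
  known <- c(67, 44)  # center of the planted template in the big image
  big[(known[1] - 20):(known[1] + 20), (known[2] - 20):(known[2] + 20)] <- tm
  search_img <- sensor_image(big, "B")
  marker <- list(center = c(21, 21), radius = 5, score = 1,
                 source_channel = "B")
  res <- refine_by_ncc(tmpl_img, search_img, marker,
                       search_center = known + c(-4, 6),  # wrong prior
                       window_px = 20, slack_px = 8)
  expect_equal(res$center, known)
  expect_equal(res$score, 1.0)
  # oracle: exhaustive NCC over every possible placement
  best <- c(NA, NA); best_s <- -2
  for (r in 21:100) for (c in 21:100) {
    s <- ncc_score(tm, big[(r - 20):(r + 20), (c - 20):(c + 20)])
    if (!is.na(s) && s > best_s) { best_s <- s; best <- c(r, c) }
  }
  expect_equal(res$center, best)
})

test_that("zero-variance windows give an undefined-correlation error", {
  flat <- sensor_image(matrix(1, 50, 50), "B")
  tex <- sensor_image(matrix(stats::runif(2500), 50, 50), "B")
  marker <- list(center = c(25, 25), radius = 4, score = 1,
                 source_channel = "B")
  expect_error(refine_by_ncc(flat, tex, marker, window_px = 6, slack_px = 3),
               "zero-variance template")
  expect_error(refine_by_ncc(tex, flat, marker, window_px = 6, slack_px = 3),
               "undefined correlation")
})

test_that("NCC score is invariant to affine intensity changes", {
  set.seed(41)
  a <- matrix(stats::runif(225), 15, 15)
  b <- matrix(stats::runif(225), 15, 15)
  s0 <- ncc_score(a, b)
  for (gain in c(0.3, 2.5, 40)) for (offset in c(-3, 0, 11)) {
    expect_equal(ncc_score(a, gain * b + offset), s0, tolerance = 1e-9)
  }
  expect_equal(ncc_score(a, -1 * b), -s0, tolerance = 1e-9)
})

test_that("projective fit is exact for identity and known homographies", {
  pts <- cbind(c(1, 1, 100, 100), c(1, 80, 1, 80))
  m <- fit_projective(pts, pts)
  expect_equal(m$H, diag(3), tolerance = 1e-9)
  expect_equal(m$rmse, 0, tolerance = 1e-9)

  Ht <- matrix(c(0.98, 0.03, 12, -0.02, 1.05, -7, 3e-5, -1e-5, 1),
               3, 3, byrow = TRUE)
  set.seed(13)
  src <- cbind(stats::runif(8, 1, 400), stats::runif(8, 1, 500))
  m2 <- fit_projective(src, apply_homography(Ht, src))
  expect_lt(max(abs(m2$H - Ht)), 1e-6)
  expect_lt(m2$rmse, 1e-9)  # consistent correspondences leave no residual
})

test_that("degenerate correspondence sets are rejected", {
  line <- cbind(1:4, 2 * (1:4) + 3)
  expect_error(fit_projective(line, line), "collinear")
  expect_error(fit_projective(cbind(1:3, 1:3), cbind(1:3, 1:3)), ">= 4")
  # four points, three of them collinear
  p <- cbind(c(1, 2, 3, 10), c(1, 2, 3, 1))
  expect_error(fit_projective(p, p), "collinear")
})

test_that("identity warp reproduces the source crop exactly", {
  set.seed(17)
  img <- sensor_image(matrix(stats::runif(60 * 70), 60, 70), "B")
  pts <- cbind(c(1, 1, 60, 60), c(1, 70, 1, 70))
  m <- fit_projective(pts, pts)
  out <- warp_to_aoi(img, m, c(40, 50))
  expect_equal(out$pixels[, , 1], img$pixels[1:40, 1:50, 1],
               tolerance = 1e-12)
})

test_that("warp followed by inverse warp restores a smooth image", {
  n <- 120
  g <- outer(seq_len(n), seq_len(n),
             function(r, c) 0.5 + 0.3 * sin(r / 12) * cos(c / 15))
  img <- sensor_image(g, "B")
  Ht <- matrix(c(1.02, 0.015, 4, -0.01, 0.985, -3, 2e-5, -1e-5, 1),
               3, 3, byrow = TRUE)
  set.seed(19)
  anchors <- cbind(stats::runif(8, 10, 110), stats::runif(8, 10, 110))
  fwd <- fit_projective(anchors, apply_homography(Ht, anchors))
  bwd <- fit_projective(apply_homography(Ht, anchors), anchors)
  there <- warp_to_aoi(img, fwd, c(n, n))
  back <- warp_to_aoi(there, bwd, c(n, n))
  core <- 20:100
  diff <- abs(back$pixels[core, core, 1] - g[core, core])
  expect_lt(mean(diff, na.rm = TRUE), 0.01 * diff(range(g)))
})

test_that("a warp that misses the source yields all-invalid output", {
  img <- sensor_image(matrix(0.5, 30, 30), "B")
  pts <- cbind(c(1, 1, 30, 30), c(1, 30, 1, 30))
  # model translating the source far outside the AoI window
  m <- fit_projective(pts, pts + 500)
  out <- warp_to_aoi(img, m, c(30, 30))
  expect_true(all(is.na(out$pixels)))
  ndvi <- compute_ndvi(out$pixels[, , 1], out$pixels[, , 1])
  mask <- segment_ndvi(ndvi, out$pixels[, , 1],
                       segmentation_config(intensity_threshold = 0.2))
  lab <- matrix(1L, 30, 30)
  attr(lab, "plot_ids") <- "p1"
  rec <- extract_plot_traits(ndvi, mask, lab)
  expect_equal(rec$error, "no valid pixels in plot")
})

test_that("thermal upscaling preserves temperatures", {
  const <- sensor_image(matrix(25.0, 20, 30), "T", units = "celsius")
  same <- upscale_thermal(const, c(20, 30))
  expect_identical(same$pixels, const$pixels)
  up <- upscale_thermal(const, c(120, 180))
  expect_true(all(abs(up$pixels - 25.0) < 1e-12))
  expect_equal(mean(up$pixels), 25.0, tolerance = 1e-3)  # mean preserved

  ramp <- sensor_image(outer(seq(10, 30, length.out = 25), rep(1, 40)),
                       "T", units = "celsius")
  up2 <- upscale_thermal(ramp, c(50, 80))
  # a linear field stays linear under bilinear resampling
  col1 <- up2$pixels[, 1, 1]
  expect_lt(max(abs(diff(diff(col1)))), 1e-6)
  expect_equal(range(col1), c(10, 30), tolerance = 1e-9)

  expect_error(upscale_thermal(ramp, c(10, 40)), "downscal")
})

test_that("marker matching survives cyclic rotation and scale change", {
  ref <- rbind(c(10, 10), c(10, 100), c(100, 100), c(100, 10),
               c(10, 55), c(55, 100), c(100, 55), c(55, 10))
  # detections in another frame: scaled, slightly rotated, shuffled
  th <- 0.02
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  det_pts <- t(R %*% t(ref * 1.4)) + 7
  set.seed(23)
  shuffle <- sample(8)
  markers <- lapply(shuffle, function(i)
    list(center = det_pts[i, ], radius = 5, score = 1 - i / 100,
         source_channel = "B"))
  matched <- match_markers(markers, ref)
  got <- t(vapply(matched, `[[`, numeric(2), "center"))
  expect_equal(got, det_pts, tolerance = 1e-9, ignore_attr = TRUE)
})
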