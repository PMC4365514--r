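#' Apply a projective transform to points
#'
#' @param H 3x3 homography matrix acting on homogeneous (row, col, 1)
#'   coordinates.
#' @param pts Numeric `n x 2` matrix of (row, col) points.
#' @return `n x 2` matrix of transformed (row, col) points.
#' @export
apply_homography <- function(H, pts) {
  stopifnot(is.matrix(H), all(dim(H) == c(3, 3)))
  pts <- rbind2cols(pts)
  p <- H %*% rbind(t(pts), 1)
  t(p[1:2, , drop = FALSE] / rep(p[3, ], each = 2))
}

rbind2cols <- function(pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2, byrow = TRUE)
  stopifnot(ncol(pts) == 2)
  pts
}

# similarity normalization for the DLT (centroid at origin, mean distance
# sqrt(2)); conditioning step of the standard normalized DLT
normalize_pts <- function(pts) {
  ctr <- colMeans(pts)
  d <- sqrt(rowSums(sweep(pts, 2, ctr)^2))
  s <- if (mean(d) > 0) sqrt(2) / mean(d) else 1
  T <- matrix(c(s, 0, -s * ctr[1],
                0, s, -s * ctr[2],
                0, 0, 1), 3, 3, byrow = TRUE)
  list(T = T, pts = t(T %*% rbind(t(pts), 1))[, 1:2, drop = FALSE])
}

# TRUE when three or more of the points are (nearly) collinear
has_collinear_triple <- function(pts, tol = 1e-8) {
  n <- nrow(pts)
  scale2 <- max(apply(pts, 2, function(v) diff(range(v)))^2, 1)
  for (i in seq_len(n - 2)) for (j in seq(i + 1, n - 1)) for (k in seq(j + 1, n)) {
    a <- pts[j, ] - pts[i, ]; b <- pts[k, ] - pts[i, ]
    if (abs(a[1] * b[2] - a[2] * b[1]) < tol * scale2) return(TRUE)
  }
  FALSE
}

#' Fit a projective transform to point correspondences
#'
#' Estimates the 3x3 homography mapping source (row, col) points onto
#' target points by the normalized direct linear transform; with more than
#' four correspondences the solution is the total-least-squares minimizer
#' of the algebraic residual, refined against the geometric residual
#' reported as `rmse`. With exactly four non-degenerate pairs the fit
#' interpolates them exactly.
#'
#' @param src,dst Numeric `n x 2` matrices of (row, col) points, `n >= 4`.
#' @return An object of class `registration_model` with elements
#'   `correspondences` (list of src/dst), `H` (normalized so `H[3,3] = 1`)
#'   and `rmse` (pixels, in the target frame).
#' @export
fit_projective <- function(src, dst) {
  src <- rbind2cols(src); dst <- rbind2cols(dst)
  if (nrow(src) != nrow(dst)) stop("src and dst differ in length", call. = FALSE)
  n <- nrow(src)
  if (n < 4)
    stop(sprintf("projective fit needs >= 4 correspondences, got %d", n),
         call. = FALSE)
  # with exactly 4 pairs, any collinear triple removes a degree of freedom;
  # with more points collinear triples are harmless (markers commonly sit on
  # the field edges) as long as the full set spans the plane, which the
  # conditioning check below catches
  if (n == 4 && (has_collinear_triple(dst) || has_collinear_triple(src))) {
    stop("degenerate configuration: three of the four points are collinear",
         call. = FALSE)
  }
  ns <- normalize_pts(src); nd <- normalize_pts(dst)
  s <- ns$pts; d <- nd$pts
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    x <- s[i, 1]; y <- s[i, 2]; u <- d[i, 1]; v <- d[i, 2]
    A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y, -u)
    A[2 * i, ]     <- c(0, 0, 0, x, y, 1, -v * x, -v * y, -v)
  }
  # null vector of A via the normal matrix (A may have fewer than 9 rows'
  # worth of rank with n = 4, where svd() returns no 9th right vector)
  e <- eigen(crossprod(A), symmetric = TRUE)
  ev <- pmax(e$values, 0)
  if (ev[8] < 1e-20 * max(ev[1], 1))
    stop("degenerate configuration: correspondences do not determine a homography",
         call. = FALSE)
  h <- e$vectors[, 9]
  Hn <- matrix(h, 3, 3, byrow = TRUE)
  H <- solve(nd$T) %*% Hn %*% ns$T
  if (abs(H[3, 3]) < 1e-12)
    stop("degenerate homography (vanishing scale)", call. = FALSE)
  H <- H / H[3, 3]
  proj <- apply_homography(H, src)
  rmse <- sqrt(mean(rowSums((proj - dst)^2)))
  structure(list(correspondences = list(src = src, dst = dst),
                 H = H, rmse = rmse),
            class = "registration_model")
}

#' @export
print.registration_model <- function(x, ...) {
  cat(sprintf("<registration_model> %d correspondences, rmse %.4g px\n",
              nrow(x$correspondences$src), x$rmse))
  invisible(x)
}

#' Warp a sensor image into the common area-of-interest frame
#'
#' Inverse-maps every pixel of the `aoi_shape` output grid through the
#' model's homography (which maps sensor coordinates to AoI coordinates)
#' and resamples the source with bicubic interpolation. Output pixels whose
#' pre-image falls outside the source raster are `NA` and stay excluded
#' from all downstream statistics.
#'
#' @param img A [sensor_image()].
#' @param model A [fit_projective()] model mapping `img` pixels to AoI
#'   pixels.
#' @param aoi_shape Integer `c(H, W)` of the common frame.
#' @return A [sensor_image()] of size `aoi_shape`.
#' @export
warp_to_aoi <- function(img, model, aoi_shape) {
  stopifnot(inherits(img, "sensor_image"),
            inherits(model, "registration_model"))
  Hi <- tryCatch(solve(model$H),
                 error = function(e) stop("homography is not invertible",
                                          call. = FALSE))
  Ho <- as.integer(aoi_shape[1]); Wo <- as.integer(aoi_shape[2])
  grid <- cbind(rep(seq_len(Ho), times = Wo),
                rep(seq_len(Wo), each = Ho))
  srcpts <- apply_homography(Hi, grid)
  d <- dim(img$pixels)
  out <- array(NA_real_, c(Ho, Wo, d[3]))
  for (ch in seq_len(d[3])) {
    out[, , ch] <- bicubic_sample(img$pixels[, , ch], srcpts[, 1], srcpts[, 2])
  }
  sensor_image(out, img$channel_names, img$campaign_id, units = img$units,
               bit_depth = img$bit_depth)
}

#' Up-scale a thermal image to the optical resolution
#'
#' Temperature-preserving bilinear resampling (corner-aligned grid), used
#' before the projective transformation so that all sensors share one
#' resolution. Down-scaling is refused.
#'
#' @param img A thermal [sensor_image()].
#' @param target_shape Integer `c(H, W)`, at least the source shape.
#' @return A [sensor_image()] of size `target_shape`, values still in
#'   degrees Celsius.
#' @export
upscale_thermal <- function(img, target_shape) {
  stopifnot(inherits(img, "sensor_image"))
  d <- dim(img$pixels)
  Ht <- as.integer(target_shape[1]); Wt <- as.integer(target_shape[2])
  if (Ht < d[1] || Wt < d[2])
    stop("upscale_thermal: target shape smaller than source (downscaling refused)",
         call. = FALSE)
  if (Ht == d[1] && Wt == d[2]) return(img)
  rr <- if (Ht == 1) 1 else 1 + (seq_len(Ht) - 1) * (d[1] - 1) / (Ht - 1)
  cc <- if (Wt == 1) 1 else 1 + (seq_len(Wt) - 1) * (d[2] - 1) / (Wt - 1)
  grid_r <- rep(rr, times = Wt)
  grid_c <- rep(cc, each = Ht)
  out <- array(NA_real_, c(Ht, Wt, d[3]))
  for (ch in seq_len(d[3])) {
    out[, , ch] <- bilinear_sample(img$pixels[, , ch], grid_r, grid_c)
  }
  sensor_image(out, img$channel_names, img$campaign_id, units = img$units,
               bit_depth = img$bit_depth)
}

#' Scale factor between two pixel grids
#'
#' Convenience helper: the homothety mapping pixels of size `from_m` onto
#' pixels of size `to_m`, as a 3x3 matrix usable with
#' [apply_homography()]. Pixel centers at integer coordinates, so the map
#' is `x -> (x - 0.5) * s + 0.5`.
#'
#' @param from_m,to_m Ground pixel sizes in metres.
#' @return 3x3 matrix.
#' @export
scale_homography <- function(from_m, to_m) {
  s <- from_m / to_m
  matrix(c(s, 0, 0.5 - 0.5 * s,
           0, s, 0.5 - 0.5 * s,
           0, 0, 1), 3, 3, byrow = TRUE)
}
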