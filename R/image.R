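#' Multi-channel sensor image
#'
#' In-memory container for one calibrated raster from one camera. Pixels
#' are stored as an `H x W x C` numeric array in (row, col, channel) order;
#' pixel centers sit at integer (row, col) coordinates starting at 1.
#' Optical channels hold digital numbers rescaled to `[0, 1]` (16-bit DN /
#' 65535); the thermal channel holds degrees Celsius. Pixels that fall
#' outside the source during warping are `NA` and are excluded from all
#' downstream statistics.
#'
#' @param pixels Numeric matrix (`H x W`) or array (`H x W x C`).
#' @param channel_names Character vector naming the channels, e.g.
#'   `c("R","G","B")`, `c("B","NIR")` or `"T"`.
#' @param campaign_id Campaign label.
#' @param units Per-channel units, `"dn"` (rescaled digital number) or
#'   `"celsius"`; recycled across channels.
#' @param bit_depth Nominal bit depth of the source file.
#' @return An object of class `sensor_image`.
#' @export
sensor_image <- function(pixels, channel_names, campaign_id = "c1",
                         units = "dn", bit_depth = 16L) {
  if (is.matrix(pixels)) dim(pixels) <- c(dim(pixels), 1L)
  stopifnot(is.array(pixels), length(dim(pixels)) == 3)
  if (dim(pixels)[3] != length(channel_names))
    stop("channel count does not match channel_names", call. = FALSE)
  if (dim(pixels)[1] < 1 || dim(pixels)[2] < 1)
    stop("image must have at least one pixel", call. = FALSE)
  units <- rep_len(units, length(channel_names))
  th <- which(units == "celsius")
  if (length(th) && any(is.infinite(pixels[, , th])))
    stop("thermal channel contains non-finite values", call. = FALSE)
  structure(list(pixels = pixels,
                 channel_names = as.character(channel_names),
                 campaign_id = campaign_id,
                 units = units,
                 bit_depth = as.integer(bit_depth)),
            class = "sensor_image")
}

#' @export
print.sensor_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<sensor_image> %d x %d px, channels [%s], campaign %s\n",
              d[1], d[2], paste(x$channel_names, collapse = ","),
              x$campaign_id))
  invisible(x)
}

#' @export
dim.sensor_image <- function(x) dim(x$pixels)

#' Extract one channel of a sensor image as a matrix
#'
#' @param img A [sensor_image()].
#' @param name Channel name.
#' @return Numeric `H x W` matrix.
#' @export
get_channel <- function(img, name) {
  stopifnot(inherits(img, "sensor_image"))
  i <- match(name, img$channel_names)
  if (is.na(i))
    stop(sprintf("channel '%s' not present (have: %s)", name,
                 paste(img$channel_names, collapse = ",")), call. = FALSE)
  img$pixels[, , i]
}

# Cubic convolution kernel (Keys, a = -0.5), the classical bicubic weight.
cubic_kernel <- function(x) {
  ax <- abs(x)
  w <- numeric(length(x))
  i1 <- ax <= 1
  w[i1] <- (1.5 * ax[i1] - 2.5) * ax[i1]^2 + 1
  i2 <- ax > 1 & ax < 2
  w[i2] <- ((-0.5 * ax[i2] + 2.5) * ax[i2] - 4) * ax[i2] + 2
  w
}

#' Sample a matrix at real-valued positions with bicubic interpolation
#'
#' Positions use the package pixel convention (centers at integer
#' (row, col), first pixel at (1, 1)). Positions outside the matrix extent
#' return `NA`; border pixels are handled by edge clamping of the 4x4
#' neighbourhood.
#'
#' @param mat Numeric matrix.
#' @param r,c Numeric vectors of row/column positions (same length).
#' @return Numeric vector of interpolated values.
#' @export
bicubic_sample <- function(mat, r, c) {
  stopifnot(is.matrix(mat), length(r) == length(c))
  H <- nrow(mat); W <- ncol(mat)
  out <- rep(NA_real_, length(r))
  tol <- 1e-6  # boundary positions within rounding noise stay valid
  ok <- is.finite(r) & is.finite(c) &
    r >= 1 - tol & r <= H + tol & c >= 1 - tol & c <= W + tol
  if (!any(ok)) return(out)
  r <- pmin(pmax(r[ok], 1), H); c <- pmin(pmax(c[ok], 1), W)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  acc <- numeric(length(r))
  wrs <- lapply(-1:2, function(i) cubic_kernel(fr - i))
  wcs <- lapply(-1:2, function(j) cubic_kernel(fc - j))
  for (i in -1:2) {
    ri <- pmin(pmax(r0 + i, 1), H)
    for (j in -1:2) {
      cj <- pmin(pmax(c0 + j, 1), W)
      acc <- acc + wrs[[i + 2]] * wcs[[j + 2]] * mat[cbind(ri, cj)]
    }
  }
  out[ok] <- acc
  out
}

#' Sample a matrix at real-valued positions with bilinear interpolation
#'
#' Same conventions as [bicubic_sample()].
#'
#' @inheritParams bicubic_sample
#' @return Numeric vector of interpolated values.
#' @export
bilinear_sample <- function(mat, r, c) {
  stopifnot(is.matrix(mat), length(r) == length(c))
  H <- nrow(mat); W <- ncol(mat)
  out <- rep(NA_real_, length(r))
  tol <- 1e-6
  ok <- is.finite(r) & is.finite(c) &
    r >= 1 - tol & r <= H + tol & c >= 1 - tol & c <= W + tol
  if (!any(ok)) return(out)
  r <- pmin(pmax(r[ok], 1), H); c <- pmin(pmax(c[ok], 1), W)
  r0 <- pmin(floor(r), H - 1L); c0 <- pmin(floor(c), W - 1L)
  r0 <- pmax(r0, 1L); c0 <- pmax(c0, 1L)
  fr <- r - r0; fc <- c - c0
  v <- (1 - fr) * (1 - fc) * mat[cbind(r0, c0)] +
    (1 - fr) * fc * mat[cbind(r0, c0 + 1L)] +
    fr * (1 - fc) * mat[cbind(r0 + 1L, c0)] +
    fr * fc * mat[cbind(r0 + 1L, c0 + 1L)]
  out[ok] <- v
  out
}

#' Read a sensor image from a TIFF file
#'
#' 16-bit integer TIFFs (optical digital numbers) are returned on the
#' `[0, 1]` scale. 32-bit float thermal TIFFs store temperature through
#' the fixed affine map `(T + 50) / 150` (valid for -50 to 100 degrees C,
#' resolution far below the sensor's 0.03 K) and are converted back to
#' degrees Celsius on reading.
#'
#' @param path Path to the TIFF file.
#' @param channel_names Channel names, in file order.
#' @param campaign_id Campaign label.
#' @param units `"dn"` or `"celsius"` (recycled).
#' @return A [sensor_image()].
#' @export
read_sensor_tiff <- function(path, channel_names, campaign_id = "c1",
                             units = "dn") {
  x <- tiff::readTIFF(path)
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  if (dim(x)[3] > length(channel_names))  # drop padding channels
    x <- x[, , seq_along(channel_names), drop = FALSE]
  if (!all(units == "dn")) x <- x * 150 - 50  # stored (T + 50)/150
  sensor_image(x, channel_names, campaign_id, units = units,
               bit_depth = if (all(units == "dn")) 16L else 32L)
}

#' Write a sensor image to a TIFF file
#'
#' Optical images ("dn" units, values in `[0, 1]`) are written as 16-bit
#' integer TIFF; thermal images as 32-bit float holding `(T + 50) / 150`
#' (see [read_sensor_tiff()]). `NA` pixels are written as the sentinel
#' value passed in `na_value`.
#'
#' @param img A [sensor_image()].
#' @param path Output path.
#' @param na_value Sentinel written for invalid pixels.
#' @return `path`, invisibly.
#' @export
write_sensor_tiff <- function(img, path, na_value = 0) {
  stopifnot(inherits(img, "sensor_image"))
  px <- img$pixels
  px[is.na(px)] <- if (all(img$units == "dn")) na_value else -50
  dimnames(px) <- NULL
  dim(px) <- unname(dim(px))
  # two-channel rasters are padded to three: gray+alpha TIFFs are widely
  # misread (the second sample is treated as transparency)
  if (dim(px)[3] == 2) {
    px <- array(c(px, matrix(0, dim(px)[1], dim(px)[2])),
                c(dim(px)[1:2], 3))
  }
  if (all(img$units == "dn")) {
    px[] <- pmin(pmax(px, 0), 1)
    tiff::writeTIFF(drop3(px), path, bits.per.sample = 16L,
                    compression = "none")
  } else {
    px <- pmin(pmax((px + 50) / 150, 0), 1)
    tiff::writeTIFF(drop3(px), path, bits.per.sample = 32L,
                    compression = "none")
  }
  invisible(path)
}

# drop a trailing singleton channel dimension (writeTIFF wants a matrix
# for single-channel images)
drop3 <- function(a) if (length(dim(a)) == 3 && dim(a)[3] == 1)
  array(a, dim(a)[1:2]) else a
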