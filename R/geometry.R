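#' Sensor specification
#'
#' Describes one camera of the aerial sensor array: focal length, pixel
#' counts and physical sensor dimensions along the long and short axes, and
#' the shutter duration. All optics arithmetic ([compute_ifov()],
#' [compute_footprint()], [compute_motion_blur()]) starts from this record.
#'
#' @param name Label for the sensor (e.g. `"nir"`, `"rgb"`, `"ir"`).
#' @param focal_length_mm Focal length of the lens in millimetres.
#' @param pixels Integer vector `c(long, short)`: pixel counts along the two
#'   sensor axes.
#' @param sensor_mm Numeric vector `c(long, short)`: physical sensor
#'   dimensions in millimetres.
#' @param shutter_ms Shutter (exposure) duration in milliseconds.
#' @return An object of class `sensor_spec`.
#' @examples
#' nir_sensor_spec()
#' @export
sensor_spec <- function(name, focal_length_mm, pixels, sensor_mm,
                        shutter_ms = 0) {
  stopifnot(length(pixels) == 2, length(sensor_mm) == 2)
  pixels <- as.integer(pixels)
  if (!is.character(name) || length(name) != 1)
    stop("'name' must be a single label", call. = FALSE)
  if (!is.finite(focal_length_mm) || focal_length_mm <= 0)
    stop("invalid sensor spec: focal length must be positive", call. = FALSE)
  if (any(pixels < 1))
    stop("invalid sensor spec: pixel counts must be integers >= 1",
         call. = FALSE)
  if (any(!is.finite(sensor_mm)) || any(sensor_mm <= 0))
    stop("invalid sensor spec: sensor dimensions must be positive",
         call. = FALSE)
  if (!is.finite(shutter_ms) || shutter_ms < 0)
    stop("invalid sensor spec: shutter must be >= 0", call. = FALSE)
  structure(list(name = name,
                 focal_length_mm = as.numeric(focal_length_mm),
                 pixels = pixels,
                 sensor_mm = as.numeric(sensor_mm),
                 shutter_ms = as.numeric(shutter_ms)),
            class = "sensor_spec")
}

#' @export
print.sensor_spec <- function(x, ...) {
  cat(sprintf("<sensor_spec '%s'> f=%g mm, %d x %d px, %g x %g mm, shutter %g ms\n",
              x$name, x$focal_length_mm, x$pixels[1], x$pixels[2],
              x$sensor_mm[1], x$sensor_mm[2], x$shutter_ms))
  invisible(x)
}

#' Built-in sensor specs for the reference camera array
#'
#' The three cameras of the handheld array: a modified two-channel
#' blue + near-infrared consumer camera ("nir"), a standard RGB consumer
#' camera ("rgb"), both with 60 mm lenses, and an industrial thermal
#' camera ("ir") with a 75 mm lens and a 50 ms shutter.
#'
#' @return A `sensor_spec`.
#' @name builtin_specs
NULL

#' @rdname builtin_specs
#' @export
nir_sensor_spec <- function()
  sensor_spec("nir", 60, c(4282L, 2848L), c(22.2, 14.8), shutter_ms = 1)

#' @rdname builtin_specs
#' @export
rgb_sensor_spec <- function()
  sensor_spec("rgb", 60, c(3898L, 2595L), c(22.2, 14.8), shutter_ms = 1)

#' @rdname builtin_specs
#' @export
ir_sensor_spec <- function()
  sensor_spec("ir", 75, c(640L, 480L), c(14.9, 11.2), shutter_ms = 50)

#' Flight parameters
#'
#' @param altitude_m Flight altitude above ground in metres.
#' @param ground_speed_kmh Ground speed in km/h.
#' @return An object of class `flight_params`.
#' @export
flight_params <- function(altitude_m, ground_speed_kmh = 0) {
  if (!is.finite(altitude_m) || altitude_m < 0)
    stop("altitude must be >= 0", call. = FALSE)
  if (!is.finite(ground_speed_kmh) || ground_speed_kmh < 0)
    stop("ground speed must be >= 0", call. = FALSE)
  structure(list(altitude_m = as.numeric(altitude_m),
                 ground_speed_kmh = as.numeric(ground_speed_kmh)),
            class = "flight_params")
}

#' Instantaneous field of view (ground size of one pixel)
#'
#' IFoV = (pixel dimension x distance) / focal length, i.e. the ground
#' extent covered by a single sensor pixel at a given flight altitude.
#' Full precision is returned; use [format_length()] for table-style
#' rounding.
#'
#' @param spec A [sensor_spec()].
#' @param altitude_m Distance to the ground in metres (>= 0).
#' @param axis `"long"` or `"short"` sensor axis.
#' @param pixel_pitch_mm Optional physical pixel pitch in millimetres; when
#'   given it overrides `sensor_mm/pixels` (some vendors quote the pitch
#'   directly rather than the sensor dimensions).
#' @return IFoV in metres.
#' @examples
#' compute_ifov(nir_sensor_spec(), 300)          # ~0.026 m
#' compute_ifov(rgb_sensor_spec(), 300)          # ~0.0285 m
#' @export
compute_ifov <- function(spec, altitude_m, axis = c("long", "short"),
                         pixel_pitch_mm = NULL) {
  stopifnot(inherits(spec, "sensor_spec"))
  axis <- match.arg(axis)
  if (!is.finite(altitude_m) || altitude_m < 0)
    stop("altitude must be >= 0", call. = FALSE)
  i <- if (axis == "long") 1L else 2L
  pitch_mm <- if (is.null(pixel_pitch_mm))
    spec$sensor_mm[i] / spec$pixels[i] else pixel_pitch_mm
  # pitch [mm] / focal [mm] is dimensionless; multiply by altitude [m]
  pitch_mm / spec$focal_length_mm * altitude_m
}

#' Ground footprint of one image
#'
#' Ground extent imaged in a single frame, plus the forward-motion blur for
#' the sensor's shutter duration at the flight's ground speed.
#'
#' @param spec A [sensor_spec()].
#' @param flight A [flight_params()].
#' @return A list of class `ground_footprint` with elements `ifov_long`,
#'   `ifov_short` (m), `length_ground`, `width_ground` (m), `blur_distance`
#'   (m) and `blur_pixels` (count; blur along the flight direction divided
#'   by the long-axis IFoV).
#' @examples
#' compute_footprint(nir_sensor_spec(), flight_params(300, 20))
#' @export
compute_footprint <- function(spec, flight) {
  stopifnot(inherits(spec, "sensor_spec"), inherits(flight, "flight_params"))
  h <- flight$altitude_m
  ifov_long <- compute_ifov(spec, h, "long")
  ifov_short <- compute_ifov(spec, h, "short")
  length_ground <- spec$sensor_mm[1] / spec$focal_length_mm * h
  width_ground <- spec$sensor_mm[2] / spec$focal_length_mm * h
  blur <- if (ifov_long > 0)
    compute_motion_blur(flight, spec$shutter_ms, ifov_long)
  else list(blur_distance = 0, blur_pixels = 0L)
  structure(list(ifov_long = ifov_long, ifov_short = ifov_short,
                 length_ground = length_ground, width_ground = width_ground,
                 blur_distance = blur$blur_distance,
                 blur_pixels = blur$blur_pixels),
            class = "ground_footprint")
}

#' Forward-motion blur
#'
#' Distance travelled during the shutter opening and the corresponding
#' smear expressed in ground pixels.
#'
#' @param flight A [flight_params()].
#' @param shutter_ms Shutter duration in milliseconds (>= 0).
#' @param ground_pixel_m Ground size of one pixel in metres (> 0).
#' @return List with `blur_distance` (m, full precision) and `blur_pixels`
#'   (nearest integer).
#' @examples
#' compute_motion_blur(flight_params(300, 20), 50, 0.1)  # 0.28 m, 3 px
#' @export
compute_motion_blur <- function(flight, shutter_ms, ground_pixel_m) {
  stopifnot(inherits(flight, "flight_params"))
  if (!is.finite(shutter_ms) || shutter_ms < 0)
    stop("shutter must be >= 0", call. = FALSE)
  if (!is.finite(ground_pixel_m) || ground_pixel_m <= 0)
    stop("ground pixel size must be > 0", call. = FALSE)
  speed_ms <- flight$ground_speed_kmh * 1000 / 3600
  blur_distance <- speed_ms * shutter_ms / 1000
  list(blur_distance = blur_distance,
       blur_pixels = as.integer(round(blur_distance / ground_pixel_m)))
}

#' Survey throughput extrapolation
#'
#' Total area of a hypothetical trial of `n_plots` plots and the imaging
#' time obtained by scaling a reference acquisition linearly with area.
#'
#' @param plot_len_m,plot_wid_m Plot dimensions in metres.
#' @param n_plots Number of plots.
#' @param reference_area_m2 Area of the reference survey in square metres.
#' @param reference_time_s Time taken to image the reference area, seconds.
#' @return List with `total_area_ha` (hectares) and `total_time_s` /
#'   `total_time_min` (the latter rounded to the nearest minute).
#' @examples
#' survey_throughput(1.5, 4.75, 20000, reference_area_m2 = 30 * 132,
#'                   reference_time_s = 10)
#' @export
survey_throughput <- function(plot_len_m, plot_wid_m, n_plots,
                              reference_area_m2 = 30 * 132,
                              reference_time_s = 10) {
  vals <- c(plot_len_m, plot_wid_m, n_plots, reference_time_s)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all survey arguments must be positive", call. = FALSE)
  if (!is.finite(reference_area_m2) || reference_area_m2 <= 0)
    stop("reference area must be > 0", call. = FALSE)
  total_area_m2 <- n_plots * plot_len_m * plot_wid_m
  total_time_s <- total_area_m2 / reference_area_m2 * reference_time_s
  list(total_area_ha = total_area_m2 / 1e4,
       total_time_s = total_time_s,
       total_time_min = as.integer(round(total_time_s / 60)))
}

#' Table-style rounding of a length
#'
#' Rounds a length in metres to a fixed number of decimals, the convention
#' used when printing footprint/IFoV summaries. All computational functions
#' return full precision; rounding is applied only for presentation.
#'
#' @param x Length(s) in metres.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
format_length <- function(x, digits = 3) round(x, digits)
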