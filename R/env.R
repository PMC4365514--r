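#' Thermal time (growing degree days)
#'
#' Accumulates `max(0, (t_max + t_min)/2 - t_base)` over a daily series.
#' Days whose mean temperature falls below the base contribute zero rather
#' than a negative amount, so the sum is non-decreasing in series length.
#'
#' @param weather Data frame with columns `t_max` and `t_min` in deg C (an
#'   optional `date` column is used in error messages).
#' @param t_base Base temperature in deg C (8 for maize).
#' @return Thermal time in degree days (deg C d).
#' @examples
#' thermal_time(data.frame(t_max = 20, t_min = 10))  # 7
#' @export
thermal_time <- function(weather, t_base = 8) {
  stopifnot(is.data.frame(weather), all(c("t_max", "t_min") %in% names(weather)))
  if (nrow(weather) == 0) stop("empty weather series", call. = FALSE)
  bad <- which(weather$t_max < weather$t_min)
  if (length(bad)) {
    day <- if ("date" %in% names(weather)) weather$date[bad[1]] else bad[1]
    stop(sprintf("t_max < t_min on day %s", day), call. = FALSE)
  }
  sum(pmax(0, (weather$t_max + weather$t_min) / 2 - t_base))
}

#' Saturation vapour pressure
#'
#' Magnus-type formula `SVP [Pa] = 610.7 * 10^(7.5 t / (237.3 + t))`.
#'
#' @param t_c Air temperature in deg C (must exceed -237.3).
#' @return Saturation vapour pressure in Pa.
#' @examples
#' svp(0)  # 610.7
#' @export
svp <- function(t_c) {
  if (any(!is.finite(t_c)) || any(t_c <= -237.3))
    stop("temperature out of domain (must be > -237.3 deg C)", call. = FALSE)
  610.7 * 10^(7.5 * t_c / (237.3 + t_c))
}

#' Vapour pressure deficit
#'
#' `VPD = ((100 - rH)/100) * SVP(t)`, reported in kPa.
#'
#' @param t_c Air temperature in deg C.
#' @param rh Relative humidity in percent, within \[0, 100\].
#' @return Vapour pressure deficit in kPa.
#' @examples
#' vpd(25.95, 51.25)
#' @export
vpd <- function(t_c, rh) {
  if (any(!is.finite(rh)) || any(rh < 0) || any(rh > 100))
    stop("relative humidity must be in [0, 100]", call. = FALSE)
  (100 - rh) / 100 * svp(t_c) / 1000
}

#' Leaf area index from leaf biomass
#'
#' Converts destructively sampled leaf fresh biomass to specific leaf
#' weight, `SLW [mg cm^-2] = biomass [g] / (SL [cm] * row_distance [cm]) *
#' 1000`, and then to leaf area index through the linear calibration
#' `LAI = (SLW - 3.96) / 27.4`. A negative LAI (SLW below the calibration
#' intercept) is clamped to 0 with a warning.
#'
#' @param leaf_biomass_g Leaf fresh biomass in grams (> 0).
#' @param sampling_length_cm Sampled row length in cm (> 0).
#' @param row_distance_cm Row spacing in cm (default 70).
#' @return List with `slw` (mg cm^-2) and `lai` (m^2 m^-2).
#' @examples
#' lai_from_biomass(200, 100)
#' @export
lai_from_biomass <- function(leaf_biomass_g, sampling_length_cm,
                             row_distance_cm = 70) {
  vals <- c(leaf_biomass_g, sampling_length_cm, row_distance_cm)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("biomass, sampling length and row distance must be positive",
         call. = FALSE)
  slw <- leaf_biomass_g / (sampling_length_cm * row_distance_cm) * 1000
  lai <- (slw - 3.96) / 27.4
  if (lai < 0) {
    warning("SLW below calibration intercept; LAI clamped to 0")
    lai <- 0
  }
  list(slw = slw, lai = lai)
}
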