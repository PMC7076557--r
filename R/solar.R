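#' Solar declination angle
#'
#' Cooper-type approximation of the sun's declination for a given day of
#' year: \eqn{\delta = 23.44 \sin(2\pi(284 + n)/365)} degrees. Smooth
#' annual cycle between -23.44 and +23.44 degrees; the 365-day
#' denominator is kept for leap years (error well under 0.1 degree).
#'
#' @param day_of_year integer day of year, 1--366 (vectorised).
#' @return Declination in degrees, same length as `day_of_year`.
#' @examples
#' solar_declination(172)  # June solstice, ~ +23.4
#' @export
solar_declination <- function(day_of_year) {
  if (!is.numeric(day_of_year) || anyNA(day_of_year))
    stop("`day_of_year` must be numeric and non-missing", call. = FALSE)
  if (any(day_of_year < 1 | day_of_year > 366))
    stop("`day_of_year` must lie in [1, 366]", call. = FALSE)
  23.44 * sin(2 * pi * (284 + day_of_year) / 365)
}

#' Astronomical day length
#'
#' Day length in hours for a latitude and day of year, from the sunrise
#' hour angle \eqn{\cos H = (\sin h_0 - \sin\phi \sin\delta) /
#' (\cos\phi \cos\delta)} with the geometric sun centre on the horizon
#' (`horizon = 0`, no atmospheric refraction) by default. The hour-angle
#' argument is clamped to \eqn{[-1, 1]} so polar day and polar night
#' return 24 and 0 hours.
#'
#' The 14.5 h photoperiod gate that blocks initiation of new broods is
#' evaluated on this quantity; the `horizon` offset (degrees below the
#' geometric horizon, e.g. -0.833 for civil sunrise conventions) shifts
#' the date at which a mid-latitude site crosses the gate by one to two
#' days and is exposed for that reason.
#'
#' @param latitude degrees north, in \[-90, 90\].
#' @param day_of_year integer day of year, 1--366 (vectorised; recycled
#'   against `latitude`).
#' @param horizon solar altitude of the horizon in degrees (default 0).
#' @return Day length in hours, in \[0, 24\].
#' @examples
#' day_length(46.37, 172)  # ~15.6 h at a Slovenian mid-latitude site
#' @export
day_length <- function(latitude, day_of_year, horizon = 0) {
  if (!is.numeric(latitude) || anyNA(latitude))
    stop("`latitude` must be numeric and non-missing", call. = FALSE)
  if (any(latitude < -90 | latitude > 90))
    stop("`latitude` must lie in [-90, 90]", call. = FALSE)
  delta <- solar_declination(day_of_year) * pi / 180
  phi <- latitude * pi / 180
  h0 <- horizon * pi / 180
  cos_h <- (sin(h0) - sin(phi) * sin(delta)) / (cos(phi) * cos(delta))
  cos_h <- pmin(1, pmax(-1, cos_h))
  2 * acos(cos_h) * 180 / pi / 15
}
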