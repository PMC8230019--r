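#' Daylength from latitude and day of year (FAO-56)
#'
#' Astronomical daylight hours computed with the FAO-56 formulas:
#' solar declination `delta = 0.409 sin(2 pi doy / 365 - 1.39)`, sunset hour
#' angle `ws = acos(-tan(lat) tan(delta))`, daylength `N = 24 ws / pi`.
#' The declination argument always uses a 365-day year; day 366 of a leap
#' year is treated as day 365. At latitudes where `|tan(lat) tan(delta)| > 1`
#' the argument is clamped, giving 0 or 24 h (polar night/day).
#'
#' @param latitude Latitude(s) in decimal degrees, in [-90, 90].
#' @param doy Day(s) of year, 1-366. Recycled against `latitude`.
#' @return Daylength in hours, in [0, 24].
#' @examples
#' compute_daylength(0, 100)       # ~12 h at the equator
#' compute_daylength(39.38, 172)   # ~14.8 h near the summer solstice
#' @export
compute_daylength <- function(latitude, doy) {
  if (any(abs(latitude) > 90)) {
    stop("latitude must be in [-90, 90] degrees", call. = FALSE)
  }
  doy <- as.integer(doy)
  if (any(doy < 1L | doy > 366L)) {
    stop("doy must be in [1, 366]", call. = FALSE)
  }
  doy[doy == 366L] <- 365L
  phi <- latitude * pi / 180
  delta <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  x <- pmin(pmax(-tan(phi) * tan(delta), -1), 1)
  24 / pi * acos(x)
}

#' Day of year of a calendar date
#' @param date A `Date` vector.
#' @return Integer day-of-year (1-366).
#' @keywords internal
date_doy <- function(date) {
  as.integer(format(date, "%j"))
}
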