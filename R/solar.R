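# Low-precision solar ephemeris (declination + equation of time + hour
# angle), vectorised over time.  Stated accuracy ~0.5 degrees, ample for
# hourly radiation modelling on 5-m terrain.

#' Solar altitude and azimuth
#'
#' Computes the sun's altitude above the horizon and azimuth (degrees
#' clockwise from north) for given coordinates and UTC times, using a
#' standard low-precision ephemeris (Fourier fits for declination and the
#' equation of time, then the hour angle).  Accuracy is about 0.5 degrees,
#' sufficient for hourly terrain radiation budgets.
#'
#' @param latitude degrees north, in \code{[-90, 90]}.
#' @param longitude degrees east (west negative).
#' @param time \code{POSIXct} time(s), UTC.
#' @return data.frame with columns \code{altitude} (degrees, negative below
#'   the horizon) and \code{azimuth} (degrees clockwise from north, in
#'   \code{[0, 360)}), one row per time.
#' @examples
#' noon <- as.POSIXct("2000-03-20 12:00:00", tz = "UTC")
#' solar_position(51, 0, noon)  # altitude ~ 39 deg, azimuth ~ 180 deg
#' @export
solar_position <- function(latitude, longitude, time) {
  if (abs(latitude) > 90) stop("latitude must be within [-90, 90]")
  t <- as.POSIXlt(time, tz = "UTC")
  doy <- t$yday
  hour <- t$hour + t$min / 60 + t$sec / 3600
  ndays <- ifelse((t$year + 1900) %% 4 == 0 &
                  ((t$year + 1900) %% 100 != 0 | (t$year + 1900) %% 400 == 0),
                  366, 365)
  g <- 2 * pi / ndays * (doy + (hour - 12) / 24)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                      0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  tst <- hour * 60 + eqtime + 4 * longitude        # true solar time, minutes
  ha <- (tst / 4 - 180) * pi / 180                 # hour angle, radians
  lat <- latitude * pi / 180
  sin_alt <- sin(lat) * sin(decl) + cos(lat) * cos(decl) * cos(ha)
  alt <- asin(pmin(1, pmax(-1, sin_alt)))
  east <- -cos(decl) * sin(ha)
  north <- cos(lat) * sin(decl) - sin(lat) * cos(decl) * cos(ha)
  az <- (atan2(east, north) * 180 / pi) %% 360
  data.frame(altitude = alt * 180 / pi, azimuth = az)
}
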