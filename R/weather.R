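# Synthetic hourly weather: seasonal + diurnal temperature cycles with AR(1)
# synoptic noise and per-year offsets (hot/cool summers), non-negative wind,
# and an hourly sunshine fraction forced to zero when the sun is down.

#' Configuration for the synthetic weather generator
#'
#' @param years calendar years to generate (hourly, UTC).
#' @param t_mean annual mean temperature (deg C).
#' @param seasonal_amp half peak-to-trough seasonal amplitude (deg C); the
#'   seasonal maximum falls on \code{peak_doy}.
#' @param peak_doy day of year of the seasonal temperature maximum.
#' @param diurnal_amp half peak-to-trough diurnal amplitude (deg C); the
#'   daily maximum falls at \code{peak_hour} (UTC).
#' @param peak_hour hour of the diurnal temperature maximum.
#' @param noise_sd standard deviation of the AR(1) synoptic temperature
#'   noise (deg C); must be >= 0.
#' @param noise_ar lag-1 autocorrelation of the synoptic noise, in [0, 1).
#' @param year_offsets named or unnamed numeric vector of per-year
#'   temperature offsets (deg C), recycled over \code{years}; models runs of
#'   hot and cool summers.
#' @param wind_mean,wind_sd mean and sd of hourly wind speed (m/s); wind is
#'   AR(1) with the same autocorrelation as temperature and truncated at 0.
#' @param sun_shape1,sun_shape2 beta-distribution parameters (> 0) for the
#'   hourly daytime sunshine fraction.
#' @param latitude,longitude site coordinates used to zero sunshine when the
#'   sun is below the horizon.
#' @param seed integer seed.
#' @return a list of class \code{synth_weather_config}.
#' @export
synth_weather_config <- function(years = 1982:1991,
                                 t_mean = 11, seasonal_amp = 7,
                                 peak_doy = 205, diurnal_amp = 4,
                                 peak_hour = 14, noise_sd = 2.5,
                                 noise_ar = 0.8, year_offsets = 0,
                                 wind_mean = 4, wind_sd = 2,
                                 sun_shape1 = 0.8, sun_shape2 = 0.8,
                                 latitude = 51.2, longitude = -0.5,
                                 seed = NULL) {
  stopifnot(length(years) >= 1, seasonal_amp >= 0, diurnal_amp >= 0,
            noise_sd >= 0, noise_ar >= 0, noise_ar < 1,
            sun_shape1 > 0, sun_shape2 > 0, wind_mean >= 0)
  structure(as.list(environment()), class = "synth_weather_config")
}

#' Generate a synthetic hourly weather series
#'
#' Temperature is a seasonal sinusoid plus a diurnal sinusoid plus AR(1)
#' synoptic noise plus a per-year offset.  Wind is AR(1) noise around its
#' mean, truncated at zero.  Sunshine fraction is drawn from a beta
#' distribution for daylight hours and is exactly zero when the sun is below
#' the horizon.  Identical configurations (including seed) give bit-identical
#' output.
#'
#' @param config a \code{\link{synth_weather_config}}.
#' @return an \code{hourly_weather} data.frame with columns \code{time}
#'   (POSIXct UTC, hourly), \code{temp_c}, \code{wind_ms}, \code{sun_frac}.
#' @export
generate_weather <- function(config) {
  stopifnot(inherits(config, "synth_weather_config"))
  cf <- config
  if (length(cf$years) == 0) stop("empty year list")
  offs <- rep_len(cf$year_offsets, length(cf$years))
  times <- do.call(c, lapply(cf$years, function(y) {
    seq(as.POSIXct(sprintf("%d-01-01 00:00:00", y), tz = "UTC"),
        as.POSIXct(sprintf("%d-12-31 23:00:00", y), tz = "UTC"), by = "hour")
  }))
  lt <- as.POSIXlt(times, tz = "UTC")
  n <- length(times)
  ydays_in <- ifelse(lt$year %% 4 == 0 &
                     (lt$year %% 100 != 0 | (lt$year + 1900) %% 400 == 0),
                     366, 365)
  frac_doy <- lt$yday + lt$hour / 24
  seasonal <- cf$t_mean +
    cf$seasonal_amp * cos(2 * pi * (frac_doy - cf$peak_doy) / ydays_in)
  diurnal <- cf$diurnal_amp * cos(2 * pi * (lt$hour - cf$peak_hour) / 24)
  yoff <- offs[match(lt$year + 1900, cf$years)]
  with_seed(cf$seed, {
    temp <- seasonal + diurnal + yoff + ar1_noise(n, cf$noise_sd, cf$noise_ar)
    wind <- pmax(0, cf$wind_mean + ar1_noise(n, cf$wind_sd, cf$noise_ar))
    sun <- rbeta(n, cf$sun_shape1, cf$sun_shape2)
    alt <- solar_position(cf$latitude, cf$longitude, times)$altitude
    sun[alt <= 0] <- 0
    structure(data.frame(time = times, temp_c = temp, wind_ms = wind,
                         sun_frac = sun),
              class = c("hourly_weather", "data.frame"))
  })
}

ar1_noise <- function(n, sd, ar) {
  if (sd == 0) return(numeric(n))
  e <- rnorm(n, 0, sd * sqrt(1 - ar^2))
  x0 <- rnorm(1, 0, sd)
  as.numeric(stats::filter(e, ar, method = "recursive", init = x0))
}

# Internal validator: strict hourly spacing and bounded fields.
validate_weather <- function(w) {
  stopifnot(inherits(w, "data.frame"),
            all(c("time", "temp_c", "wind_ms", "sun_frac") %in% names(w)),
            all(diff(as.numeric(w$time)) == 3600),
            all(w$wind_ms >= 0),
            all(w$sun_frac >= 0 & w$sun_frac <= 1))
  invisible(TRUE)
}
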