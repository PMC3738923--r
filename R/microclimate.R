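# Near-surface (10 cm) temperature over terrain: clear-sky direct/diffuse
# shortwave partition adjusted for sunshine fraction, slope, aspect and
# horizon shading; wind attenuated by a topographic shelter index; a
# two-parameter radiation/wind warming form; and August threshold-hour
# summaries per cell and per patch.

#' Microclimate model coefficients
#'
#' The warming of the 10-cm air layer over ambient is modelled as
#' \code{k1 * Q / (1 + k2 * u)} where \code{Q} is net shortwave irradiance
#' (W/m2) and \code{u} the shelter-adjusted local wind (m/s).  Defaults are
#' chosen so that sunlit, sheltered slopes exceed ambient by roughly 5-15
#' deg C, the behaviour observed in short chalk-grassland turf; all
#' coefficients are configuration-exposed.
#'
#' @param solar_constant extraterrestrial normal irradiance (W/m2).
#' @param transmittance clear-sky broadband transmittance (per unit optical
#'   air mass, approximated by 1/sin(altitude)).
#' @param diffuse_frac clear-sky diffuse fraction of global horizontal
#'   irradiance.
#' @param k1 radiation-to-warming gain (deg C per W/m2).
#' @param k2 wind damping of the warming (s/m).
#' @param shelter_c shelter response: local wind = ambient / (1 + c * s)
#'   with s the tangent of the upwind horizon angle.
#' @param wind_floor minimum local wind speed (m/s) under full shelter.
#' @return list of class \code{microclim_coeffs}.
#' @export
microclim_coeffs <- function(solar_constant = 1361, transmittance = 0.75,
                             diffuse_frac = 0.2, k1 = 0.015, k2 = 0.5,
                             shelter_c = 1, wind_floor = 0.1) {
  stopifnot(solar_constant > 0, transmittance > 0, transmittance <= 1,
            diffuse_frac >= 0, k1 >= 0, k2 >= 0, shelter_c >= 0,
            wind_floor >= 0)
  structure(as.list(environment()), class = "microclim_coeffs")
}

# Clear-sky direct-normal irradiance at a given solar altitude (deg).
clearsky_dni <- function(altitude, coeffs) {
  s <- sin(pmax(altitude, 0) * pi / 180)
  ifelse(altitude <= 0, 0, coeffs$solar_constant * coeffs$transmittance^(1 / s))
}

#' Net shortwave irradiance of a terrain cell
#'
#' Direct beam is clear-sky direct-normal irradiance times the sunshine
#' fraction times the cosine of the incidence angle on the tilted surface,
#' zeroed when the sun is below the cell's horizon angle in the solar
#' azimuth sector or when the incidence cosine is negative.  Diffuse is a
#' fixed fraction of clear-sky global horizontal irradiance times the
#' sky-view factor.  Vectorised over cells.
#'
#' @param slope,aspect cell slope (deg) and downslope azimuth (deg from
#'   north; \code{NA} allowed where slope is 0).
#' @param horizon_sun horizon angle (deg) in the solar azimuth sector.
#' @param svf sky-view factor in [0, 1] (e.g. mean of squared cosines of
#'   the sector horizon angles).
#' @param sun a one-row \code{\link{solar_position}} result (altitude,
#'   azimuth in degrees).
#' @param sun_frac sunshine fraction for the hour, in [0, 1].
#' @param coeffs a \code{\link{microclim_coeffs}}.
#' @return net shortwave irradiance, W/m2 (>= 0).
#' @export
cell_irradiance <- function(slope, aspect, horizon_sun, svf, sun, sun_frac,
                            coeffs = microclim_coeffs()) {
  stopifnot(sun_frac >= 0, sun_frac <= 1)
  alt <- sun$altitude; az <- sun$azimuth
  dni <- clearsky_dni(alt, coeffs)
  ghi <- dni * sin(pmax(alt, 0) * pi / 180)
  diffuse <- ifelse(alt <= 0, 0, coeffs$diffuse_frac * ghi * svf)
  b <- slope * pi / 180
  asp <- ifelse(is.na(aspect), 0, aspect) * pi / 180
  cosi <- cos(b) * sin(alt * pi / 180) +
    sin(b) * cos(alt * pi / 180) * cos((az * pi / 180) - asp)
  shaded <- alt <= horizon_sun
  direct <- ifelse(alt <= 0 | shaded | cosi < 0, 0,
                   dni * sun_frac * cosi)
  direct + diffuse
}

#' Shelter-adjusted local wind speed
#'
#' The shelter index is the tangent of the horizon angle in the upwind
#' sector; local wind is \code{ambient / (1 + c * s)}.  A horizon angle at
#' (or numerically near) 90 degrees is treated as full shelter and returns
#' the configured wind floor.
#'
#' @param horizon_upwind horizon angle (deg) in the direction the wind
#'   comes from; vectorised over cells.
#' @param wind ambient wind speed (m/s, >= 0).
#' @param coeffs a \code{\link{microclim_coeffs}}.
#' @return local wind speed, m/s.
#' @export
shelter_wind <- function(horizon_upwind, wind, coeffs = microclim_coeffs()) {
  stopifnot(all(wind >= 0))
  full <- horizon_upwind >= 90 - 1e-6
  s <- tan(pmin(horizon_upwind, 90 - 1e-6) * pi / 180)
  out <- wind / (1 + coeffs$shelter_c * s)
  out[full] <- coeffs$wind_floor
  out
}

#' Near-surface (10 cm) air temperature
#'
#' \code{T = ambient + k1 * Q / (1 + k2 * u)}: increasing in radiation,
#' decreasing in wind, and equal to ambient at zero radiation.
#'
#' @param ambient ambient air temperature (deg C).
#' @param net_radiation net shortwave irradiance (W/m2, >= 0).
#' @param local_wind shelter-adjusted wind (m/s).
#' @param coeffs a \code{\link{microclim_coeffs}}.
#' @return temperature at 10 cm, deg C.
#' @export
near_surface_temperature <- function(ambient, net_radiation, local_wind,
                                     coeffs = microclim_coeffs()) {
  if (any(net_radiation < 0)) stop("net_radiation must be >= 0")
  ambient + coeffs$k1 * net_radiation / (1 + coeffs$k2 * local_wind)
}

#' Count August hours above the activity threshold
#'
#' Strict inequality: an hour exactly at the threshold does not count.
#'
#' @param cell_temps hourly temperatures (deg C) covering all 744 August
#'   hours of one year.
#' @param threshold activity threshold (deg C, default 25).
#' @return integer count in [0, 744].
#' @export
threshold_hours <- function(cell_temps, threshold = 25) {
  if (length(cell_temps) != 744)
    stop("expected a complete August series of 744 hours")
  sum(cell_temps > threshold)
}

#' Thermal habitat quality of a patch
#'
#' The mean over a patch's member cells of the number of August hours above
#' the activity threshold.
#'
#' @param cell_hours numeric vector of per-cell threshold hours for the
#'   patch's member cells (length >= 1).
#' @return mean hours, in [0, 744].
#' @export
patch_thermal_quality <- function(cell_hours) {
  if (length(cell_hours) == 0) stop("patch has no member cells")
  mean(cell_hours)
}

#' Run the microclimate model over a terrain grid for one August
#'
#' For each August hour: solar position; per-cell net shortwave (direct
#' adjusted for sunshine fraction, slope, aspect and horizon shading in the
#' solar sector; diffuse by sky-view factor); wind attenuated by the
#' upwind-sector shelter index; near-surface temperature; and accumulation
#' of hours above the threshold.
#'
#' @param terrain a \code{terrain_grid}.
#' @param weather an \code{hourly_weather} covering August of \code{year}
#'   (other hours are ignored).
#' @param year calendar year whose August is evaluated.
#' @param latitude,longitude site coordinates (deg).
#' @param coeffs a \code{\link{microclim_coeffs}}.
#' @param threshold activity threshold (deg C, default 25).
#' @param wind_direction prevailing wind direction (deg from north, the
#'   direction the wind comes from; default 225, south-westerly).
#' @param cells optional two-column matrix/data.frame (\code{row},
#'   \code{col}) restricting computation to those cells; default all cells.
#' @return matrix (or vector when \code{cells} is given) of per-cell
#'   threshold hours.
#' @export
run_microclimate <- function(terrain, weather, year, latitude = 51.2,
                             longitude = -0.5,
                             coeffs = microclim_coeffs(), threshold = 25,
                             wind_direction = 225, cells = NULL) {
  validate_weather(weather)
  lt <- as.POSIXlt(weather$time, tz = "UTC")
  aug <- which(lt$year + 1900 == year & lt$mon == 7)
  if (length(aug) != 744)
    stop(sprintf("weather does not cover all 744 August hours of %d", year))
  nsec <- dim(terrain$horizon)[3]
  if (is.null(cells)) {
    idx <- seq_along(terrain$elevation)
    slope <- as.vector(terrain$slope)
    aspect <- as.vector(terrain$aspect)
    hor <- matrix(terrain$horizon, ncol = nsec)
  } else {
    cells <- as.matrix(cells[, c("row", "col")])
    idx <- cells[, 1] + (cells[, 2] - 1) * nrow(terrain$elevation)
    slope <- terrain$slope[idx]
    aspect <- terrain$aspect[idx]
    hor <- matrix(terrain$horizon, ncol = nsec)[idx, , drop = FALSE]
  }
  svf <- rowMeans(cos(hor * pi / 180)^2)
  up_sec <- azimuth_sector(wind_direction, nsec)
  shelter_s <- hor[, up_sec]
  sun <- solar_position(latitude, longitude, weather$time[aug])
  counts <- numeric(length(idx))
  for (h in seq_along(aug)) {
    i <- aug[h]
    sun_h <- list(altitude = sun$altitude[h], azimuth = sun$azimuth[h])
    hsec <- hor[, azimuth_sector(sun_h$azimuth, nsec)]
    q <- cell_irradiance(slope, aspect, hsec, svf, sun_h,
                         weather$sun_frac[i], coeffs)
    u <- shelter_wind(shelter_s, weather$wind_ms[i], coeffs)
    temp <- near_surface_temperature(weather$temp_c[i], q, u, coeffs)
    counts <- counts + (temp > threshold)
  }
  if (is.null(cells)) {
    matrix(counts, nrow(terrain$elevation), ncol(terrain$elevation))
  } else counts
}

# Nearest horizon sector index for an azimuth (sector centres at
# 0, 360/n, ...).
azimuth_sector <- function(azimuth, n_sectors) {
  1L + (as.integer(round(azimuth / (360 / n_sectors))) %% n_sectors)
}

#' Thermal quality table for a patch network
#'
#' Runs the microclimate model over each year's August on the patches'
#' member cells and returns per-patch mean threshold hours.
#'
#' @param network a \code{patch_network} whose cells index \code{terrain}.
#' @param terrain a \code{terrain_grid}.
#' @param weather an \code{hourly_weather} covering the requested years.
#' @param years integer vector of years.
#' @param ... passed to \code{\link{run_microclimate}}.
#' @return data.frame \code{patch_id}, \code{year}, \code{q_hours}.
#' @export
network_thermal_quality <- function(network, terrain, weather, years, ...) {
  res <- lapply(years, function(y) {
    hrs <- run_microclimate(terrain, weather, y, ...)
    q <- vapply(network$cells, function(cl) {
      patch_thermal_quality(hrs[as.matrix(cl[, c("row", "col")])])
    }, 0)
    data.frame(patch_id = network$patch_id, year = y, q_hours = q)
  })
  do.call(rbind, res)
}

#' Per-patch, per-year effective areas
#'
#' In microclimate mode the effective area is the patch area weighted by
#' thermal habitat quality normalised so the mean quality across all
#' patches and all calibration years equals 1; in habitat-area mode the
#' effective area is simply the patch area in every year.
#'
#' @param network a \code{patch_network}.
#' @param quality data.frame \code{patch_id}, \code{year}, \code{q_hours}
#'   covering all patches and years (required in microclimate mode).
#' @param calibration_years years over which mean quality is normalised to 1.
#' @param mode \code{"microclimate"} or \code{"habitat-area"}.
#' @param years years to emit in habitat-area mode when \code{quality} is
#'   absent.
#' @return data.frame \code{patch_id}, \code{year}, \code{a_eff_ha}.
#' @export
effective_areas <- function(network, quality = NULL,
                            calibration_years = NULL,
                            mode = c("microclimate", "habitat-area"),
                            years = NULL) {
  mode <- match.arg(mode)
  if (mode == "habitat-area") {
    yrs <- years %||% sort(unique(quality$year))
    if (length(yrs) == 0) stop("no years given")
    return(data.frame(
      patch_id = rep(network$patch_id, times = length(yrs)),
      year = rep(yrs, each = length(network$patch_id)),
      a_eff_ha = rep(network$area_ha, times = length(yrs))))
  }
  stopifnot(!is.null(quality), !is.null(calibration_years))
  miss <- setdiff(network$patch_id, quality$patch_id)
  if (length(miss)) stop("quality missing for some patches")
  cal <- quality[quality$year %in% calibration_years, ]
  if (!all(calibration_years %in% quality$year))
    stop("quality missing for some calibration years")
  qbar <- mean(cal$q_hours)
  if (qbar == 0) stop("mean thermal quality over the calibration window is 0")
  area <- network$area_ha[match(quality$patch_id, network$patch_id)]
  data.frame(patch_id = quality$patch_id, year = quality$year,
             a_eff_ha = area * quality$q_hours / qbar)
}
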