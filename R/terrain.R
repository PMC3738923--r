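# Terrain grids: elevation plus derived slope, aspect and horizon-angle
# layers.  Matrices are indexed [row, col] with row 1 the northern edge and
# column 1 the western edge; x increases east, y increases north.

#' Build a terrain grid from an elevation matrix
#'
#' Computes slope, aspect and per-sector horizon angles from an elevation
#' raster.  Slope and aspect use central differences (one-sided at edges);
#' the horizon angle in each azimuth sector is found by ray-marching from
#' each cell towards the grid edge.
#'
#' @param elevation numeric matrix of elevations (m); row 1 is the northern
#'   edge, column 1 the western edge.
#' @param resolution cell size in metres (default 5).
#' @param n_sectors number of azimuth sectors for the horizon profile
#'   (default 16).
#' @param max_horizon_m maximum ray length (m) searched for the horizon;
#'   relief further away than this is ignored (default 500).
#' @return an object of class \code{terrain_grid}: a list with elements
#'   \code{resolution}, \code{elevation}, \code{slope} (degrees),
#'   \code{aspect} (degrees clockwise from north of the downslope direction;
#'   \code{NA} where slope is zero), \code{horizon} (array
#'   \code{nrow x ncol x n_sectors}, degrees), and \code{sector_azimuth}
#'   (sector centre azimuths, degrees).
#' @export
terrain_from_elevation <- function(elevation, resolution = 5,
                                   n_sectors = 16, max_horizon_m = 500) {
  stopifnot(is.matrix(elevation), resolution > 0, n_sectors >= 4)
  if (nrow(elevation) < 3 || ncol(elevation) < 3)
    stop("elevation grid must be at least 3 x 3 cells")
  if (anyNA(elevation)) stop("elevation must have no missing cells")
  sa <- slope_aspect(elevation, resolution)
  hor <- horizon_angles(elevation, resolution, n_sectors, max_horizon_m)
  structure(list(
    resolution = resolution,
    elevation = elevation,
    slope = sa$slope,
    aspect = sa$aspect,
    horizon = hor,
    sector_azimuth = (seq_len(n_sectors) - 1) * 360 / n_sectors
  ), class = "terrain_grid")
}

#' Generate a synthetic ridge-and-valley terrain grid
#'
#' Elevation is a sinusoidal ridge--valley surface (ridges running
#' north--south) plus seeded smooth noise built from random-phase sinusoids,
#' which keeps slopes and aspects analytically checkable while providing
#' realistic topographic variety.
#'
#' @param extent_m extent in metres, length-2 (x, y) or a single value for a
#'   square grid.
#' @param relief_m peak-to-trough relief of the sinusoidal component (m).
#' @param wavelength_m ridge-to-ridge wavelength (m); must be positive.
#' @param resolution_m cell size (m, default 5); extents must be divisible by
#'   it.
#' @param seed integer seed for the noise component.
#' @param noise_relief_m amplitude scale of the smooth noise component
#'   (default \code{relief_m / 5}).
#' @inheritParams terrain_from_elevation
#' @return a \code{terrain_grid}; see \code{\link{terrain_from_elevation}}.
#' @examples
#' tg <- generate_terrain(c(250, 250), relief_m = 30, wavelength_m = 200,
#'                        seed = 1)
#' range(tg$slope)
#' @export
generate_terrain <- function(extent_m, relief_m, wavelength_m,
                             resolution_m = 5, seed = NULL,
                             noise_relief_m = relief_m / 5,
                             n_sectors = 16, max_horizon_m = 500) {
  if (length(extent_m) == 1) extent_m <- c(extent_m, extent_m)
  if (wavelength_m <= 0) stop("wavelength_m must be positive")
  if (relief_m < 0) stop("relief_m must be non-negative")
  if (any(extent_m %% resolution_m != 0))
    stop("extent_m must be divisible by resolution_m")
  nc <- extent_m[1] / resolution_m
  nr <- extent_m[2] / resolution_m
  if (nr < 3 || nc < 3) stop("extent smaller than 3 x 3 cells")
  x <- (seq_len(nc) - 0.5) * resolution_m
  y <- (nr - seq_len(nr) + 0.5) * resolution_m   # row 1 = north
  elev <- matrix(rep(relief_m / 2 * sin(2 * pi * x / wavelength_m),
                     each = nr), nr, nc)
  if (noise_relief_m > 0) {
    elev <- elev + with_seed(seed, {
      z <- matrix(0, nr, nc)
      for (k in 1:6) {  # random-phase smooth waves at a few wavelengths
        wl <- wavelength_m * runif(1, 0.6, 3)
        th <- runif(1, 0, 2 * pi); ph <- runif(1, 0, 2 * pi)
        amp <- noise_relief_m / 2 * runif(1, 0.3, 1)
        z <- z + amp * sin(2 * pi * (outer(y, x * 0, "+") * sin(th) +
                                     outer(y * 0, x, "+") * cos(th)) / wl + ph)
      }
      z
    })
  }
  terrain_from_elevation(elev, resolution_m, n_sectors, max_horizon_m)
}

# Central-difference slope/aspect.  Aspect is the downslope azimuth,
# degrees clockwise from north; NA where the gradient is zero.
slope_aspect <- function(elev, res) {
  nr <- nrow(elev); nc <- ncol(elev)
  gx <- matrix(0, nr, nc); gy <- matrix(0, nr, nc)
  gx[, 2:(nc - 1)] <- (elev[, 3:nc] - elev[, 1:(nc - 2)]) / (2 * res)
  gx[, 1] <- (elev[, 2] - elev[, 1]) / res
  gx[, nc] <- (elev[, nc] - elev[, nc - 1]) / res
  # row index increases southwards, so d(elev)/dy(north) flips the sign
  gy[2:(nr - 1), ] <- (elev[1:(nr - 2), ] - elev[3:nr, ]) / (2 * res)
  gy[1, ] <- (elev[1, ] - elev[2, ]) / res
  gy[nr, ] <- (elev[nr - 1, ] - elev[nr, ]) / res
  slope <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  aspect <- (atan2(-gx, -gy) * 180 / pi) %% 360
  aspect[slope == 0] <- NA_real_
  list(slope = slope, aspect = aspect)
}

# Horizon angle per azimuth sector by marching rays outward from every cell
# simultaneously (whole-grid shifts).  Angles are >= 0 (an open horizon at or
# below the cell's own elevation gives 0).
horizon_angles <- function(elev, res, n_sectors, max_horizon_m) {
  nr <- nrow(elev); nc <- ncol(elev)
  n_steps <- max(1L, floor(max_horizon_m / res))
  hor <- array(0, dim = c(nr, nc, n_sectors))
  az <- (seq_len(n_sectors) - 1) * 2 * pi / n_sectors
  for (s in seq_len(n_sectors)) {
    dx <- sin(az[s]); dy <- cos(az[s])
    best <- matrix(0, nr, nc)
    for (k in seq_len(n_steps)) {
      oc <- round(k * dx)           # column offset (east)
      or_ <- -round(k * dy)         # row offset (north = decreasing row)
      if (abs(oc) >= nc && abs(or_) >= nr) break
      dist <- res * sqrt((k * dx)^2 + (k * dy)^2)
      shifted <- shift_matrix(elev, or_, oc)
      ang <- atan((shifted - elev) / dist)
      ang[is.na(ang)] <- -Inf
      best <- pmax(best, ang)
    }
    hor[, , s] <- pmin(best, pi / 2 - 1e-9) * 180 / pi
  }
  hor
}

# Shift a matrix by (dr, dc); vacated cells become NA.
shift_matrix <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
  rok <- rs >= 1 & rs <= nr; cok <- cs >= 1 & cs <= nc
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

#' @export
print.terrain_grid <- function(x, ...) {
  cat(sprintf(
    "terrain_grid: %d x %d cells at %g m (%g x %g m), %d horizon sectors\n",
    nrow(x$elevation), ncol(x$elevation), x$resolution,
    ncol(x$elevation) * x$resolution, nrow(x$elevation) * x$resolution,
    dim(x$horizon)[3]))
  cat(sprintf("  elevation %0.1f..%0.1f m, slope 0..%0.1f deg\n",
              min(x$elevation), max(x$elevation), max(x$slope)))
  invisible(x)
}

# Internal validator used by tests and the pipeline.
validate_terrain <- function(tg) {
  stopifnot(inherits(tg, "terrain_grid"),
            all(tg$slope >= 0 & tg$slope < 90),
            all(is.na(tg$aspect) | (tg$aspect >= 0 & tg$aspect < 360)),
            all(tg$horizon >= 0 & tg$horizon <= 90),
            !anyNA(tg$elevation))
  invisible(TRUE)
}
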