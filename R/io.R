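# Plain-text interchange formats: hourly weather CSV, occupancy CSV,
# effective-area CSV, ESRI ASCII grids for rasters, and GeoJSON +
# cell-membership CSV for patch networks.  The grid and GeoJSON writers are
# small hand-rolled routines for these line-oriented text formats.

#' Read/write an hourly weather CSV
#'
#' Columns: \code{timestamp} (ISO-8601, hourly, UTC), \code{temp_c},
#' \code{wind_ms}, \code{sun_frac}.
#'
#' @param weather an \code{hourly_weather} data.frame.
#' @param path file path.
#' @return \code{read_weather_csv} returns an \code{hourly_weather}.
#' @export
write_weather_csv <- function(weather, path) {
  validate_weather(weather)
  out <- data.frame(
    timestamp = format(weather$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    temp_c = weather$temp_c, wind_ms = weather$wind_ms,
    sun_frac = weather$sun_frac)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_weather_csv
#' @export
read_weather_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  w <- data.frame(
    time = as.POSIXct(d$timestamp, format = "%Y-%m-%dT%H:%M:%SZ",
                      tz = "UTC"),
    temp_c = d$temp_c, wind_ms = d$wind_ms, sun_frac = d$sun_frac)
  class(w) <- c("hourly_weather", "data.frame")
  validate_weather(w)
  w
}

#' Read/write occupancy snapshots as CSV
#'
#' Columns: \code{patch_id}, \code{year}, \code{occupied} (0/1).
#'
#' @param occupancy data.frame \code{patch_id}, \code{year},
#'   \code{occupied}.
#' @param path file path.
#' @export
write_occupancy_csv <- function(occupancy, path) {
  stopifnot(all(c("patch_id", "year", "occupied") %in% names(occupancy)),
            all(occupancy$occupied %in% 0:1))
  write.csv(occupancy[, c("patch_id", "year", "occupied")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_occupancy_csv
#' @export
read_occupancy_csv <- function(path) {
  d <- read.csv(path)
  stopifnot(all(c("patch_id", "year", "occupied") %in% names(d)))
  d
}

#' Read/write effective areas as CSV
#'
#' Columns: \code{patch_id}, \code{year}, \code{a_eff_ha} (hectares).
#'
#' @param areas data.frame \code{patch_id}, \code{year}, \code{a_eff_ha}.
#' @param path file path.
#' @export
write_effective_areas_csv <- function(areas, path) {
  stopifnot(all(c("patch_id", "year", "a_eff_ha") %in% names(areas)))
  write.csv(areas[, c("patch_id", "year", "a_eff_ha")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_effective_areas_csv
#' @export
read_effective_areas_csv <- function(path) {
  d <- read.csv(path)
  stopifnot(all(c("patch_id", "year", "a_eff_ha") %in% names(d)))
  d
}

#' Read/write a raster as an ESRI ASCII grid
#'
#' @param m numeric matrix (row 1 = northern edge).
#' @param path file path.
#' @param resolution cell size in the grid's units.
#' @param xll,yll lower-left corner coordinates.
#' @export
write_ascii_grid <- function(m, path, resolution, xll = 0, yll = 0) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %g", xll),
    sprintf("yllcorner %g", yll),
    sprintf("cellsize %g", resolution),
    "NODATA_value -9999"), con)
  mm <- m
  mm[is.na(mm)] <- -9999
  writeLines(apply(mm, 1, paste, collapse = " "), con)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @return \code{read_ascii_grid} returns a list \code{matrix},
#'   \code{resolution}, \code{xll}, \code{yll}.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(tolower(lines[1:6]), "\\s+")
  kv <- setNames(vapply(hdr, function(x) as.numeric(x[2]), 0),
                 vapply(hdr, `[`, "", 1))
  m <- do.call(rbind, lapply(lines[-(1:6)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  m[m == kv["nodata_value"]] <- NA
  stopifnot(nrow(m) == kv["nrows"], ncol(m) == kv["ncols"])
  list(matrix = m, resolution = unname(kv["cellsize"]),
       xll = unname(kv["xllcorner"]), yll = unname(kv["yllcorner"]))
}

#' Write a patch network as GeoJSON plus a cell-membership CSV
#'
#' Each patch is emitted as a square polygon centred on its centroid with
#' area equal to the patch area (the models consume member cells and
#' areas; the polygon is an interchange convenience only).  The companion
#' CSV holds the raster cell membership (\code{patch_id}, \code{row},
#' \code{col}).
#'
#' @param network a \code{patch_network}.
#' @param geojson_path,cells_path output paths.
#' @export
write_patch_geojson <- function(network, geojson_path, cells_path = NULL) {
  n <- length(network$patch_id)
  feats <- lapply(seq_len(n), function(i) {
    half <- sqrt(network$area_ha[i] * 1e4) / 2 / 1000  # km
    cx <- network$centroid_km[i, 1]; cy <- network$centroid_km[i, 2]
    ring <- list(c(cx - half, cy - half), c(cx + half, cy - half),
                 c(cx + half, cy + half), c(cx - half, cy + half),
                 c(cx - half, cy - half))
    list(type = "Feature",
         properties = list(patch_id = network$patch_id[i],
                           area_m2 = network$area_ha[i] * 1e4),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, geojson_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(cells_path)) {
    tab <- do.call(rbind, lapply(seq_len(n), function(i)
      cbind(patch_id = network$patch_id[i], network$cells[[i]])))
    write.csv(tab, cells_path, row.names = FALSE, quote = FALSE)
  }
  invisible(geojson_path)
}
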