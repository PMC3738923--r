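# End-to-end orchestration: synth -> downscale -> microclimate -> effective
# areas -> population-dynamics ladder / metapopulation fit -> ensemble ->
# evaluation, from one declarative configuration with per-stage seeds, a
# manifest of output checksums, and full determinism under fixed seeds.

#' Default pipeline configuration
#'
#' Returns the declarative configuration consumed by
#' \code{\link{run_pipeline}}.  Any element can be overridden via
#' \code{...}.  Sizes default to a small landscape so a full run completes
#' in minutes.
#'
#' @param out_dir output directory.
#' @param ... overrides of any configuration element.
#' @return a named list of class \code{run_config}.
#' @export
pipeline_config <- function(out_dir = tempfile("thermapop_run_"), ...) {
  cf <- list(
    out_dir = out_dir,
    stages = c("synth", "downscale", "microclim", "effarea", "popdyn",
               "metapop_fit", "metapop_sim", "evaluate"),
    mode = "microclimate",          # or "habitat-area"
    threshold_c = 25,
    years = 1982:1991,
    calibration_years = 1982:1991,
    n_patches = 40,
    # patch sizes scaled to the demonstration landscape (a 1 km square):
    # log-normal around ~0.06 ha, capped at 0.5 ha
    area_meanlog = log(0.06), area_sdlog = 0.8, area_max_ha = 0.5,
    extent_m = 1000,
    relief_m = 40,
    wavelength_m = 400,
    latitude = 51.2, longitude = -0.5,
    wind_direction = 225,
    snapshot_gap = 9,
    n_runs = 100,
    n_permutations = 200,
    n_param_sets = 20,
    seeds = list(terrain = 11, weather = 12, network = 13, density = 14,
                 history = 15, fit = 16, sample = 17, ensemble = 18,
                 popdyn = 19),
    units = list(distance = "km", area = "ha", temperature = "degC"),
    true_ifm = list(alpha = 3, y = 20, mu = 0.1, x = 0.5, b = 0.5),
    # density-model coefficients scaled to the ~30-70 h quality range the
    # demonstration landscape produces
    betas = c(6e-3, 6e-3, -0.1, 0.05))
  over <- list(...)
  cf[names(over)] <- over
  structure(cf, class = "run_config")
}

#' Run the modelling pipeline end to end
#'
#' Executes the requested stages in dependency order on a synthetic
#' landscape: generate terrain/weather/network, downscale weather to
#' self-derived gridded targets, compute per-patch August threshold-hours
#' and effective areas (microclimate or habitat-area mode), fit the
#' population-dynamics ladder with a randomisation test, fit the IFM to a
#' generated snapshot pair, sample parameter sets, simulate an ensemble,
#' and evaluate occupancy.  Writes stage outputs and a manifest (config
#' hash, seeds, checksums) under \code{config$out_dir}; identical
#' configurations reproduce identical outputs.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return invisibly, a run report list: \code{manifest}, and the main
#'   stage results (\code{quality}, \code{eff_areas}, \code{ladder},
#'   \code{rand_test}, \code{ifm_fit}, \code{evaluation}).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cf <- config
  dir.create(cf$out_dir, recursive = TRUE, showWarnings = FALSE)
  want <- function(s) s %in% cf$stages
  res <- list()
  paths <- character()
  deps <- list(downscale = "synth", microclim = "downscale",
               effarea = "microclim", popdyn = "effarea",
               metapop_fit = "effarea", metapop_sim = "metapop_fit",
               evaluate = "metapop_sim")
  for (s in cf$stages) {
    d <- deps[[s]]
    if (!is.null(d) && !want(d))
      stop(sprintf("stage '%s' requires stage '%s'", s, d))
  }

  if (want("synth")) {
    res$terrain <- generate_terrain(cf$extent_m, cf$relief_m,
                                    cf$wavelength_m,
                                    seed = cf$seeds$terrain)
    wcf <- synth_weather_config(
      years = cf$years, seed = cf$seeds$weather,
      year_offsets = rep(c(0, 1.5, -1, 2.5, 0.5), length.out =
                           length(cf$years)),
      latitude = cf$latitude, longitude = cf$longitude)
    res$weather_raw <- generate_weather(wcf)
    ncf <- synth_network_config(
      n_patches = cf$n_patches,
      area_meanlog = cf$area_meanlog, area_sdlog = cf$area_sdlog,
      area_max_ha = cf$area_max_ha,
      extent_km = cf$extent_m / 1000,
      seed = cf$seeds$network)
    res$network <- generate_patch_network(ncf, terrain = res$terrain)
    paths["weather"] <- file.path(cf$out_dir, "weather.csv")
    write_weather_csv(res$weather_raw, paths["weather"])
    paths["patches"] <- file.path(cf$out_dir, "patches.geojson")
    paths["cells"] <- file.path(cf$out_dir, "patch_cells.csv")
    write_patch_geojson(res$network, paths["patches"], paths["cells"])
    paths["elevation"] <- file.path(cf$out_dir, "elevation.asc")
    write_ascii_grid(res$terrain$elevation, paths["elevation"],
                     res$terrain$resolution)
  }

  if (want("downscale")) {
    targets <- climate_targets_from_weather(res$weather_raw,
                                            temp_offset = 0.5,
                                            wind_factor = 0.9,
                                            sun_factor = 1.05)
    res$weather <- downscale_weather(res$weather_raw, targets,
                                     degenerate_fill = TRUE)
    paths["weather_ds"] <- file.path(cf$out_dir, "weather_downscaled.csv")
    write_weather_csv(res$weather, paths["weather_ds"])
  }

  if (want("microclim")) {
    res$quality <- network_thermal_quality(
      res$network, res$terrain, res$weather, cf$years,
      latitude = cf$latitude, longitude = cf$longitude,
      threshold = cf$threshold_c, wind_direction = cf$wind_direction)
    paths["quality"] <- file.path(cf$out_dir, "thermal_quality.csv")
    write.csv(res$quality, paths["quality"], row.names = FALSE)
  }

  if (want("effarea")) {
    res$eff_areas <- effective_areas(
      res$network, res$quality, calibration_years = cf$calibration_years,
      mode = cf$mode)
    paths["effarea"] <- file.path(cf$out_dir, "effective_areas.csv")
    write_effective_areas_csv(res$eff_areas, paths["effarea"])
  }

  if (want("popdyn")) {
    # density series on a subset of patches treated as monitored transects
    qt <- res$quality
    tr_ids <- head(res$network$patch_id, min(10, cf$n_patches))
    qt <- qt[qt$patch_id %in% tr_ids, ]
    Ttab <- data.frame(transect = qt$patch_id, year = qt$year,
                       T_cov = qt$q_hours)
    dens <- generate_density_series(cf$betas, Ttab, D0 = 0.5,
                                    noise_sd = 0.02,
                                    seed = cf$seeds$density)
    dens$T_quality <- Ttab$T_cov[match(paste(dens$transect, dens$year),
                                       paste(Ttab$transect, Ttab$year))]
    # regional covariate: yearly mean quality (same for all transects)
    ym <- tapply(qt$q_hours, qt$year, mean)
    dens$T_regional <- as.numeric(ym[as.character(dens$year)])
    res$density <- dens
    res$ladder <- model_ladder(dens)
    res$rand_test <- randomisation_test(dens, "vi",
                                        n_reps = cf$n_permutations,
                                        seed = cf$seeds$popdyn)
    paths["ladder"] <- file.path(cf$out_dir, "model_ladder.csv")
    write.csv(res$ladder, paths["ladder"], row.names = FALSE)
  }

  if (want("metapop_fit")) {
    n <- length(res$network$patch_id)
    Amat <- area_matrix_from_table(res$eff_areas, res$network,
                                   sort(unique(res$eff_areas$year)))
    truep <- do.call(ifm_params, cf$true_ifm)
    start <- as.integer(res$network$area_ha >=
                          quantile(res$network$area_ha, 0.7))
    hist <- generate_occupancy_history(res$network, truep,
                                       Amat[seq_len(cf$snapshot_gap), ,
                                            drop = FALSE],
                                       start, cf$snapshot_gap,
                                       seed = cf$seeds$history)
    res$snap0 <- hist[[1]]
    res$snap1 <- hist[[length(hist)]]
    res$ifm_fit <- fit_ifm(res$snap0, res$snap1,
                           Amat[seq_len(cf$snapshot_gap), , drop = FALSE],
                           res$network$dist_km, n_steps = cf$snapshot_gap,
                           seed = cf$seeds$fit)
    paths["ifm_fit"] <- file.path(cf$out_dir, "ifm_fit.json")
    jsonlite::write_json(
      list(params = unclass(res$ifm_fit$params),
           loglik = res$ifm_fit$loglik,
           chisq_crit = res$ifm_fit$chisq_crit,
           boundary_pinned = as.list(res$ifm_fit$boundary_pinned)),
      paths["ifm_fit"], auto_unbox = TRUE, digits = NA)
  }

  if (want("metapop_sim")) {
    sets <- sample_parameter_sets(res$ifm_fit, cf$n_param_sets,
                                  seed = cf$seeds$sample)
    res$param_sets <- sets
    Amat <- area_matrix_from_table(res$eff_areas, res$network,
                                   sort(unique(res$eff_areas$year)))
    ny <- nrow(Amat)
    res$ensemble <- simulate_ensemble(res$snap0, Amat, sets, cf$n_runs,
                                      ny, res$network$dist_km,
                                      seed = cf$seeds$ensemble)
    freq <- res$ensemble$freq
    ftab <- data.frame(
      patch_id = rep(res$network$patch_id, times = ncol(freq)),
      year = rep(res$ensemble$years, each = nrow(freq)),
      freq = as.vector(freq))
    paths["freq"] <- file.path(cf$out_dir, "ensemble_frequencies.csv")
    write.csv(ftab, paths["freq"], row.names = FALSE)
    ces <- colonisation_extinction_series(res$ensemble)
    paths["colext"] <- file.path(cf$out_dir, "colonisation_extinction.csv")
    write.csv(ces$series, paths["colext"], row.names = FALSE)
  }

  if (want("evaluate")) {
    res$evaluation <- evaluate_occupancy(
      res$ensemble, res$snap1,
      year_index = cf$snapshot_gap + 1,
      group_size_km = 5, coords_km = res$network$centroid_km)
    paths["evaluation"] <- file.path(cf$out_dir, "evaluation.json")
    jsonlite::write_json(
      list(AIC = res$evaluation$AIC,
           group_AIC = res$evaluation$group_AIC,
           total_loglik = res$evaluation$total_loglik,
           n_groups = res$evaluation$n_groups),
      paths["evaluation"], auto_unbox = TRUE, digits = NA)
  }

  manifest <- list(
    config = cf[setdiff(names(cf), "out_dir")],
    seeds = cf$seeds,
    r_version = as.character(getRversion()),
    outputs = lapply(paths, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(cf$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}

# Effective-area table -> (years x patches) matrix in network patch order.
area_matrix_from_table <- function(areas, network, years) {
  n <- length(network$patch_id)
  m <- matrix(NA_real_, length(years), n)
  for (k in seq_along(years)) {
    d <- areas[areas$year == years[k], ]
    m[k, ] <- d$a_eff_ha[match(network$patch_id, d$patch_id)]
  }
  if (anyNA(m)) stop("effective areas missing for some patch-years")
  m
}
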