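coe <- microclim_coeffs()

test_that("irradiance follows the shading and tilt rules", {
  sun_up <- list(altitude = 40, azimuth = 180)
  sun_dn <- list(altitude = -5, azimuth = 30)
  # sun below horizon: nothing
  expect_equal(cell_irradiance(0, NA, 0, 1, sun_dn, 1, coe), 0)
  # flat open cell: direct proportional to sin(altitude)
  q_flat <- cell_irradiance(0, NA, 0, 1, sun_up, 1, coe)
  dni <- coe$solar_constant * coe$transmittance^(1 / sin(40 * pi / 180))
  expect_equal(q_flat, dni * sin(40 * pi / 180) * (1 + coe$diffuse_frac))
  # topographic shading kills the beam, leaves diffuse
  q_shaded <- cell_irradiance(0, NA, 45, 1, sun_up, 1, coe)
  expect_equal(q_shaded, dni * sin(40 * pi / 180) * coe$diffuse_frac)
  # south-facing slope beats north-facing slope under a southern sun
  q_s <- cell_irradiance(20, 180, 0, 1, sun_up, 1, coe)
  q_n <- cell_irradiance(20, 0, 0, 1, sun_up, 1, coe)
  expect_gt(q_s, q_n)
  # never exceeds the clear-sky bound at that altitude
  for (sl in c(0, 15, 35)) for (asp in c(0, 90, 180)) {
    q <- cell_irradiance(sl, asp, 0, 1, sun_up, 1, coe)
    expect_lte(q, dni + coe$diffuse_frac * dni * sin(40 * pi / 180) + 1e-9)
  }
})

test_that("wind shelter follows the tangent rule and is monotone", {
  expect_equal(shelter_wind(0, 5, coe), 5)
  # tan 45 = 1, c = 1 -> halved
  expect_equal(shelter_wind(45, 5, coe), 2.5)
  u <- shelter_wind(c(0, 10, 30, 50, 70, 85), 5, coe)
  expect_true(all(diff(u) < 0))
  # full shelter floor
  expect_equal(shelter_wind(90, 5, coe), coe$wind_floor)
})

test_that("near-surface warming is the two-parameter radiation/wind form", {
  expect_equal(near_surface_temperature(12, 0, 3, coe), 12)
  co2 <- microclim_coeffs(k1 = 0.02, k2 = 0.5)
  # 1 + k2*u = 2 at u = 2: excess = 0.02 * 500 / 2 = 5
  expect_equal(near_surface_temperature(20, 500, 2, co2), 25)
  # doubling wind strictly reduces the excess
  e1 <- near_surface_temperature(20, 500, 2, co2) - 20
  e2 <- near_surface_temperature(20, 500, 4, co2) - 20
  expect_lt(e2, e1)
  expect_error(near_surface_temperature(20, -5, 2, co2), ">= 0")
})

test_that("threshold hours use the strict inequality and the August bound", {
  expect_equal(threshold_hours(rep(20, 744)), 0)
  expect_equal(threshold_hours(rep(26, 744)), 744)
  expect_equal(threshold_hours(rep(25, 744)), 0)   # exactly at threshold
  expect_error(threshold_hours(rep(26, 500)), "744")
})

test_that("patch thermal quality is the mean over member cells", {
  expect_equal(patch_thermal_quality(rep(100, 7)), 100)
  expect_equal(patch_thermal_quality(c(0, 10)), 5)
  expect_equal(patch_thermal_quality(42), 42)
  expect_error(patch_thermal_quality(numeric(0)), "no member cells")
})

test_that("south-facing cells accumulate at least as many threshold hours as
           north-facing cells of the same slope", {
  # same-slope south- and north-facing planes under identical August weather
  g <- tan(25 * pi / 180); res <- 5; nr <- 12; nc <- 12
  south <- matrix(rep(g * res * (nr - seq_len(nr)), times = nc), nr, nc)
  north <- south[nr:1, ]
  tg_s <- terrain_from_elevation(south, res)
  tg_n <- terrain_from_elevation(north, res)
  for (seed in c(11, 12, 13)) {
    w <- generate_weather(synth_weather_config(years = 1990, seed = seed,
                                               year_offsets = 2))
    hs <- run_microclimate(tg_s, w, 1990)
    hn <- run_microclimate(tg_n, w, 1990)
    # compare away from the edge rows where one-sided gradients differ
    expect_true(all(hs[4:9, 4:9] >= hn[4:9, 4:9]))
  }
})

test_that("a flat open-horizon cell reproduces the unshaded unsheltered
           baseline exactly", {
  tg <- generate_terrain(c(60, 60), relief_m = 0, wavelength_m = 100,
                         noise_relief_m = 0)
  w <- fixture_weather()
  hrs <- run_microclimate(tg, w, 1990)
  # baseline computed directly from the module primitives
  lt <- as.POSIXlt(w$time, tz = "UTC")
  aug <- which(lt$year + 1900 == 1990 & lt$mon == 7)
  sun <- solar_position(51.2, -0.5, w$time[aug])
  temps <- vapply(seq_along(aug), function(h) {
    q <- cell_irradiance(0, NA, 0, 1,
                         list(altitude = sun$altitude[h],
                              azimuth = sun$azimuth[h]),
                         w$sun_frac[aug[h]], coe)
    near_surface_temperature(w$temp_c[aug[h]], q, w$wind_ms[aug[h]], coe)
  }, 0)
  expect_true(all(hrs == threshold_hours(temps)))
})

test_that("effective areas normalise mean quality to one over the
           calibration window", {
  nw <- generate_patch_network(synth_network_config(n_patches = 12,
                                                    seed = 2))
  q <- expand.grid(patch_id = nw$patch_id, year = 1982:1985)
  set.seed(8)
  q$q_hours <- runif(nrow(q), 20, 200)
  ea <- effective_areas(nw, q, calibration_years = 1982:1984)
  area <- nw$area_ha[match(ea$patch_id, nw$patch_id)]
  ratio <- ea$a_eff_ha / area
  cal <- ea$year %in% 1982:1984
  expect_equal(mean(ratio[cal]), 1, tolerance = 1e-12)
  # all-equal quality -> effective area equals area everywhere
  q2 <- q; q2$q_hours <- 77
  ea2 <- effective_areas(nw, q2, calibration_years = 1982:1984)
  expect_equal(ea2$a_eff_ha, nw$area_ha[match(ea2$patch_id, nw$patch_id)])
  # habitat-area mode is the constant-quality special case
  ea3 <- effective_areas(nw, q, mode = "habitat-area")
  expect_equal(ea3$a_eff_ha, rep(nw$area_ha, times = 4))
  # degenerate: no suitability anywhere
  q0 <- q; q0$q_hours <- 0
  expect_error(effective_areas(nw, q0, calibration_years = 1982:1984),
               "calibration")
})
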