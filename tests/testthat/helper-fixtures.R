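# Shared fixtures, built in code and cached per test session.

# Small random patch geometry: n centroids in a box, distance matrix in km.
rand_geometry <- function(n, extent_km = 5, seed = 1) {
  set.seed(seed)
  cent <- matrix(runif(2 * n, 0, extent_km), n, 2)
  d <- as.matrix(stats::dist(cent))
  dimnames(d) <- NULL
  list(cent = cent, dist = d)
}

# One synthetic year of hourly weather, memoised.
fixture_weather <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_weather(synth_weather_config(years = 1990,
                                                      seed = 42))
    cache
  }
})

# Density data generated from the thermal logistic model (model vi
# structure), with regional and quality covariates attached.
make_density_data <- function(betas = c(2e-3, 2e-3, -0.1, 0.05),
                              n_transects = 10, n_years = 21,
                              noise_sd = 0, seed = 1, D0 = 0.5) {
  set.seed(seed)
  years <- seq(2000, length.out = n_years)
  # quality covariate: shared year signal + transect offset + noise
  yr_sig <- runif(n_years, 100, 300)
  tr_off <- runif(n_transects, -60, 60)
  Ttab <- data.frame(
    transect = rep(seq_len(n_transects), each = n_years),
    year = rep(years, n_transects),
    T_cov = pmax(10, rep(yr_sig, n_transects) +
                   rep(tr_off, each = n_years) +
                   rnorm(n_transects * n_years, 0, 20)))
  dens <- generate_density_series(betas, Ttab, D0 = D0,
                                  noise_sd = noise_sd, seed = seed + 1)
  key <- paste(dens$transect, dens$year)
  dens$T_quality <- Ttab$T_cov[match(key, paste(Ttab$transect, Ttab$year))]
  yr_T <- tapply(Ttab$T_cov, Ttab$year, mean)
  dens$T_regional <- as.numeric(yr_T[as.character(dens$year)])
  dens
}
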