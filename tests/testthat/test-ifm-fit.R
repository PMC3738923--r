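# Small-network fitting contracts; the full parameter-recovery study lives
# in the acceptance suite.

make_fit_fixture <- function(seed = 1) {
  nw <- generate_patch_network(synth_network_config(n_patches = 60,
                                                    extent_km = 12,
                                                    seed = seed))
  truep <- ifm_params(1, 100, 2, 0.5, 0.5)
  start <- as.integer(seq_len(60) %% 2 == 0)
  s0 <- generate_occupancy_history(nw, truep, nw$area_ha, start, 15,
                                   seed = seed + 1)[[16]]
  s1 <- generate_occupancy_history(nw, truep, nw$area_ha, s0, 9,
                                   seed = seed + 2)[[10]]
  list(nw = nw, truep = truep, s0 = s0, s1 = s1)
}

test_that("the fitted likelihood beats the starting point and the returned
           surface evaluator is consistent", {
  fx <- make_fit_fixture(31)
  init <- ifm_params(0.5, 10, 0.5, 1, 1)
  f <- fit_ifm(fx$s0, fx$s1, fx$nw$area_ha, fx$nw$dist_km, n_steps = 9,
               init = init, n_starts = 2, seed = 1)
  expect_gte(f$loglik, f$loglik_fn(unlist(init)))
  expect_equal(f$loglik, f$loglik_fn(unlist(f$params)), tolerance = 1e-8)
  expect_true(f$in_ci(unlist(f$params)))
  expect_equal(f$chisq_crit, qchisq(0.95, 5), tolerance = 1e-12)
})

test_that("a static snapshot pair pins the extinction scale to the lower
           bound", {
  nw <- generate_patch_network(synth_network_config(n_patches = 40,
                                                    extent_km = 10,
                                                    seed = 33))
  s0 <- rep(1L, 40)
  # mu -> 0 generating process: snapshot unchanged, so the fitted
  # extinction scale collapses towards the lower bound (the likelihood is
  # flat once implied extinction probabilities are negligible)
  f <- fit_ifm(s0, s0, nw$area_ha, nw$dist_km, n_steps = 9, n_starts = 3,
               seed = 2)
  expect_lt(f$params$mu, 0.01)
  E_implied <- extinction_prob(0, nw$area_ha, f$params$mu, f$params$x)
  expect_lt(max(E_implied), 0.05)
})

test_that("sampled parameter sets all lie inside the joint 95% region, are
           seeded-deterministic, and concentrate near the MLE", {
  fx <- make_fit_fixture(35)
  f <- fit_ifm(fx$s0, fx$s1, fx$nw$area_ha, fx$nw$dist_km, n_steps = 9,
               n_starts = 3, seed = 3)
  sets <- sample_parameter_sets(f, 40, seed = 4)
  expect_length(sets, 40)
  devs <- vapply(sets, function(s)
    2 * (f$loglik - f$loglik_fn(unlist(s))), 0)
  expect_true(all(devs <= f$chisq_crit + 1e-9))
  sets2 <- sample_parameter_sets(f, 40, seed = 4)
  expect_identical(sets, sets2)
  # likelihood-proportional: more mass in the inner half of the region than
  # a uniform draw over the region would give
  expect_gt(mean(devs <= f$chisq_crit / 2), 0.5)
})

test_that("occupancy evaluation applies the pseudocount likelihood and the
           grouped conjunction bound", {
  g <- rand_geometry(6, extent_km = 8, seed = 40)
  A <- rep(2, 6)
  pars <- ifm_params(1, 4, 0.3, 0.5, 0.5)
  ens <- simulate_ensemble(c(1, 1, 0, 0, 1, 0), A, list(pars), 200, 5,
                           g$dist, seed = 41)
  obs <- ens$occupancy[1, , 6]   # one run's end state: certainly matched once
  ev <- evaluate_occupancy(ens, obs, k_params = 5)
  n <- ens$n_runs
  expect_true(all(ev$per_patch_loglik <= log((n + 0.5) / (n + 1)) + 1e-12))
  expect_true(all(ev$per_patch_loglik >= log(0.5 / (n + 1)) - 1e-12))
  expect_equal(ev$AIC, -2 * ev$total_loglik + 10)
  # perfect and never-matched bounds
  ens1 <- simulate_ensemble(c(1, 0), c(1, 1),
                            list(ifm_params(1, 1, 0, 0.5, 0.5)), 50, 3,
                            matrix(c(0, 500, 500, 0), 2, 2), seed = 42)
  ev1 <- evaluate_occupancy(ens1, c(1, 0))
  expect_equal(unname(ev1$per_patch_loglik),
               rep(log(50.5 / 51), 2))
  ev0 <- evaluate_occupancy(ens1, c(0, 1))
  expect_equal(unname(ev0$per_patch_loglik), rep(log(0.5 / 51), 2))
  # grouped: joint likelihood cannot exceed any member's individual one
  evg <- evaluate_occupancy(ens, obs, group_size_km = 4,
                            coords_km = g$cent)
  gid <- paste(floor(g$cent[, 1] / 4), floor(g$cent[, 2] / 4))
  for (gg in unique(gid)) {
    ix <- which(gid == gg)
    expect_lte(evg$group_loglik[[gg]],
               min(ev$per_patch_loglik[ix]) + 1e-9)
  }
})

test_that("colonisation/extinction series summarise the ensemble and
           correlate perfectly with themselves", {
  g <- rand_geometry(8, extent_km = 6, seed = 50)
  pars <- ifm_params(1, 4, 0.4, 0.5, 0.5)
  ens <- simulate_ensemble(rep(c(1L, 0L), 4), runif(8, 0.5, 3), list(pars),
                           300, 6, g$dist, seed = 51)
  ces <- colonisation_extinction_series(ens)
  expect_equal(nrow(ces$series), 6)
  expect_true(all(ces$series$lo_col <= ces$series$med_col))
  expect_true(all(ces$series$med_col <= ces$series$hi_col))
  self <- colonisation_extinction_series(ens,
                                         comparison = ces$series$med_net)
  expect_equal(self$R2, 1)
  # correlation invariant to affine transforms of the comparison series
  aff <- colonisation_extinction_series(
    ens, comparison = 3 - 2 * ces$series$med_net)
  expect_equal(aff$R2, 1)
  expect_warning(
    flat <- colonisation_extinction_series(ens, comparison = rep(1, 6)),
    "zero-variance")
  expect_true(is.na(flat$R2))
})
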