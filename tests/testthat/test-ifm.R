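test_that("connectivity sums the kernel over occupied neighbours", {
  g <- rand_geometry(4, seed = 1)
  A <- c(2, 0.5, 1, 4)
  # nobody else occupied -> zero
  expect_equal(connectivity(g$dist, c(1, 0, 0, 0), A, 1, 1, i = 1), 0)
  # unit construction: one neighbour at 0.95 km, alpha = b = 1, A = 1
  d <- matrix(c(0, 0.95, 0.95, 0), 2, 2)
  expect_equal(connectivity(d, c(1, 1), c(1, 1), 1, 1, i = 1), 1)
  # three occupied neighbours: term-by-term hand sum
  occ <- c(0, 1, 1, 1)
  alpha <- 1.4; b <- 0.6
  hand <- sum((g$dist[1, 2:4] + 0.05)^(-alpha) * A[2:4]^b)
  expect_equal(connectivity(g$dist, occ, A, alpha, b, i = 1), hand)
  # vectorised form agrees with per-patch form
  S <- connectivity(g$dist, occ, A, alpha, b)
  expect_equal(S[1], hand)
  expect_equal(S, vapply(1:4, function(i)
    connectivity(g$dist, occ, A, alpha, b, i = i), 0))
})

test_that("colonisation and extinction probabilities follow their closed
           forms and bounds", {
  expect_equal(colonisation_prob(0, 1), 0)
  expect_equal(colonisation_prob(sqrt(3), 3), 0.5)   # S^2 = y
  expect_equal(colonisation_prob(2, 1), 0.8)
  expect_equal(extinction_prob(0, 1, 0.2, 0), 0.2)
  # cap: mu A^-x = 2 -> capped at 1
  expect_equal(extinction_prob(0, 0.1, 0.2, 1), 1)
  # rescue effect halves extinction at C = 0.5
  expect_equal(extinction_prob(0.5, 1, 0.2, 0), 0.1)
  # property: bounds and monotonicity over random draws
  set.seed(3)
  for (k in 1:200) {
    S <- runif(1, 0, 50); y <- runif(1, 1e-3, 100)
    A <- runif(1, 1e-3, 100); mu <- runif(1, 0, 5); x <- runif(1, 0, 3)
    C <- colonisation_prob(S, y)
    E <- extinction_prob(C, A, mu, x)
    expect_true(C >= 0 && C < 1)
    expect_true(E >= 0 && E <= 1)
    expect_gt(colonisation_prob(S + 1, y), C)
    expect_lt(colonisation_prob(S + 1e-9, y + 1), colonisation_prob(S + 1e-9, y))
  }
})

test_that("the annual step honours absorbing and deterministic limits", {
  g <- rand_geometry(5, seed = 2)
  A <- rep(1, 5)
  p0 <- ifm_params(alpha = 1, y = 1, mu = 0, x = 0.5, b = 0.5)
  set.seed(1)
  expect_equal(ifm_step(rep(1, 5), A, p0, g$dist), rep(1L, 5))
  p1 <- ifm_params(alpha = 1, y = 1, mu = 0.5, x = 0.5, b = 0.5)
  expect_equal(ifm_step(rep(0, 5), A, p1, g$dist), rep(0L, 5))
})

test_that("occupancy histories preserve absorbing states and determinism", {
  nw <- generate_patch_network(synth_network_config(n_patches = 6,
                                                    extent_km = 3,
                                                    seed = 3))
  pars <- ifm_params(1, 1, 0, 0.5, 0.5)
  h <- generate_occupancy_history(nw, pars, nw$area_ha, rep(1, 6), 5,
                                  seed = 4)
  expect_true(all(vapply(h, function(s) all(s == 1), TRUE)))
  pars2 <- ifm_params(1, 1, 0.3, 0.5, 0.5)
  h0 <- generate_occupancy_history(nw, pars2, nw$area_ha, rep(0, 6), 5,
                                   seed = 4)
  expect_true(all(vapply(h0, function(s) all(s == 0), TRUE)))
  ha <- generate_occupancy_history(nw, pars2, nw$area_ha, c(1, 1, 1, 0, 0, 0),
                                   5, seed = 8)
  hb <- generate_occupancy_history(nw, pars2, nw$area_ha, c(1, 1, 1, 0, 0, 0),
                                   5, seed = 8)
  expect_identical(ha, hb)
  expect_error(generate_occupancy_history(
    nw, pars2, matrix(1, 2, 6), c(1, 1, 1, 0, 0, 0), 5, seed = 1),
    "fewer years")
})

test_that("exact marginals reproduce closed forms and a hand-propagated
           two-patch chain", {
  # isolated patch: survival is geometric
  d1 <- matrix(0, 1, 1)
  pars <- ifm_params(1, 1, 0.3, 0.5, 1)
  e <- min(1, 0.3 * 2^(-0.5))
  expect_equal(exact_marginals(1, 2, pars, 3, d1), (1 - e)^3,
               tolerance = 1e-12)
  # two symmetric patches, two years, hand matrix propagation
  d2 <- matrix(c(0, 0.95, 0.95, 0), 2, 2)
  pars2 <- ifm_params(1, 1, 0.4, 1, 1)
  A <- c(1, 1)
  # state (1, 0): S2 = 1 -> C2 = 0.5; E1 = (1 - C1) mu; C1 from S1 = 0
  states <- list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  trans <- function(z) {
    S <- c((z[2]) * 1, (z[1]) * 1)
    C <- S^2 / (1 + S^2)
    E <- (1 - C) * pmin(1, 0.4 / A)
    p <- z * (1 - E) + (1 - z) * C
    vapply(states, function(w) prod(ifelse(w == 1, p, 1 - p)), 0)
  }
  P <- do.call(rbind, lapply(states, trans))
  v <- c(0, 1, 0, 0)            # start (1, 0)
  v2 <- as.vector(v %*% P %*% P)
  hand <- c(sum(v2[c(2, 4)]), sum(v2[c(3, 4)]))
  expect_equal(exact_marginals(c(1, 0), A, pars2, 2, d2), hand,
               tolerance = 1e-12)
  # marginals stay within [0, 1]
  g <- rand_geometry(4, seed = 5)
  m <- exact_marginals(c(1, 0, 1, 0), c(2, 1, 0.5, 3),
                       ifm_params(1.5, 2, 0.3, 0.5, 0.7), 6, g$dist)
  expect_true(all(m >= 0 & m <= 1))
  expect_error(exact_marginals(rep(1, 13), rep(1, 13),
                               pars, 1, matrix(0, 13, 13)),
               "too large")
})

test_that("mean-field marginals match closed forms and approximate the
           exact chain under moderate coupling", {
  d1 <- matrix(0, 1, 1)
  pars <- ifm_params(1, 1, 0.3, 0.5, 1)
  e <- min(1, 0.3 * 2^(-0.5))
  expect_equal(meanfield_marginals(1, 2, pars, 4, d1), (1 - e)^4)
  # mu = 0: probabilities monotone non-decreasing
  g <- rand_geometry(4, seed = 6)
  p0 <- ifm_params(1, 1, 0, 0.5, 0.5)
  p_prev <- c(1, 0, 0, 1)
  for (t in 1:5) {
    p_next <- meanfield_marginals(p_prev, rep(1, 4), p0, 1, g$dist)
    expect_true(all(p_next >= p_prev - 1e-12))
    p_prev <- p_next
  }
  # within 0.05 of the exact joint chain for a moderately coupled 3-patch
  # network over 5 years
  g3 <- rand_geometry(3, extent_km = 3, seed = 7)
  pars3 <- ifm_params(1.5, 4, 0.3, 0.5, 0.5)
  A3 <- c(2, 0.8, 1.5)
  mf <- meanfield_marginals(c(1, 0, 1), A3, pars3, 5, g3$dist)
  ex <- exact_marginals(c(1, 0, 1), A3, pars3, 5, g3$dist)
  expect_lt(max(abs(mf - ex)), 0.05)
})

test_that("mean-field and simulation both converge to the exact chain in
           the weak-coupling limit", {
  g3 <- rand_geometry(3, extent_km = 8, seed = 8)
  pars <- ifm_params(6, 5, 0.4, 0.5, 0.5)   # steep kernel: weak coupling
  A3 <- c(1, 2, 0.7)
  ex <- exact_marginals(c(1, 1, 0), A3, pars, 5, g3$dist)
  mf <- meanfield_marginals(c(1, 1, 0), A3, pars, 5, g3$dist)
  expect_lt(max(abs(mf - ex)), 0.01)
  ens <- simulate_ensemble(c(1, 1, 0), A3, list(pars), 20000, 5, g3$dist,
                           seed = 9)
  expect_lt(max(abs(ens$freq[, 6] - ex)), 0.02)
})

test_that("ensemble bookkeeping identity holds and mu = 0 runs are
           monotone", {
  g <- rand_geometry(6, seed = 10)
  A <- runif(6, 0.5, 4)
  pars <- ifm_params(1.5, 2, 0.3, 0.5, 0.5)
  ens <- simulate_ensemble(c(1, 0, 1, 0, 1, 0), A, list(pars), 400, 6,
                           g$dist, seed = 11)
  occ_counts <- apply(ens$occupancy, c(1, 3), sum)
  expect_true(all(occ_counts[, -1] ==
    occ_counts[, -ncol(occ_counts)] + ens$colonisations - ens$extinctions))
  expect_equal(dim(ens$freq), c(6, 7))
  expect_true(all(ens$freq >= 0 & ens$freq <= 1))
  p0 <- ifm_params(1.5, 2, 0, 0.5, 0.5)
  ens0 <- simulate_ensemble(c(1, 0, 1, 0, 1, 0), A, list(p0), 200, 6,
                            g$dist, seed = 12)
  occ0 <- apply(ens0$occupancy, c(1, 3), sum)
  expect_true(all(apply(occ0, 1, function(z) all(diff(z) >= 0))))
  # determinism
  ens2 <- simulate_ensemble(c(1, 0, 1, 0, 1, 0), A, list(pars), 400, 6,
                            g$dist, seed = 11)
  expect_identical(ens$occupancy, ens2$occupancy)
})

test_that("replicate occupancy histories match the exact four-state chain
           on a two-patch network", {
  nw <- generate_patch_network(synth_network_config(n_patches = 2,
                                                    extent_km = 1,
                                                    seed = 70))
  pars <- ifm_params(1, 2, 0.3, 0.5, 0.5)
  start <- c(1L, 0L)
  n_hist <- 4000
  ends <- matrix(0L, n_hist, 2)
  for (r in seq_len(n_hist)) {
    h <- generate_occupancy_history(nw, pars, nw$area_ha, start, 3,
                                    seed = 7000 + r)
    ends[r, ] <- h[[4]]
  }
  ex <- exact_marginals(start, nw$area_ha, pars, 3, nw$dist_km)
  ci <- binomial_ci(n_hist, ex)
  cnt <- colSums(ends)
  expect_true(all(cnt >= ci$lo & cnt <= ci$hi))
})

test_that("an isolated occupied patch survives with geometric frequency", {
  d2 <- matrix(c(0, 500, 500, 0), 2, 2)   # effectively unreachable pair
  pars <- ifm_params(2, 1, 0.4, 1, 1)
  A <- c(1, 1)
  e <- min(1, 0.4)
  ens <- simulate_ensemble(c(1, 0), A, list(pars), 10000, 4, d2, seed = 13)
  expected <- (1 - e)^4
  ci <- qbinom(c(0.005, 0.995), 10000, expected) / 10000
  expect_gte(ens$freq[1, 5], ci[1])
  expect_lte(ens$freq[1, 5], ci[2])
})

test_that("warm-year effective areas yield at least the occupancy of cool
           years", {
  nw <- generate_patch_network(synth_network_config(n_patches = 25,
                                                    extent_km = 12,
                                                    seed = 14))
  pars <- ifm_params(2, 5, 0.6, 0.5, 0.5)
  start <- rep(c(1L, 0L), length.out = 25)
  occ_at <- function(fac, seed) {
    ens <- simulate_ensemble(start, nw$area_ha * fac, list(pars), 300, 8,
                             nw$dist_km, seed = seed)
    mean(ens$freq[, 9])
  }
  warm <- mean(vapply(1:5, function(s) occ_at(1.6, 20 + s), 0))
  cool <- mean(vapply(1:5, function(s) occ_at(0.6, 20 + s), 0))
  expect_gte(warm, cool)
})
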