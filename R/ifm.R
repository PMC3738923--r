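# Incidence function model with annually varying effective areas.
# Connectivity S_i = sum_{j occupied, j != i} (d_ij + 0.05)^-alpha * A_j^b
# (distances in km; the 0.05 offset is 50 m; power-law dispersal kernel),
# colonisation C_i = S_i^2 / (y + S_i^2), extinction
# E_i = (1 - C_i) * min(1, mu * A_i^-x) (rescue effect; raw term capped at
# 1).  The annual update is synchronous: C and E are evaluated on the
# pre-step state.

#' Incidence function model parameters
#'
#' @param alpha dispersal exponent of the power-law kernel (per km scale).
#' @param y colonisation half-saturation constant (squared-connectivity
#'   units), > 0.
#' @param mu extinction scale.
#' @param x extinction area exponent.
#' @param b emigration (source strength) area exponent.
#' @return list of class \code{ifm_params}.
#' @export
ifm_params <- function(alpha, y, mu, x, b) {
  stopifnot(alpha >= 0, y > 0, mu >= 0, x >= 0, b >= 0)
  structure(list(alpha = unname(alpha), y = unname(y), mu = unname(mu),
                 x = unname(x), b = unname(b)),
            class = "ifm_params")
}

# Distance kernel matrix W[i, j] = (d_ij + 0.05)^-alpha, diagonal zeroed.
ifm_kernel <- function(dist_km, alpha) {
  W <- (dist_km + 0.05)^(-alpha)
  diag(W) <- 0
  W
}

#' Connectivity of patches
#'
#' \code{S_i = sum_{j occupied, j != i} (d_ij + 0.05)^-alpha * A_j^b} with
#' distances in km.
#'
#' @param dist_km symmetric patch distance matrix (km).
#' @param occupied 0/1 (or logical) occupancy vector.
#' @param A per-patch (effective) areas, hectares.
#' @param alpha,b kernel and source-strength exponents.
#' @param i optional patch index; when given only \code{S_i} is returned.
#' @return connectivity vector (or scalar for one patch).
#' @export
connectivity <- function(dist_km, occupied, A, alpha, b, i = NULL) {
  occupied <- as.numeric(occupied)
  src <- occupied * A^b
  if (!is.null(i)) {
    w <- (dist_km[i, ] + 0.05)^(-alpha)
    w[i] <- 0
    return(sum(w * src))
  }
  as.vector(ifm_kernel(dist_km, alpha) %*% src)
}

#' Colonisation probability from connectivity
#'
#' \code{C = S^2 / (y + S^2)}: 0 at S = 0, 0.5 at \code{S^2 = y}, strictly
#' increasing in S and decreasing in y, always < 1.
#'
#' @param S connectivity (>= 0); vectorised.
#' @param y half-saturation constant (> 0).
#' @return colonisation probability in [0, 1).
#' @export
colonisation_prob <- function(S, y) {
  stopifnot(all(S >= 0), y > 0)
  S^2 / (y + S^2)
}

#' Extinction probability
#'
#' \code{E = (1 - C) * min(1, mu * A^-x)}; the \code{(1 - C)} factor is the
#' rescue effect and the raw area term is capped at 1.
#'
#' @param C colonisation probability in [0, 1]; vectorised.
#' @param A (effective) patch area, hectares (> 0).
#' @param mu,x extinction scale and area exponent.
#' @return extinction probability in [0, 1].
#' @export
extinction_prob <- function(C, A, mu, x) {
  stopifnot(all(C >= 0 & C <= 1), all(A > 0))
  (1 - C) * pmin(1, mu * A^(-x))
}

# Per-patch (C, E) for a state (or matrix of states, runs in rows).
ifm_rates <- function(Z, W, A, params) {
  src <- A^params$b
  S <- if (is.matrix(Z)) Z %*% sweep(W, 1, src, "*") else
    as.vector(W %*% (Z * src))
  C <- colonisation_prob(pmax(S, 0), params$y)
  Eraw <- pmin(1, params$mu * A^(-params$x))
  E <- (1 - C) * rep(Eraw, each = if (is.matrix(Z)) nrow(Z) else 1)
  list(C = C, E = E)
}

#' One synchronous annual transition of the IFM
#'
#' Occupied patches survive with probability \code{1 - E_i}; empty patches
#' are colonised with probability \code{C_i}.  Both are computed from the
#' pre-step state; draws are independent given the state.
#'
#' @param state 0/1 occupancy vector.
#' @param A_t per-patch effective areas for the year, hectares.
#' @param params an \code{\link{ifm_params}}.
#' @param dist_km patch distance matrix (km).
#' @return next 0/1 occupancy vector.
#' @export
ifm_step <- function(state, A_t, params, dist_km) {
  W <- ifm_kernel(dist_km, params$alpha)
  r <- ifm_rates(as.numeric(state), W, A_t, params)
  u <- runif(length(state))
  as.integer(ifelse(state > 0, u > r$E, u < r$C))
}

#' Generate an occupancy history from a known IFM
#'
#' Repeated application of the annual transition; one snapshot per year.
#'
#' @param network a \code{patch_network} (its \code{dist_km} is used).
#' @param params an \code{\link{ifm_params}}.
#' @param A_series effective areas: matrix \code{n_years x n_patches} (row
#'   t used for step t), or a vector recycled over years.
#' @param start 0/1 starting occupancy vector.
#' @param n_years number of annual steps.
#' @param seed integer seed.
#' @return list of 0/1 vectors of length \code{n_years + 1} (including the
#'   start).
#' @export
generate_occupancy_history <- function(network, params, A_series, start,
                                       n_years, seed = NULL) {
  A_series <- as_area_matrix(A_series, n_years, length(start))
  with_seed(seed, {
    snaps <- vector("list", n_years + 1)
    snaps[[1]] <- as.integer(start)
    for (t in seq_len(n_years))
      snaps[[t + 1]] <- ifm_step(snaps[[t]], A_series[t, ], params,
                                 network$dist_km)
    snaps
  })
}

as_area_matrix <- function(A_series, n_years, n_patch) {
  if (is.matrix(A_series)) {
    if (nrow(A_series) < n_years)
      stop("A_series has fewer years than n_years")
    A_series[seq_len(n_years), , drop = FALSE]
  } else {
    matrix(rep(A_series, each = n_years), n_years, n_patch)
  }
}

#' Deterministic mean-field occupancy marginals
#'
#' Propagates per-patch occupancy probabilities
#' \code{p(t+1) = p(t) (1 - E(t)) + (1 - p(t)) C(t)}, with connectivity
#' computed from expected source contributions \code{p_j(t) A_j^b}.  A
#' smooth surrogate for the exact joint chain, used inside likelihood
#' fitting; it ignores correlations between patches.
#'
#' @param start starting occupancy (0/1 or probabilities).
#' @param A_series effective-area matrix (years x patches) or vector.
#' @param params an \code{\link{ifm_params}}.
#' @param n_years number of annual steps.
#' @param dist_km patch distance matrix (km).
#' @return per-patch occupancy probabilities after \code{n_years} steps.
#' @export
meanfield_marginals <- function(start, A_series, params, n_years, dist_km) {
  A_series <- as_area_matrix(A_series, n_years, length(start))
  p <- as.numeric(start)
  W <- ifm_kernel(dist_km, params$alpha)
  for (t in seq_len(n_years)) {
    A <- A_series[t, ]
    S <- as.vector(W %*% (p * A^params$b))
    C <- colonisation_prob(S, params$y)
    E <- extinction_prob(C, A, params$mu, params$x)
    p <- p * (1 - E) + (1 - p) * C
  }
  p
}

#' Exact occupancy marginals by joint-chain propagation
#'
#' Propagates the full joint distribution over all \code{2^n} occupancy
#' states year by year (Chapman-Kolmogorov); exact, and feasible only for
#' small networks.  Used as the test oracle for the simulator and the
#' mean-field surrogate.
#'
#' @inheritParams meanfield_marginals
#' @param max_patches refuse larger networks (default 12).
#' @return per-patch exact occupancy probabilities after \code{n_years}
#'   steps.
#' @export
exact_marginals <- function(start, A_series, params, n_years, dist_km,
                            max_patches = 12) {
  n <- length(start)
  if (n > max_patches) stop("network too large for exact enumeration")
  A_series <- as_area_matrix(A_series, n_years, n)
  states <- as.matrix(expand.grid(rep(list(0:1), n)))
  dimnames(states) <- NULL                       # column i = patch i
  prob <- as.numeric(apply(states, 1, function(s)
    all(s == as.numeric(start))))
  W <- ifm_kernel(dist_km, params$alpha)
  for (t in seq_len(n_years)) {
    A <- A_series[t, ]
    newp <- numeric(length(prob))
    for (k in which(prob > 0)) {
      z <- states[k, ]
      S <- as.vector(W %*% (z * A^params$b))
      C <- colonisation_prob(S, params$y)
      E <- extinction_prob(C, A, params$mu, params$x)
      pnext <- z * (1 - E) + (1 - z) * C         # P(occupied next), per patch
      m <- rep(prob[k], length(prob))            # product measure over states
      for (i in seq_len(n))
        m <- m * ifelse(states[, i] == 1, pnext[i], 1 - pnext[i])
      newp <- newp + m
    }
    prob <- newp
  }
  as.vector(t(states) %*% prob)
}
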