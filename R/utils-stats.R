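#' Central binomial acceptance interval for a known success probability
#'
#' Returns, for each probability, the smallest interval of counts
#' \code{[lo, hi]} whose tails each hold less than \code{(1 - level)/2}
#' probability: \code{lo} is the smallest m with \code{P(X <= m) >= a} and
#' \code{hi} the smallest m with \code{P(X <= m) >= 1 - a}, found by binary
#' search on \code{pbinom}.  (A direct \code{qbinom} call is avoided: some
#' R versions return wrong quantiles for success probabilities very close
#' to 1.)  Used to test simulated occupancy frequencies against exact
#' chain marginals.
#'
#' @param n number of trials.
#' @param p success probabilities (vectorised).
#' @param level interval level (default 0.99).
#' @return list with integer vectors \code{lo} and \code{hi}.
#' @export
binomial_ci <- function(n, p, level = 0.99) {
  stopifnot(n >= 1, all(p >= 0 & p <= 1), level > 0, level < 1)
  a <- (1 - level) / 2
  qsearch <- function(target) {
    L <- rep(-1, length(p)); R <- rep(n, length(p))
    while (any(L + 1 < R)) {
      M <- floor((L + R) / 2)
      ok <- pbinom(M, n, p) >= target
      R[ok] <- pmin(R[ok], M[ok])
      L[!ok] <- pmax(L[!ok], M[!ok])
    }
    R
  }
  list(lo = qsearch(a), hi = qsearch(1 - a))
}
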