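# Downscaling of an hourly station series to gridded climate targets:
# per-day affine rescaling of temperature to daily max/min, multiplicative
# rescaling of wind to monthly means, and capped "water-filling" rescaling
# of the hourly sunshine fraction to monthly means.

#' Rescale one day of hourly temperatures to target extremes
#'
#' Applies the affine map that sends the day's observed maximum and minimum
#' exactly onto \code{tmax} and \code{tmin}, preserving the within-day rank
#' order.
#'
#' @param hourly_day numeric vector of 24 hourly temperatures (deg C).
#' @param tmax,tmin target daily maximum and minimum (deg C),
#'   \code{tmax >= tmin}.
#' @param degenerate_fill if \code{TRUE}, a constant input day with
#'   \code{tmax > tmin} (for which no affine map exists) is filled with
#'   \code{(tmax + tmin) / 2} instead of raising an error.
#' @return numeric vector of 24 rescaled temperatures with
#'   \code{max == tmax} and \code{min == tmin}.
#' @export
rescale_day_temperature <- function(hourly_day, tmax, tmin,
                                    degenerate_fill = FALSE) {
  if (length(hourly_day) != 24) stop("expected 24 hourly values")
  if (tmax < tmin) stop("tmax must be >= tmin")
  lo <- min(hourly_day); hi <- max(hourly_day)
  if (hi == lo) {
    if (tmax == tmin) return(rep(tmax, 24))
    if (degenerate_fill) return(rep((tmax + tmin) / 2, 24))
    stop("degenerate day: constant input but tmax > tmin; ",
         "set degenerate_fill = TRUE to fill with the midpoint")
  }
  tmin + (hourly_day - lo) / (hi - lo) * (tmax - tmin)
}

#' Rescale hourly wind speeds to a target monthly mean
#'
#' Multiplicative scaling so the mean of the output equals the target
#' exactly; non-negativity is preserved.
#'
#' @param hourly numeric vector of hourly wind speeds (m/s) for one month.
#' @param target_mean target monthly mean (m/s), >= 0.
#' @return rescaled series.
#' @export
rescale_monthly_wind <- function(hourly, target_mean) {
  if (length(hourly) == 0) stop("empty month")
  if (target_mean < 0) stop("target mean must be >= 0")
  if (any(hourly < 0)) stop("wind speeds must be >= 0")
  m <- mean(hourly)
  if (m == 0) {
    if (target_mean == 0) return(hourly)
    stop("cannot rescale an all-zero wind series to a positive mean")
  }
  hourly * (target_mean / m)
}

#' Rescale hourly sunshine fractions to a target monthly mean with a cap of 1
#'
#' Iterative proportional scaling with capping ("water-filling"): uncapped
#' hours are scaled multiplicatively, any hour exceeding 1 is clamped to 1,
#' and the remaining deficit is redistributed over the still-uncapped hours
#' until the monthly mean matches the target to \code{tol}.  Hours that are
#' zero (e.g. night) stay zero, so the achievable maximum mean is the
#' fraction of nonzero hours; an unreachable target raises an error naming
#' that maximum.
#'
#' @param hourly numeric vector of hourly sunshine fractions in [0, 1] for
#'   one month.
#' @param target_mean target monthly mean fraction in [0, 1].
#' @param tol convergence tolerance on the mean (default 1e-9).
#' @return rescaled series in [0, 1] with \code{mean == target_mean} (to
#'   \code{tol}).
#' @export
rescale_monthly_sunshine <- function(hourly, target_mean, tol = 1e-9) {
  if (length(hourly) == 0) stop("empty month")
  if (any(hourly < 0 | hourly > 1)) stop("sunshine fractions must be in [0, 1]")
  if (target_mean < 0 || target_mean > 1)
    stop("target mean must be in [0, 1]")
  n <- length(hourly)
  achievable <- sum(hourly > 0) / n
  if (target_mean > achievable + tol)
    stop(sprintf(
      "target mean %.6g unreachable: achievable maximum is %.6g given %d zero hours",
      target_mean, achievable, sum(hourly == 0)))
  out <- hourly
  capped <- rep(FALSE, n)
  for (iter in 1:(n + 1)) {
    need <- target_mean * n - sum(out[capped])
    free_sum <- sum(hourly[!capped])
    if (free_sum == 0) break
    f <- need / free_sum
    out[!capped] <- hourly[!capped] * f
    over <- !capped & out > 1
    if (!any(over)) break
    out[over] <- 1
    capped <- capped | over
  }
  out <- pmin(pmax(out, 0), 1)
  if (abs(mean(out) - target_mean) > tol * max(1, n))
    stop("water-filling failed to reach the target mean")
  out
}

#' Downscale an hourly weather series to gridded climate targets
#'
#' Applies \code{\link{rescale_day_temperature}} day by day,
#' \code{\link{rescale_monthly_wind}} and
#' \code{\link{rescale_monthly_sunshine}} month by month.  Days are local
#' civil midnight-to-midnight in the series' own (UTC) clock.
#'
#' @param weather an \code{hourly_weather} data.frame (\code{time},
#'   \code{temp_c}, \code{wind_ms}, \code{sun_frac}).
#' @param targets a \code{climate_targets} list: \code{daily} data.frame
#'   (\code{date}, \code{tmax}, \code{tmin}) and \code{monthly} data.frame
#'   (\code{year}, \code{month}, \code{wind_ms}, \code{sun_frac}).  Days or
#'   months missing from the targets are left unchanged.
#' @param degenerate_fill passed to \code{\link{rescale_day_temperature}}.
#' @return the rescaled \code{hourly_weather}.
#' @export
downscale_weather <- function(weather, targets, degenerate_fill = FALSE) {
  validate_weather(weather)
  lt <- as.POSIXlt(weather$time, tz = "UTC")
  day <- format(weather$time, "%Y-%m-%d", tz = "UTC")
  out <- weather
  dtab <- targets$daily
  if (!is.null(dtab)) {
    idx <- split(seq_len(nrow(weather)), day)
    rows <- match(names(idx), as.character(dtab$date))
    for (k in seq_along(idx)) {
      if (is.na(rows[k]) || length(idx[[k]]) != 24) next
      out$temp_c[idx[[k]]] <- rescale_day_temperature(
        weather$temp_c[idx[[k]]], dtab$tmax[rows[k]], dtab$tmin[rows[k]],
        degenerate_fill = degenerate_fill)
    }
  }
  mtab <- targets$monthly
  if (!is.null(mtab)) {
    ym <- paste(lt$year + 1900, lt$mon + 1)
    idx <- split(seq_len(nrow(weather)), ym)
    rows <- match(names(idx), paste(mtab$year, mtab$month))
    for (k in seq_along(idx)) {
      if (is.na(rows[k])) next
      out$wind_ms[idx[[k]]] <-
        rescale_monthly_wind(out$wind_ms[idx[[k]]], mtab$wind_ms[rows[k]])
      out$sun_frac[idx[[k]]] <-
        rescale_monthly_sunshine(out$sun_frac[idx[[k]]], mtab$sun_frac[rows[k]])
    }
  }
  out
}

#' Derive gridded climate targets from a weather series
#'
#' Convenience generator for synthetic studies: targets are the series' own
#' daily extremes and monthly means, optionally shifted/scaled to emulate a
#' regional gradient between the station and a grid cell.
#'
#' @param weather an \code{hourly_weather}.
#' @param temp_offset additive shift applied to daily tmax and tmin (deg C).
#' @param wind_factor multiplicative factor on monthly mean wind.
#' @param sun_factor multiplicative factor on monthly mean sunshine fraction
#'   (capped at the month's achievable maximum).
#' @return a \code{climate_targets} list (\code{daily}, \code{monthly}).
#' @export
climate_targets_from_weather <- function(weather, temp_offset = 0,
                                         wind_factor = 1, sun_factor = 1) {
  validate_weather(weather)
  day <- format(weather$time, "%Y-%m-%d", tz = "UTC")
  lt <- as.POSIXlt(weather$time, tz = "UTC")
  daily <- data.frame(
    date = unique(day),
    tmax = as.numeric(tapply(weather$temp_c, day, max)[unique(day)]) +
      temp_offset,
    tmin = as.numeric(tapply(weather$temp_c, day, min)[unique(day)]) +
      temp_offset,
    row.names = NULL)
  ym <- paste(lt$year + 1900, lt$mon + 1)
  uym <- unique(ym)
  ach <- as.numeric(tapply(weather$sun_frac > 0, ym, mean)[uym])
  monthly <- data.frame(
    year = as.integer(sub(" .*", "", uym)),
    month = as.integer(sub(".* ", "", uym)),
    wind_ms = as.numeric(tapply(weather$wind_ms, ym, mean)[uym]) * wind_factor,
    sun_frac = pmin(
      as.numeric(tapply(weather$sun_frac, ym, mean)[uym]) * sun_factor, ach),
    row.names = NULL)
  list(daily = daily, monthly = monthly)
}
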