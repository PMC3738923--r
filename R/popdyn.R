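# Temperature-dependent discrete logistic models of transect density
# change.  The fitted linear form regresses annual density change dD on
# {D, D^2, T*D, T*D^2} (no intercept: dD = 0 at D = 0), with the intrinsic
# growth rate r = beta0*T + beta2 and the D^2 coefficient representing
# (under the "paper" sign convention, s = +1) beta1*T + beta3 as stated for
# -r/K, or (under the "logistic" convention, s = -1) r/K itself so that a
# positive carrying capacity K = r / (beta1*T + beta3) exists.

#' One-step density change of the thermal discrete logistic model
#'
#' \code{dD = (beta0*T + beta2) * D + s * (beta1*T + beta3) * D^2}, where
#' \code{s = +1} under the \code{"paper"} convention (the quadratic
#' coefficient is read as the stated \code{-r/K} linear form) and
#' \code{s = -1} under the conventional \code{"logistic"} sign, for which
#' \code{K = (beta0*T + beta2) / (beta1*T + beta3)} is positive when both
#' terms are.
#'
#' @param D density (>= 0); vectorised.
#' @param T_cov thermal covariate (same length as \code{D} or scalar).
#' @param betas numeric length-4 vector \code{c(beta0, beta1, beta2, beta3)}.
#' @param sign_convention \code{"paper"} or \code{"logistic"}.
#' @return density change dD.
#' @export
delta_density <- function(D, T_cov, betas,
                          sign_convention = c("paper", "logistic")) {
  sign_convention <- match.arg(sign_convention)
  stopifnot(length(betas) == 4, all(D >= 0))
  s <- if (sign_convention == "paper") 1 else -1
  (betas[1] * T_cov + betas[3]) * D + s * (betas[2] * T_cov + betas[4]) * D^2
}

#' Generate synthetic transect density series from the logistic model
#'
#' Iterates the quadratic recursion with additive Gaussian noise truncated
#' at zero.  Refitting noise-free output recovers the generating betas
#' exactly (to numerical tolerance).
#'
#' @param betas generating coefficients \code{c(beta0, beta1, beta2, beta3)}.
#' @param T_table data.frame \code{transect}, \code{year}, \code{T_cov}
#'   giving the thermal covariate per transect-year.
#' @param D0 initial density (>= 0), recycled over transects.
#' @param noise_sd sd of the additive Gaussian noise on dD (>= 0).
#' @param seed integer seed.
#' @param sign_convention passed to \code{\link{delta_density}} (default
#'   \code{"logistic"} so a positive carrying capacity exists).
#' @return data.frame \code{transect}, \code{year}, \code{D}.
#' @export
generate_density_series <- function(betas, T_table, D0, noise_sd = 0,
                                    seed = NULL,
                                    sign_convention = "logistic") {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  stopifnot(all(D0 >= 0))
  tr <- sort(unique(T_table$transect))
  D0 <- rep_len(D0, length(tr))
  with_seed(seed, {
    out <- lapply(seq_along(tr), function(i) {
      tt <- T_table[T_table$transect == tr[i], ]
      tt <- tt[order(tt$year), ]
      D <- numeric(nrow(tt))
      D[1] <- D0[i]
      for (k in seq_len(nrow(tt) - 1)) {
        # an extinct population stays extinct: noise applies only to
        # extant populations, so D = 0 is absorbing
        eps <- if (noise_sd > 0 && D[k] > 0) rnorm(1, 0, noise_sd) else 0
        D[k + 1] <- max(0, D[k] +
          delta_density(D[k], tt$T_cov[k], betas, sign_convention) + eps)
      }
      data.frame(transect = tr[i], year = tt$year, D = D)
    })
    do.call(rbind, out)
  })
}

# Build the consecutive-year pairs table used by all model fits: one row
# per (transect, year t) with D_t, dD = D_{t+1} - D_t, and the covariates
# evaluated at year t (lagged quality at year t - 1).  Gaps break pairs.
density_pairs <- function(data) {
  need <- c("transect", "year", "D")
  stopifnot(all(need %in% names(data)))
  out <- lapply(split(data, data$transect), function(d) {
    d <- d[order(d$year), ]
    i <- which(diff(d$year) == 1)
    if (!length(i)) return(NULL)
    p <- data.frame(transect = d$transect[i], year = d$year[i],
                    D = d$D[i], dD = d$D[i + 1] - d$D[i])
    for (cv in c("T_regional", "T_quality")) {
      if (cv %in% names(d)) p[[cv]] <- d[[cv]][i]
    }
    if ("T_quality" %in% names(d)) {
      lag <- match(d$year[i] - 1, d$year)
      p$T_quality_lag <- d$T_quality[lag]
    }
    p
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

model_covariate <- function(model_id) {
  switch(model_id,
         i = NA, ii = NA,
         iii = "T_regional", iv = "T_regional", v = "T_regional",
         vi = "T_quality", vii = "T_quality_lag",
         stop("unknown model id: ", model_id))
}

#' Fit one model of the density-change ladder
#'
#' The seven model structures are: (i) a single \code{r} and \code{K} for
#' all transects (pooled quadratic in \code{D}, no intercept); (ii) as (i)
#' with per-transect random deviations of the \code{D} and \code{D^2}
#' effects; (iii) \code{r} and \code{K} linear in the regional August mean
#' daily maximum temperature (pooled); (iv) as (iii) plus per-transect
#' random deviations of the temperature-independent \code{D}, \code{D^2}
#' effects (intercept level of the \code{r}, \code{K} vs temperature
#' relations); (v) as (iii) plus per-transect random deviations of all four
#' effects (slopes and intercepts); (vi) as (iii) but with annual patch
#' thermal habitat quality as the covariate; (vii) as (vi) with the
#' covariate lagged one year.  Fixed-effect models are fitted by OLS; mixed
#' models by maximum likelihood (\code{lme4::lmer}, \code{REML = FALSE}) so
#' AICs are comparable across fixed-effect structures.
#'
#' @param data density series data.frame with columns \code{transect},
#'   \code{year}, \code{D}, and covariates \code{T_regional} and/or
#'   \code{T_quality} as required by the model.
#' @param model_id one of \code{"i" ... "vii"}.
#' @param sign_convention convention used to report betas (the linear fit
#'   itself is sign-agnostic); see \code{\link{delta_density}}.
#' @param r2_method \code{"cor"} (squared Pearson correlation of fitted vs
#'   observed dD, the default) or \code{"ss"} (1 - SSE/SST).
#' @return a \code{logistic_fit} list: \code{model_id}, \code{betas} (named
#'   \code{beta0..beta3}; \code{NA} where the structure has no such term),
#'   \code{loglik}, \code{AIC}, \code{R2}, \code{n}, \code{k} (parameter
#'   count = fixed effects + variance components + residual variance),
#'   \code{sigma} (residual sd), \code{fitted}, \code{observed},
#'   \code{fit} (the underlying lm/lmerMod object).
#' @export
fit_logistic_model <- function(data, model_id,
                               sign_convention = c("paper", "logistic"),
                               r2_method = c("cor", "ss")) {
  sign_convention <- match.arg(sign_convention)
  r2_method <- match.arg(r2_method)
  pairs <- if (!is.null(attr(data, "is_pairs"))) data else density_pairs(data)
  if (nrow(pairs) < 3) stop("insufficient consecutive-year observations")
  cv <- model_covariate(model_id)
  df <- data.frame(dD = pairs$dD, D = pairs$D, D2 = pairs$D^2,
                   transect = factor(pairs$transect))
  if (!is.na(cv)) {
    if (!cv %in% names(pairs)) stop("covariate ", cv, " missing from data")
    Tv <- pairs[[cv]]
    keep <- !is.na(Tv)
    df <- df[keep, ]; Tv <- Tv[keep]
    if (length(unique(Tv)) < 2)
      stop("singular design: thermal covariate is constant")
    df$TD <- Tv * df$D
    df$TD2 <- Tv * df$D2
  }
  fit <- switch(model_id,
    i = lm(dD ~ 0 + D + D2, data = df),
    ii = lme4::lmer(dD ~ 0 + D + D2 + (0 + D + D2 | transect), data = df,
                    REML = FALSE,
                    control = lme4::lmerControl(calc.derivs = FALSE, check.conv.singular =
                      "ignore")),
    iii = , vi = , vii = lm(dD ~ 0 + D + D2 + TD + TD2, data = df),
    iv = lme4::lmer(dD ~ 0 + D + D2 + TD + TD2 + (0 + D + D2 | transect),
                    data = df, REML = FALSE,
                    control = lme4::lmerControl(calc.derivs = FALSE, check.conv.singular =
                      "ignore")),
    v = lme4::lmer(dD ~ 0 + D + D2 + TD + TD2 +
                     (0 + D + D2 + TD + TD2 | transect),
                   data = df, REML = FALSE,
                   control = lme4::lmerControl(calc.derivs = FALSE, check.conv.singular =
                     "ignore")))
  ll <- logLik(fit)
  fe <- if (inherits(fit, "merMod")) lme4::fixef(fit) else coef(fit)
  s <- if (sign_convention == "paper") 1 else -1
  betas <- c(beta0 = unname(fe["TD"]), beta1 = s * unname(fe["TD2"]),
             beta2 = unname(fe["D"]), beta3 = s * unname(fe["D2"]))
  fv <- fitted(fit)
  r2 <- if (r2_method == "cor") cor(fv, df$dD)^2 else
    1 - sum((df$dD - fv)^2) / sum((df$dD - mean(df$dD))^2)
  structure(list(model_id = model_id, betas = betas,
                 loglik = as.numeric(ll), AIC = AIC(fit), R2 = r2,
                 n = nrow(df), k = attr(ll, "df"),
                 sigma = stats::sigma(fit), fitted = fv, observed = df$dD,
                 fit = fit),
            class = "logistic_fit")
}

#' Fit and compare the seven-model ladder
#'
#' @inheritParams fit_logistic_model
#' @return data.frame with one row per model: \code{model}, \code{k}
#'   (parameters), \code{R2}, \code{AIC}, \code{dAIC} (relative to the
#'   best), sorted by AIC ascending; models that fail to fit carry
#'   \code{NA}s and an \code{error} message.
#' @export
model_ladder <- function(data, sign_convention = "paper",
                         r2_method = "cor") {
  ids <- c("i", "ii", "iii", "iv", "v", "vi", "vii")
  pairs <- density_pairs(data)
  attr(pairs, "is_pairs") <- TRUE
  rows <- lapply(ids, function(id) {
    f <- tryCatch(fit_logistic_model(pairs, id, sign_convention, r2_method),
                  error = function(e) e)
    if (inherits(f, "error"))
      data.frame(model = id, k = NA, R2 = NA, AIC = NA,
                 error = conditionMessage(f))
    else data.frame(model = id, k = f$k, R2 = f$R2, AIC = f$AIC, error = "")
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$AIC), ]
  tab$dAIC <- tab$AIC - min(tab$AIC, na.rm = TRUE)
  rownames(tab) <- NULL
  tab[, c("model", "k", "R2", "AIC", "dAIC", "error")]
}

# Fast R^2 of the no-intercept OLS fit dD ~ {D, D2, TD, TD2}; used in the
# randomisation inner loop.
ols_r2 <- function(X, y) {
  f <- .lm.fit(X, y)
  fv <- y - f$residuals
  suppressWarnings(r <- cor(fv, y))
  if (is.na(r)) 0 else r^2
}

#' Randomisation test of the thermal covariate's explanatory power
#'
#' The covariate values are permuted jointly across all transect-year
#' cells, the model is refitted to the observed density changes for each
#' permutation, and the observed \eqn{R^2} is compared with the null
#' distribution: \code{p = (1 + #(null R2 >= observed)) / (n_reps + 1)}.
#' Permutations that leave the covariate constant are redrawn (with a
#' logged count).
#'
#' @inheritParams fit_logistic_model
#' @param n_reps number of permutations (>= 1).
#' @param seed integer seed.
#' @return list: \code{p_value}, \code{observed_R2}, \code{null_R2}
#'   (length \code{n_reps}), \code{n_redraws}.
#' @export
randomisation_test <- function(data, model_id = "vi", n_reps = 10000,
                               seed = NULL, r2_method = "cor") {
  stopifnot(n_reps >= 1)
  if (!model_id %in% c("iii", "vi", "vii"))
    stop("randomisation test applies to the pooled covariate models ",
         "(iii, vi, vii)")
  pairs <- density_pairs(data)
  cv <- model_covariate(model_id)
  Tv <- pairs[[cv]]
  keep <- !is.na(Tv)
  pairs <- pairs[keep, ]; Tv <- Tv[keep]
  D <- pairs$D; D2 <- D^2; y <- pairs$dD
  obs <- ols_r2(cbind(D, D2, Tv * D, Tv * D2), y)
  n <- length(Tv)
  with_seed(seed, {
    null_r2 <- numeric(n_reps)
    redraws <- 0L
    for (r in seq_len(n_reps)) {
      repeat {
        Tp <- Tv[sample.int(n)]
        if (length(unique(Tp)) > 1) break
        redraws <- redraws + 1L
      }
      null_r2[r] <- ols_r2(cbind(D, D2, Tp * D, Tp * D2), y)
    }
    list(p_value = (1 + sum(null_r2 >= obs)) / (n_reps + 1),
         observed_R2 = obs, null_R2 = null_r2, n_redraws = redraws)
  })
}

#' Carrying capacity and growth rate at a covariate value
#'
#' \code{r = beta0*T + beta2}; \code{K = -r / (beta1*T + beta3)} under the
#' \code{"paper"} convention and \code{K = r / (beta1*T + beta3)} under the
#' \code{"logistic"} convention (NA where the denominator is 0).
#'
#' @inheritParams delta_density
#' @return data.frame \code{T_cov}, \code{r}, \code{K}.
#' @export
rate_and_capacity <- function(T_cov, betas,
                              sign_convention = c("paper", "logistic")) {
  sign_convention <- match.arg(sign_convention)
  r <- betas[1] * T_cov + betas[3]
  den <- betas[2] * T_cov + betas[4]
  K <- ifelse(den == 0, NA_real_,
              if (sign_convention == "paper") -r / den else r / den)
  data.frame(T_cov = T_cov, r = r, K = K)
}
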