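#' Temperature window for a model fit
#'
#' @param low_c,high_c Window bounds in degrees Celsius, `low_c < high_c`.
#'   Endpoints are inclusive.
#' @return A `temperature_window` list.
#' @export
temperature_window <- function(low_c, high_c) {
  stopifnot(is.finite(low_c), is.finite(high_c))
  if (low_c >= high_c) stop("window must have low_c < high_c", call. = FALSE)
  structure(list(low_c = low_c, high_c = high_c), class = "temperature_window")
}

window_label <- function(w) sprintf("%g-%g", w$low_c, w$high_c)

# basic schema check for a rate-observation table
validate_observations <- function(obs) {
  required <- c("isolate", "enzyme", "temperature_c", "replicate", "rate")
  missing <- setdiff(required, names(obs))
  if (length(missing) > 0) {
    stop("observation table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(obs$temperature_c <= -273.15)) {
    stop("temperature below absolute zero in observations", call. = FALSE)
  }
  obs
}

# keep rows inside the (inclusive) window, dropping nonpositive rates with a
# warning; ln-scale fits cannot use rates <= 0 (below-detection activity)
prepare_fit_data <- function(obs, window) {
  obs <- validate_observations(obs)
  obs <- obs[obs$temperature_c >= window$low_c &
               obs$temperature_c <= window$high_c, , drop = FALSE]
  n_dropped <- sum(obs$rate <= 0)
  if (n_dropped > 0) {
    warning(sprintf("dropping %d nonpositive rate(s) before ln-scale fitting",
                    n_dropped), call. = FALSE)
    obs <- obs[obs$rate > 0, , drop = FALSE]
  }
  if (nrow(obs) == 0) stop("no positive-rate observations in window", call. = FALSE)
  attr(obs, "n_dropped_nonpositive") <- n_dropped
  obs
}

fit_combination <- function(obs) {
  iso <- unique(obs$isolate)
  enz <- unique(obs$enzyme)
  list(isolate = if (length(iso) == 1) iso else NA_character_,
       enzyme = if (length(enz) == 1) enz else NA_character_)
}

new_fit_result <- function(model, params, coef, covariance, rss, tss, n_obs,
                           n_params, window, converged, combination,
                           n_dropped = 0L) {
  structure(list(model = model, params = params, coef = coef,
                 covariance = covariance, rss = rss, tss = tss,
                 n_obs = n_obs, n_params = n_params, window = window,
                 converged = converged, combination = combination,
                 n_dropped_nonpositive = n_dropped),
            class = "tt_fit")
}

#' @export
print.tt_fit <- function(x, ...) {
  cat(sprintf("%s fit (%s, %s), window %s C: n = %d, rss = %.4g, converged = %s\n",
              x$model, x$combination$isolate, x$combination$enzyme,
              window_label(x$window), x$n_obs, x$rss, x$converged))
  print(round(x$coef, 4))
  invisible(x)
}

#' Predict log rate from a fitted model
#'
#' @param fit A `tt_fit` from [fit_arrhenius()] or [fit_mmrt()].
#' @param temperature_c Temperatures in degrees Celsius.
#' @param const Physical constants.
#' @return Predicted natural-log rates.
#' @export
predict_ln_rate <- function(fit, temperature_c, const = phys_constants()) {
  temp_k <- celsius_to_kelvin(temperature_c)
  switch(fit$model,
         Arrhenius = arrhenius_ln_rate(fit$params, temp_k, const),
         MMRT = mmrt_ln_rate(fit$params, temp_k, const),
         stop("unknown model: ", fit$model, call. = FALSE))
}

#' Fit the Arrhenius model to replicated rate data
#'
#' Minimizes \eqn{\sum (\ln rate - [\ln A - E_A/(R T)])^2} over the
#' observations inside `window` (inclusive bounds).  The model is linear in
#' \eqn{1/T}, so the fit is ordinary least squares with the usual
#' linear-model covariance, transformed to the `(ln_A, E_A)` scale.
#' Replicate-level points are used, not temperature means.
#'
#' @param obs Data frame of observations with columns `isolate`, `enzyme`,
#'   `temperature_c`, `replicate`, `rate`.  Nonpositive rates are dropped
#'   with a warning.
#' @param window A [temperature_window()]; defaults to the data range.
#' @param const Physical constants.
#' @return A `tt_fit` with `model = "Arrhenius"`, coefficients
#'   `(ln_A, E_A)`, their covariance, and ln-scale residual/total sums of
#'   squares.
#' @export
fit_arrhenius <- function(obs, window = NULL, const = phys_constants()) {
  obs <- validate_observations(obs)
  if (is.null(window)) {
    window <- temperature_window(min(obs$temperature_c), max(obs$temperature_c))
  }
  dat <- prepare_fit_data(obs, window)
  if (length(unique(dat$temperature_c)) < 2) {
    stop("need at least 2 distinct temperatures in the window", call. = FALSE)
  }
  inv_T <- 1 / celsius_to_kelvin(dat$temperature_c)
  y <- log(dat$rate)
  lmfit <- stats::lm(y ~ inv_T)
  b <- stats::coef(lmfit)
  V <- suppressWarnings(stats::vcov(lmfit))  # summary.lm warns on rss ~ 0
  # ln k = ln_A - (E_A/R) * (1/T)  =>  E_A = -R * slope
  J <- diag(c(1, -const$R))
  params <- arrhenius_params(ln_A = unname(b[1]), E_A = unname(-const$R * b[2]))
  covariance <- J %*% V %*% t(J)
  dimnames(covariance) <- list(c("ln_A", "E_A"), c("ln_A", "E_A"))
  new_fit_result(
    model = "Arrhenius", params = params,
    coef = c(ln_A = params$ln_A, E_A = params$E_A),
    covariance = covariance,
    rss = sum(stats::resid(lmfit)^2), tss = sum((y - mean(y))^2),
    n_obs = nrow(dat), n_params = 2L, window = window, converged = TRUE,
    combination = fit_combination(dat),
    n_dropped = attr(dat, "n_dropped_nonpositive"))
}

#' Starting values for the MMRT fit
#'
#' `dH` is initialized from an Arrhenius fit to the rising limb
#' (temperatures at or below the empirical-maximum temperature) via
#' \eqn{\Delta H^\ddagger \approx E_A - R \bar T}; if the rising limb has a
#' single temperature the global Arrhenius slope is used instead.  `dCp`
#' starts at -5000 J mol^-1 K^-1, and `dS` is chosen so the curve matches
#' the mean log rate at the temperature closest to `T0`.
#'
#' @inheritParams fit_arrhenius
#' @param T0 Reference temperature, K.
#' @return An [mmrt_params()] object.
#' @export
init_mmrt <- function(obs, T0 = 298.15, const = phys_constants()) {
  dat <- prepare_fit_data(obs, temperature_window(min(obs$temperature_c),
                                                  max(obs$temperature_c)))
  temps <- sort(unique(dat$temperature_c))
  if (length(temps) < 4) {
    stop("need at least 4 distinct temperatures for an MMRT fit", call. = FALSE)
  }
  mean_ln <- vapply(temps, function(tc) {
    mean(log(dat$rate[dat$temperature_c == tc]))
  }, numeric(1))
  t_max <- temps[which.max(mean_ln)]
  rising <- temps[temps <= t_max]
  arr <- if (length(rising) >= 2) {
    suppressWarnings(fit_arrhenius(dat, temperature_window(min(rising) - 1e-9,
                                                           t_max + 1e-9), const))
  } else {
    suppressWarnings(fit_arrhenius(dat, const = const))
  }
  dH0 <- arr$params$E_A - const$R * mean(celsius_to_kelvin(dat$temperature_c))
  dCp0 <- -5000
  t_ref <- temps[which.min(abs(celsius_to_kelvin(temps) - T0))]
  tk_ref <- celsius_to_kelvin(t_ref)
  y_ref <- mean_ln[temps == t_ref]
  # solve mmrt_ln_rate(tk_ref) = y_ref for dS
  dS0 <- const$R * (y_ref - log(const$kB_over_h * tk_ref) +
                      (dH0 + dCp0 * (tk_ref - T0)) / (const$R * tk_ref)) -
    dCp0 * (log(tk_ref) - log(T0))
  mmrt_params(dH = dH0, dS = dS0, dCp = dCp0, T0 = T0)
}

# Jacobian of mmrt_ln_rate in (dH, dS, dCp); the model is linear in the
# three coefficients, so this does not depend on them
mmrt_jacobian <- function(temp_k, T0, const) {
  cbind(dH = -1 / (const$R * temp_k),
        dS = rep(1 / const$R, length(temp_k)),
        dCp = -(temp_k - T0) / (const$R * temp_k) +
          (log(temp_k) - log(T0)) / const$R)
}

#' Fit the MMRT model to replicated rate data
#'
#' Minimizes \eqn{\sum (\ln rate - \ln k_{MMRT})^2} over
#' \eqn{(\Delta H^\ddagger, \Delta S^\ddagger, \Delta C_p^\ddagger)} with
#' `T0` fixed, by Gauss-Newton iteration with step halving.  The MMRT curve
#' is linear in its three coefficients, so the iteration converges at the
#' first full step; the damped loop guards degenerate designs.  If the fit
#' does not converge from [init_mmrt()] starting values, restarts at
#' `dCp` in \{-1000, -5000, -12000\} are tried.  The coefficient covariance
#' is \eqn{s^2 (J^\top J)^{-1}} with \eqn{s^2 = rss/(n - 3)}.
#'
#' @inheritParams fit_arrhenius
#' @param T0 Reference temperature, K (fixed, not fitted).
#' @param max_iter Maximum Gauss-Newton iterations.
#' @param tol Relative RSS-change convergence tolerance (a coefficient step
#'   below 1e-8 also terminates).
#' @param start Optional [mmrt_params()] starting values.
#' @return A `tt_fit` with `model = "MMRT"`; its `params` carry `T0` and
#'   the `converged` flag is honest (a non-converged fit is returned with
#'   `converged = FALSE` and a warning, never silently).
#' @export
fit_mmrt <- function(obs, window = NULL, T0 = 298.15, max_iter = 200,
                     tol = 1e-10, start = NULL, const = phys_constants()) {
  obs <- validate_observations(obs)
  if (is.null(window)) {
    window <- temperature_window(min(obs$temperature_c), max(obs$temperature_c))
  }
  dat <- prepare_fit_data(obs, window)
  if (length(unique(dat$temperature_c)) < 4) {
    stop("need at least 4 distinct temperatures for an MMRT fit", call. = FALSE)
  }
  temp_k <- celsius_to_kelvin(dat$temperature_c)
  y <- log(dat$rate)
  J <- mmrt_jacobian(temp_k, T0, const)

  gauss_newton <- function(theta0) {
    theta <- theta0
    rss <- sum((y - mmrt_ln_rate(mmrt_params(theta[1], theta[2], theta[3], T0),
                                 temp_k, const))^2)
    converged <- FALSE
    for (iter in seq_len(max_iter)) {
      r <- y - mmrt_ln_rate(mmrt_params(theta[1], theta[2], theta[3], T0),
                            temp_k, const)
      step <- tryCatch(solve(crossprod(J), crossprod(J, r)),
                       error = function(e) NULL)
      if (is.null(step)) break
      step <- drop(step)
      lambda <- 1
      repeat {
        cand <- theta + lambda * step
        rss_new <- sum((y - mmrt_ln_rate(mmrt_params(cand[1], cand[2], cand[3],
                                                     T0), temp_k, const))^2)
        if (is.finite(rss_new) && rss_new <= rss) break
        lambda <- lambda / 2
        if (lambda < 1e-10) break
      }
      if (lambda < 1e-10) break
      delta <- abs(rss - rss_new) / max(rss, .Machine$double.eps)
      theta <- theta + lambda * step
      rss <- rss_new
      if (delta < tol || max(abs(lambda * step)) < 1e-8) {
        converged <- TRUE
        break
      }
    }
    list(theta = theta, rss = rss, converged = converged)
  }

  init <- if (is.null(start)) init_mmrt(dat, T0 = T0, const = const) else start
  res <- gauss_newton(c(init$dH, init$dS, init$dCp))
  if (!res$converged) {
    for (dcp_try in c(-1000, -5000, -12000)) {
      alt <- init
      alt$dCp <- dcp_try
      res2 <- gauss_newton(c(alt$dH, alt$dS, alt$dCp))
      if (res2$converged) {
        res <- res2
        break
      }
      if (res2$rss < res$rss) res <- res2
    }
  }
  if (!res$converged) {
    warning("MMRT fit did not converge after multi-start fallback", call. = FALSE)
  }
  n <- nrow(dat)
  s2 <- res$rss / (n - 3)
  covariance <- s2 * solve(crossprod(J))
  dimnames(covariance) <- list(c("dH", "dS", "dCp"), c("dH", "dS", "dCp"))
  params <- mmrt_params(res$theta[1], res$theta[2], res$theta[3], T0)
  new_fit_result(
    model = "MMRT", params = params,
    coef = c(dH = params$dH, dS = params$dS, dCp = params$dCp),
    covariance = covariance,
    rss = res$rss, tss = sum((y - mean(y))^2),
    n_obs = n, n_params = 3L, window = window, converged = res$converged,
    combination = fit_combination(dat),
    n_dropped = attr(dat, "n_dropped_nonpositive"))
}

#' Monte Carlo standard errors for Topt and TSmax
#'
#' Draws coefficient vectors from a multivariate normal centered at the
#' fitted MMRT coefficients with the fit covariance, computes the
#' temperature optimum and the point of maximum temperature sensitivity per
#' draw, and reports the sample standard deviations as standard errors.
#' Draws without a finite optimum (`dCp >= -R`) or without a bracketed
#' inflection are counted in `n_failed_draws` and excluded rather than
#' clamped (clamping would bias the SEs).  The point estimates are computed
#' from the fitted coefficients, not the draw means.
#'
#' @param fit A converged MMRT `tt_fit`.
#' @param n_draws Number of Monte Carlo draws (default 1000).
#' @param seed Integer seed; required, so every run is reproducible.
#' @param bracket_low Lower bracket for the TSmax search, K.
#' @param const Physical constants.
#' @return A `trait_estimate` list: `topt`, `topt_se`, `tsmax`, `tsmax_se`
#'   (SEs in K, identical in C), `n_draws`, `seed`, `n_failed_draws`.
#' @export
mc_trait_se <- function(fit, n_draws = 1000, seed, bracket_low = 250,
                        const = phys_constants()) {
  if (missing(seed)) stop("seed is required for Monte Carlo draws", call. = FALSE)
  if (fit$model != "MMRT") stop("trait Monte Carlo requires an MMRT fit", call. = FALSE)
  if (!fit$converged) stop("fit did not converge; traits not propagated", call. = FALSE)
  eig <- eigen(fit$covariance, symmetric = TRUE, only.values = TRUE)$values
  if (any(eig < -1e-8 * max(abs(eig), 1))) {
    stop("fit covariance is not positive semidefinite", call. = FALSE)
  }
  point_topt <- topt(fit$params, const)
  point_tsmax <- tsmax(fit$params, const, bracket_low)
  set.seed(seed)
  draws <- MASS::mvrnorm(n_draws, mu = fit$coef, Sigma = fit$covariance)
  colnames(draws) <- names(fit$coef)
  topt_d <- rep(NA_real_, n_draws)
  tsmax_d <- rep(NA_real_, n_draws)
  for (i in seq_len(n_draws)) {
    p <- mmrt_params(draws[i, "dH"], draws[i, "dS"], draws[i, "dCp"],
                     fit$params$T0)
    ti <- tryCatch(topt(p, const)$temperature_K, error = function(e) NA_real_)
    if (!is.na(ti)) {
      topt_d[i] <- ti
      tsmax_d[i] <- tryCatch(tsmax(p, const, bracket_low)$temperature_K,
                             error = function(e) NA_real_)
    }
  }
  ok <- !is.na(topt_d) & !is.na(tsmax_d)
  n_failed <- sum(!ok)
  if (n_failed > n_draws / 2) {
    stop("degenerate uncertainty: more than half of the Monte Carlo draws ",
         "had no optimum/inflection", call. = FALSE)
  }
  structure(list(topt = point_topt, topt_se = stats::sd(topt_d[ok]),
                 tsmax = point_tsmax, tsmax_se = stats::sd(tsmax_d[ok]),
                 n_draws = n_draws, seed = seed, n_failed_draws = n_failed),
            class = "trait_estimate")
}

#' @export
print.trait_estimate <- function(x, ...) {
  cat(sprintf("Topt  = %.2f C (SE %.2f)\nTSmax = %.2f C (SE %.2f)\n[%d draws, %d failed, seed %d]\n",
              x$topt$temperature_C, x$topt_se, x$tsmax$temperature_C,
              x$tsmax_se, x$n_draws, x$n_failed_draws, x$seed))
  invisible(x)
}
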