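#' Small-sample corrected AIC for a least-squares fit
#'
#' Least-squares form \eqn{n \ln(rss/n) + 2p + 2p(p+1)/(n-p-1)} with
#' \eqn{p = n_{params} + 1}: the error variance is counted as an estimated
#' parameter, the standard convention for least-squares AICc.
#'
#' @param rss Residual sum of squares (> 0).
#' @param n_obs Number of observations.
#' @param n_params Number of fitted model coefficients (excluding the error
#'   variance).
#' @return The AICc value.
#' @export
aicc <- function(rss, n_obs, n_params) {
  p <- n_params + 1
  if (n_obs <= p + 1) stop("AICc undefined: n_obs <= n_params + 2", call. = FALSE)
  if (rss <= 0) stop("AICc requires rss > 0", call. = FALSE)
  n_obs * log(rss / n_obs) + 2 * p + 2 * p * (p + 1) / (n_obs - p - 1)
}

#' Adjusted R-squared for a least-squares fit
#'
#' \eqn{1 - (rss/(n - p - 1)) / (tss/(n - 1))} with `p = n_params`; may be
#' negative for fits worse than the mean-only model.
#'
#' @param rss,tss Residual and corrected total sums of squares.
#' @inheritParams aicc
#' @export
adjusted_r2 <- function(rss, tss, n_obs, n_params) {
  if (n_obs <= n_params + 1) {
    stop("adjusted R^2 undefined: no residual degrees of freedom", call. = FALSE)
  }
  1 - (rss / (n_obs - n_params - 1)) / (tss / (n_obs - 1))
}

#' Lack-of-fit decomposition of a fitted temperature-response model
#'
#' Splits the residual sum of squares (on the ln-rate scale) into pure
#' error — within-temperature replicate scatter around the temperature
#' means — and lack of fit, the systematic misfit of the model to those
#' means.  The F statistic uses `df_lof = n_distinct_temps - n_params`
#' (coefficient count) and `df_pure = n_obs - n_distinct_temps`.
#' `pct_lof_of_total` expresses the lack-of-fit SS as a percentage of the
#' corrected total SS.
#'
#' By default the decomposition is over the fit's own window; supplying
#' `eval_window` evaluates the model (including extrapolation) against the
#' observations of a different window, which is how window-limited fits
#' are compared against a common data set.
#'
#' @param obs Observation data frame (see [fit_arrhenius()]).
#' @param fit A `tt_fit`.
#' @param eval_window Optional [temperature_window()] selecting the
#'   evaluation data; defaults to `fit$window`.
#' @param const Physical constants.
#' @return An `lof_result` list: `ss_pure`, `ss_lof`, `ss_total`, `rss`,
#'   `df_lof`, `df_pure`, `f_stat`, `p_value`, `pct_lof_of_total`.
#' @export
lack_of_fit <- function(obs, fit, eval_window = NULL, const = phys_constants()) {
  if (is.null(eval_window)) eval_window <- fit$window
  dat <- prepare_fit_data(obs, eval_window)
  temps <- unique(dat$temperature_c)
  reps_per_temp <- table(dat$temperature_c)
  if (!any(reps_per_temp >= 2)) {
    stop("lack of fit undefined: no temperature has replication", call. = FALSE)
  }
  y <- log(dat$rate)
  pred <- predict_ln_rate(fit, dat$temperature_c, const)
  temp_means <- stats::ave(y, dat$temperature_c)
  ss_pure <- sum((y - temp_means)^2)
  rss <- sum((y - pred)^2)
  ss_lof <- rss - ss_pure
  ss_total <- sum((y - mean(y))^2)
  df_lof <- length(temps) - fit$n_params
  df_pure <- nrow(dat) - length(temps)
  f_stat <- if (df_lof > 0 && df_pure > 0 && ss_pure > 0) {
    (ss_lof / df_lof) / (ss_pure / df_pure)
  } else {
    NA_real_
  }
  p_value <- if (is.finite(f_stat)) {
    stats::pf(f_stat, df_lof, df_pure, lower.tail = FALSE)
  } else {
    NA_real_
  }
  structure(list(ss_pure = ss_pure, ss_lof = ss_lof, ss_total = ss_total,
                 rss = rss, df_lof = df_lof, df_pure = df_pure,
                 f_stat = f_stat, p_value = p_value,
                 pct_lof_of_total = 100 * ss_lof / ss_total),
            class = "lof_result")
}

#' Percent prediction error of a fitted model
#'
#' For every replicate at the requested temperatures, computes
#' \eqn{100 (\hat{rate} - rate)/rate} on the natural rate scale (the
#' predicted ln rate is exponentiated first).  Temperatures outside the
#' fit window are deliberately included — extrapolation error is the point
#' of the comparison; requested temperatures absent from the data are
#' skipped with a warning.
#'
#' @inheritParams lack_of_fit
#' @param temps_c Temperatures (Celsius) at which to evaluate; default the
#'   sub-denaturing assay temperatures 4, 11, 25, 35.
#' @param scale `"rate"` (default) or `"ln"` for error on the log scale.
#' @return A data frame with one row per replicate evaluated: `isolate`,
#'   `enzyme`, `model`, `window`, `temperature_c`, `replicate`,
#'   `observed`, `predicted`, `percent_error`.
#' @export
percent_error <- function(obs, fit, temps_c = c(4, 11, 25, 35),
                          scale = c("rate", "ln"), const = phys_constants()) {
  scale <- match.arg(scale)
  obs <- validate_observations(obs)
  obs <- obs[obs$rate > 0, , drop = FALSE]
  present <- temps_c[temps_c %in% obs$temperature_c]
  absent <- setdiff(temps_c, present)
  if (length(absent) > 0) {
    warning("requested temperature(s) absent from data, skipped: ",
            paste(absent, collapse = ", "), call. = FALSE)
  }
  dat <- obs[obs$temperature_c %in% present, , drop = FALSE]
  pred_ln <- predict_ln_rate(fit, dat$temperature_c, const)
  pe <- if (scale == "rate") {
    100 * (exp(pred_ln) - dat$rate) / dat$rate
  } else {
    100 * (pred_ln - log(dat$rate)) / log(dat$rate)
  }
  data.frame(isolate = dat$isolate, enzyme = dat$enzyme,
             model = fit$model, window = window_label(fit$window),
             temperature_c = dat$temperature_c, replicate = dat$replicate,
             observed = dat$rate, predicted = exp(pred_ln),
             percent_error = pe, row.names = NULL)
}

#' Compare MMRT and Arrhenius fits for one isolate-enzyme combination
#'
#' Fits MMRT over the full temperature window and Arrhenius over each
#' window in `windows` (defaults: 4-25, 4-35, 4-60 C).  The AICc /
#' adjusted-R^2 comparison is made on the shared full-window data (MMRT vs
#' the widest-window Arrhenius fit); models within `aicc_threshold` AICc
#' units are called `"equivalent"`, and an exact tie prefers the model with
#' fewer coefficients.  Also returns a per-model lack-of-fit decomposition
#' and the activation-energy profile across windows.
#'
#' @param obs Observations for a single isolate-enzyme combination.
#' @param windows List of [temperature_window()]s for the Arrhenius refits;
#'   the widest is treated as the full window.
#' @param T0 MMRT reference temperature, K.
#' @param aicc_threshold AICc-difference threshold below which the two
#'   models are reported as equivalent (default 2, the usual convention).
#' @param const Physical constants.
#' @return A list of class `tt_comparison`: `comparison` (one-row data
#'   frame with AICc, adjusted R^2, `delta_aicc = aicc_arr - aicc_mmrt` and
#'   `preferred`), `ea_profile` (data frame of window, `E_A`, `E_A_se`),
#'   `lof` (named list of `lof_result`), and the underlying `fits`.
#' @export
compare_models <- function(obs, windows = default_windows(), T0 = 298.15,
                           aicc_threshold = 2, const = phys_constants()) {
  obs <- validate_observations(obs)
  widths <- vapply(windows, function(w) w$high_c - w$low_c, numeric(1))
  full <- windows[[which.max(widths)]]
  fit_m <- fit_mmrt(obs, window = full, T0 = T0, const = const)
  fits_a <- lapply(windows, function(w) fit_arrhenius(obs, w, const))
  names(fits_a) <- vapply(windows, window_label, character(1))
  fit_a_full <- fits_a[[window_label(full)]]

  aicc_m <- aicc(fit_m$rss, fit_m$n_obs, fit_m$n_params)
  aicc_a <- aicc(fit_a_full$rss, fit_a_full$n_obs, fit_a_full$n_params)
  delta <- aicc_a - aicc_m
  preferred <- if (abs(delta) < aicc_threshold) {
    if (delta == 0) "Arrhenius" else "equivalent"  # tie -> fewer coefficients
  } else if (delta > 0) {
    "MMRT"
  } else {
    "Arrhenius"
  }
  comb <- fit_m$combination
  comparison <- data.frame(
    isolate = comb$isolate, enzyme = comb$enzyme,
    aicc_mmrt = aicc_m, aicc_arr = aicc_a,
    adj_r2_mmrt = adjusted_r2(fit_m$rss, fit_m$tss, fit_m$n_obs, fit_m$n_params),
    adj_r2_arr = adjusted_r2(fit_a_full$rss, fit_a_full$tss,
                             fit_a_full$n_obs, fit_a_full$n_params),
    delta_aicc = delta, preferred = preferred, row.names = NULL)

  ea_profile <- do.call(rbind, lapply(fits_a, function(f) {
    data.frame(isolate = comb$isolate, enzyme = comb$enzyme,
               window = window_label(f$window),
               E_A = f$params$E_A, E_A_se = sqrt(f$covariance["E_A", "E_A"]),
               row.names = NULL)
  }))

  lof <- c(list(MMRT = lack_of_fit(obs, fit_m, const = const)),
           lapply(fits_a, function(f) lack_of_fit(obs, f, const = const)))
  names(lof) <- c("MMRT", paste0("Arrhenius_", names(fits_a)))

  structure(list(comparison = comparison, ea_profile = ea_profile,
                 lof = lof, fits = c(list(MMRT = fit_m), fits_a)),
            class = "tt_comparison")
}

#' Default Arrhenius refit windows
#'
#' The 4-25, 4-35 and 4-60 C windows used throughout the analysis: the
#' narrow windows cover biologically relevant soil temperatures, the wide
#' one the full assay range.
#'
#' @return A list of three [temperature_window()]s.
#' @export
default_windows <- function() {
  list(temperature_window(4, 25), temperature_window(4, 35),
       temperature_window(4, 60))
}
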