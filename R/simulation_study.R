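#' Parameter-recovery and model-selection simulation study
#'
#' Repeatedly simulates the full assay design (19 retained combinations,
#' 6 temperatures, 8 replicates, log-scale noise), refits MMRT and
#' Arrhenius per combination, and records recovery and model-selection
#' summaries.  Per simulation and combination: the relative error of the
#' fitted heat capacity of activation, the absolute error of the fitted
#' temperature optimum (Celsius), and the AICc difference between the
#' full-window Arrhenius and MMRT fits.  Optionally also the pooled
#' lack-of-fit percentages of the three models (MMRT 4-60, Arrhenius 4-35,
#' Arrhenius 4-25), all evaluated against the common 4-35 C observations.
#'
#' @param n_sims Number of simulated data sets.
#' @param seed Base seed; simulation `s` uses `seed + s`.
#' @param design Assay design; defaults to [default_design()] at `seed`.
#' @param windows Arrhenius windows (see [default_windows()]).
#' @param lof Also compute the lack-of-fit summaries (slower).
#' @return A list with `per_fit` (data frame: sim, isolate, enzyme,
#'   `dcp_rel_error`, `topt_abs_error_c`, `delta_aicc`) and, when
#'   `lof = TRUE`, `lof_by_sim` (data frame: sim, `pct_mmrt`,
#'   `pct_arr_4_35`, `pct_arr_4_25`, `ordered` flag).
#' @export
recovery_study <- function(n_sims, seed, design = default_design(seed),
                           windows = default_windows(), lof = TRUE) {
  widths <- vapply(windows, function(w) w$high_c - w$low_c, numeric(1))
  full <- windows[[which.max(widths)]]
  w35 <- temperature_window(4, 35)
  w25 <- temperature_window(4, 25)
  truth <- design$true_traits
  keys <- paste(truth$isolate, truth$enzyme, sep = ":")
  per_fit <- vector("list", n_sims)
  lof_rows <- vector("list", n_sims)
  for (s in seq_len(n_sims)) {
    d <- design
    d$seed <- seed + s
    obs <- generate_rates(d, keep_below_detection = FALSE)
    obs_key <- paste(obs$isolate, obs$enzyme, sep = ":")
    rows <- vector("list", length(keys))
    ss_lof <- c(mmrt = 0, a35 = 0, a25 = 0)
    ss_tot <- 0
    for (i in seq_along(keys)) {
      oi <- obs[obs_key == keys[i], , drop = FALSE]
      fm <- fit_mmrt(oi, window = full, T0 = design$true_params[[keys[i]]]$T0)
      fa <- fit_arrhenius(oi, full)
      topt_hat <- tryCatch(topt(fm$params)$temperature_C,
                           error = function(e) NA_real_)
      rows[[i]] <- data.frame(
        sim = s, isolate = truth$isolate[i], enzyme = truth$enzyme[i],
        dcp_rel_error = abs(fm$params$dCp - truth$dCp[i]) / abs(truth$dCp[i]),
        topt_abs_error_c = abs(topt_hat - truth$topt_c[i]),
        delta_aicc = aicc(fa$rss, fa$n_obs, fa$n_params) -
          aicc(fm$rss, fm$n_obs, fm$n_params),
        converged = fm$converged, row.names = NULL)
      if (lof) {
        f35 <- fit_arrhenius(oi, w35)
        f25 <- fit_arrhenius(oi, w25)
        lm_ <- lack_of_fit(oi, fm, eval_window = w35)
        l35 <- lack_of_fit(oi, f35, eval_window = w35)
        l25 <- lack_of_fit(oi, f25, eval_window = w35)
        ss_lof <- ss_lof + c(lm_$ss_lof, l35$ss_lof, l25$ss_lof)
        ss_tot <- ss_tot + lm_$ss_total
      }
    }
    per_fit[[s]] <- do.call(rbind, rows)
    if (lof) {
      pct <- 100 * ss_lof / ss_tot
      lof_rows[[s]] <- data.frame(
        sim = s, pct_mmrt = pct[["mmrt"]], pct_arr_4_35 = pct[["a35"]],
        pct_arr_4_25 = pct[["a25"]],
        ordered = pct[["mmrt"]] < pct[["a35"]] && pct[["a35"]] < pct[["a25"]],
        row.names = NULL)
    }
  }
  out <- list(per_fit = do.call(rbind, per_fit))
  if (lof) out$lof_by_sim <- do.call(rbind, lof_rows)
  out
}

#' Activation-energy window profile on noiseless model data
#'
#' Generates noiseless rates from each combination's true MMRT parameters
#' and refits Arrhenius over each window, exposing the dependence of the
#' fitted activation energy on the temperature range: for concave-down
#' (negative heat capacity) truth, EA strictly decreases as the window
#' widens.
#'
#' @param design A `tt_design`; its noise SD is forced to zero.
#' @param windows Arrhenius windows.
#' @return A data frame: `isolate`, `enzyme`, one `E_A` column per window
#'   label, and `strictly_decreasing`.
#' @export
ea_window_study <- function(design = default_design(seed = 1),
                            windows = default_windows()) {
  design$noise_sd_ln <- 0
  obs <- generate_rates(design, keep_below_detection = FALSE)
  key <- paste(obs$isolate, obs$enzyme, sep = ":")
  labels <- vapply(windows, window_label, character(1))
  rows <- lapply(unique(key), function(k) {
    oi <- obs[key == k, , drop = FALSE]
    ea <- vapply(windows, function(w) fit_arrhenius(oi, w)$params$E_A,
                 numeric(1))
    out <- data.frame(isolate = oi$isolate[1], enzyme = oi$enzyme[1],
                      row.names = NULL)
    for (j in seq_along(labels)) out[[paste0("E_A_", labels[j])]] <- ea[j]
    out$strictly_decreasing <- all(diff(ea[order(vapply(windows, function(w)
      w$high_c - w$low_c, numeric(1)))]) < 0)
    out
  })
  do.call(rbind, rows)
}
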