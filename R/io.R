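#' Read a tidy rate table
#'
#' Reads a delimited text file (CSV or TSV, autodetected from the
#' extension) with header columns `isolate`, `enzyme`, `temperature_c`,
#' `replicate`, `rate`, validating types and uniqueness of
#' (isolate, enzyme, temperature, replicate) with row numbers in every
#' error message.  Temperatures are Celsius; Kelvin never appears in
#' files.
#'
#' @param path Path to a `.csv` or `.tsv`/`.txt` file.
#' @return A validated observation data frame.
#' @export
read_rate_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  required <- c("isolate", "enzyme", "temperature_c", "replicate", "rate")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("parse error: missing column(s) ", paste(missing, collapse = ", "),
         " in ", path, call. = FALSE)
  }
  for (col in c("temperature_c", "rate")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad) > 0) {
      stop("parse error: non-numeric ", col, " at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
    raw[[col]] <- v
  }
  key <- paste(raw$isolate, raw$enzyme, raw$temperature_c, raw$replicate)
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    stop("parse error: duplicate (isolate, enzyme, temperature, replicate) ",
         "at row(s) ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  validate_observations(raw)
}

#' Write a tidy rate table
#'
#' @param obs Observation data frame.
#' @param path Output path (`.csv` or `.tsv`).
#' @export
write_rate_table <- function(obs, path) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(validate_observations(obs), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' @param input Path to a rate table, or `NULL` to simulate.
#' @param simulate Simulate data from [default_design()] when no input is
#'   given.
#' @param T0 MMRT reference temperature, K.
#' @param windows Arrhenius windows (see [default_windows()]).
#' @param mc_draws Monte Carlo draws for trait standard errors.
#' @param seed Integer seed; required whenever any stage is stochastic
#'   (simulation or Monte Carlo).
#' @param alpha Significance level for pairwise flags.
#' @param out_dir Output directory for [write_results()], or `NULL` to
#'   skip writing.
#' @param eval_temps_c Temperatures for the percent-error / common
#'   lack-of-fit evaluation.
#' @param detection_limit Rates at or below this value (nmol L^-1 h^-1)
#'   are treated as below detection and excluded from fitting.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, simulate = is.null(input),
                            T0 = 298.15, windows = default_windows(),
                            mc_draws = 1000, seed = NULL, alpha = 0.05,
                            out_dir = NULL, eval_temps_c = c(4, 11, 25, 35),
                            detection_limit = 0) {
  if ((simulate || mc_draws > 0) && is.null(seed)) {
    stop("configuration error: a seed is required for stochastic stages",
         call. = FALSE)
  }
  if (length(windows) == 0) stop("windows must be nonempty", call. = FALSE)
  structure(list(input = input, simulate = simulate, T0 = T0,
                 windows = windows, mc_draws = mc_draws, seed = seed,
                 alpha = alpha, out_dir = out_dir,
                 eval_temps_c = eval_temps_c,
                 detection_limit = detection_limit),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full temperature-sensitivity pipeline
#'
#' Stages: (1) load or simulate rate data; (2) per-combination fits (MMRT
#' on the full window, Arrhenius on every window); (3) trait extraction
#' with Monte Carlo standard errors; (4) model comparison, lack-of-fit
#' and percent error; (5) trait statistics (variance partitioning,
#' Holm-adjusted pairwise Z-tests with compact letters, correlations,
#' window-to-window relationship changes); (6) optional [write_results()].
#' Non-positive and below-detection rates never enter the ln-scale fits;
#' combinations whose observations are all below detection are skipped,
#' so an unbalanced trait matrix is the normal case, not an error.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of class `tt_results` with elements
#'   `observations`, `fits`, `traits`, `comparison`, `ea_profile`, `lof`,
#'   `percent_error`, `pairwise`, `letters`, `anova`, `correlations`,
#'   `relationship_changes`, `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  obs <- stage("load", {
    if (!is.null(config$input)) {
      read_rate_table(config$input)
    } else if (config$simulate) {
      generate_rates(default_design(config$seed), keep_below_detection = TRUE)
    } else {
      stop("no input path and simulation disabled")
    }
  })
  if (!"below_detection" %in% names(obs)) obs$below_detection <- FALSE

  widths <- vapply(config$windows, function(w) w$high_c - w$low_c, numeric(1))
  full <- config$windows[[which.max(widths)]]
  usable <- obs[!obs$below_detection &
                  obs$rate > max(0, config$detection_limit), , drop = FALSE]
  keys <- unique(paste(usable$isolate, usable$enzyme, sep = ":"))
  obs_key <- paste(usable$isolate, usable$enzyme, sep = ":")

  comparisons <- stage("fit", {
    out <- list()
    for (k in keys) {
      oi <- usable[obs_key == k, , drop = FALSE]
      out[[k]] <- compare_models(oi, windows = config$windows, T0 = config$T0)
      if (!out[[k]]$fits$MMRT$converged) {
        message("non-converged MMRT fit for ", k)
      }
    }
    out
  })

  traits <- stage("traits", {
    rows <- list()
    for (i in seq_along(keys)) {
      fm <- comparisons[[keys[i]]]$fits$MMRT
      est <- mc_trait_se(fm, n_draws = config$mc_draws,
                         seed = config$seed + i)
      rows[[i]] <- data.frame(
        isolate = fm$combination$isolate, enzyme = fm$combination$enzyme,
        dCp = fm$params$dCp, dCp_se = sqrt(fm$covariance["dCp", "dCp"]),
        dH = fm$params$dH, dS = fm$params$dS,
        topt_c = est$topt$temperature_C, topt_se = est$topt_se,
        tsmax_c = est$tsmax$temperature_C, tsmax_se = est$tsmax_se,
        n_failed_draws = est$n_failed_draws, row.names = NULL)
    }
    do.call(rbind, rows)
  })

  comparison <- do.call(rbind, lapply(comparisons, `[[`, "comparison"))
  rownames(comparison) <- NULL
  ea_profile <- do.call(rbind, lapply(comparisons, `[[`, "ea_profile"))
  rownames(ea_profile) <- NULL

  lof <- stage("lack_of_fit", {
    rows <- list()
    for (k in keys) {
      for (m in names(comparisons[[k]]$lof)) {
        l <- comparisons[[k]]$lof[[m]]
        rows[[paste(k, m)]] <- data.frame(
          isolate = comparisons[[k]]$comparison$isolate,
          enzyme = comparisons[[k]]$comparison$enzyme, model = m,
          ss_pure = l$ss_pure, ss_lof = l$ss_lof, ss_total = l$ss_total,
          f_stat = l$f_stat, p_value = l$p_value,
          pct_lof_of_total = l$pct_lof_of_total, row.names = NULL)
      }
    }
    do.call(rbind, rows)
  })
  rownames(lof) <- NULL

  pct_err <- stage("percent_error", {
    rows <- list()
    for (k in keys) {
      oi <- usable[obs_key == k, , drop = FALSE]
      for (f in comparisons[[k]]$fits) {
        rows[[paste(k, f$model, window_label(f$window))]] <-
          suppressWarnings(percent_error(oi, f, temps_c = config$eval_temps_c))
      }
    }
    do.call(rbind, rows)
  })
  rownames(pct_err) <- NULL

  stats_out <- stage("trait_stats", {
    pw_dcp <- pairwise_z(traits, "dCp", alpha = config$alpha)
    pw_topt <- pairwise_z(traits, "topt_c", se = "topt_se",
                          alpha = config$alpha)
    pw_tsmax <- pairwise_z(traits, "tsmax_c", se = "tsmax_se",
                           alpha = config$alpha)
    pw_ea <- list()
    for (w in config$windows) {
      lab <- window_label(w)
      sub <- ea_profile[ea_profile$window == lab, , drop = FALSE]
      sub <- data.frame(isolate = sub$isolate, enzyme = sub$enzyme,
                        E_A = sub$E_A, E_A_se = sub$E_A_se)
      pw_ea[[lab]] <- pairwise_z(sub, "E_A", alpha = config$alpha)
    }
    anova_list <- list(
      dCp = anova_partition(traits, "dCp"),
      topt_c = anova_partition(traits, "topt_c"),
      tsmax_c = anova_partition(traits, "tsmax_c"))
    ea_long <- ea_profile
    anova_list$E_A <- anova_partition(ea_long, "E_A",
                                      factors = c("window", "isolate",
                                                  "enzyme"))
    correlations <- data.frame(
      x = c("topt_c", "dCp", "dCp"), y = c("tsmax_c", "topt_c", "tsmax_c"),
      r_squared = c(trait_correlation(traits, "topt_c", "tsmax_c"),
                    trait_correlation(traits, "dCp", "topt_c"),
                    trait_correlation(traits, "dCp", "tsmax_c")))
    labs <- vapply(config$windows, window_label, character(1))
    rel <- list()
    if (length(labs) >= 2) {
      for (i in seq_len(length(labs) - 1)) {
        pair <- paste(labs[i], "vs", labs[i + 1])
        rc <- relationship_change(pw_ea[[labs[i]]], pw_ea[[labs[i + 1]]])
        rel[[pair]] <- data.frame(window_pair = pair, n_pairs = rc$n_pairs,
                                  n_changed = rc$n_changed,
                                  fraction_changed = rc$fraction_changed,
                                  row.names = NULL)
      }
    }
    list(pairwise = list(dCp = pw_dcp, topt_c = pw_topt, tsmax_c = pw_tsmax,
                         E_A = pw_ea),
         letters = compact_letter_display(pw_dcp),
         anova = anova_list,
         correlations = correlations,
         relationship_changes = do.call(rbind, rel))
  })

  results <- structure(
    list(observations = obs,
         fits = unlist(lapply(comparisons, `[[`, "fits"), recursive = FALSE),
         traits = traits, comparison = comparison, ea_profile = ea_profile,
         lof = lof, percent_error = pct_err,
         pairwise = stats_out$pairwise, letters = stats_out$letters,
         anova = stats_out$anova, correlations = stats_out$correlations,
         relationship_changes = stats_out$relationship_changes,
         config = config),
    class = "tt_results")
  if (!is.null(config$out_dir)) {
    stage("write", write_results(results, config$out_dir))
  }
  invisible(results)
}

#' Write pipeline results as delimited tables plus a run manifest
#'
#' Emits `fits.csv`, `traits.csv`, `comparison.csv`, `lof.csv`,
#' `percent_error.csv`, `pairwise.csv` (all families, with Holm-adjusted
#' p-values), `letters.csv`, `anova.csv`, `correlations.csv`,
#' `relationship_changes.csv`, and a JSON `manifest.json` recording the
#' configuration, seed and package version.  No timestamps are written,
#' so two runs with identical configuration and seed produce byte-equal
#' files.  Missing result components yield header-only tables.
#'
#' @param results A `tt_results` list from [run_pipeline()] (possibly
#'   partial).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir,
                                 call. = FALSE)
  paths <- character()
  empty <- function(...) {
    cols <- c(...)
    as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols))
  }
  wr <- function(df, name, fallback_cols = c("isolate", "enzyme")) {
    if (is.null(df)) df <- empty(fallback_cols)
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }

  fits_df <- if (length(results$fits) > 0) {
    do.call(rbind, lapply(results$fits, function(f) {
      co <- f$coef
      data.frame(isolate = f$combination$isolate,
                 enzyme = f$combination$enzyme, model = f$model,
                 window = window_label(f$window),
                 coef = names(co), estimate = unname(co),
                 se = sqrt(diag(f$covariance)),
                 rss = f$rss, tss = f$tss, n_obs = f$n_obs,
                 aicc = aicc(f$rss, f$n_obs, f$n_params),
                 adj_r2 = adjusted_r2(f$rss, f$tss, f$n_obs, f$n_params),
                 converged = f$converged, row.names = NULL)
    }))
  } else {
    data.frame(isolate = character(), enzyme = character(),
               model = character(), window = character(), coef = character(),
               estimate = numeric(), se = numeric(), rss = numeric(),
               tss = numeric(), n_obs = integer(), aicc = numeric(),
               adj_r2 = numeric(), converged = logical())
  }
  wr(fits_df, "fits.csv")
  empty_traits <- data.frame(isolate = character(), enzyme = character(),
                             dCp = numeric(), dCp_se = numeric(),
                             dH = numeric(), dS = numeric(),
                             topt_c = numeric(), topt_se = numeric(),
                             tsmax_c = numeric(), tsmax_se = numeric(),
                             n_failed_draws = integer())
  wr(if (is.null(results$traits)) empty_traits else results$traits,
     "traits.csv")
  wr(results$comparison, "comparison.csv", c("isolate", "enzyme", "aicc_mmrt", "aicc_arr", "adj_r2_mmrt", "adj_r2_arr", "delta_aicc", "preferred"))
  wr(results$lof, "lof.csv", c("isolate", "enzyme", "model", "ss_pure", "ss_lof", "ss_total", "f_stat", "p_value", "pct_lof_of_total"))
  wr(results$percent_error, "percent_error.csv", c("isolate", "enzyme", "model", "window", "temperature_c", "replicate", "observed", "predicted", "percent_error"))

  pw <- results$pairwise
  pw_df <- NULL
  if (!is.null(pw)) {
    flat <- list()
    for (nm in names(pw)) {
      el <- pw[[nm]]
      if (inherits(el, "data.frame")) {
        el$response <- nm
        flat[[nm]] <- el
      } else {
        for (w in names(el)) {
          e2 <- el[[w]]
          e2$response <- paste(nm, w)
          flat[[paste(nm, w)]] <- e2
        }
      }
    }
    pw_df <- do.call(rbind, lapply(flat, as.data.frame))
    rownames(pw_df) <- NULL
  }
  wr(pw_df, "pairwise.csv", c("family", "member1", "member2", "estimate1", "estimate2", "diff", "se_diff", "z", "p_raw", "p_holm", "significant", "response"))
  wr(results$letters, "letters.csv", c("family", "member", "estimate", "letters"))

  an <- results$anova
  an_df <- NULL
  if (!is.null(an)) {
    an_df <- do.call(rbind, lapply(names(an), function(nm) {
      t <- an[[nm]]$table
      t$response <- nm
      t$order_sensitive <- an[[nm]]$order_sensitive
      t
    }))
  }
  wr(an_df, "anova.csv", c("factor", "ss_order1", "ss_order2", "ss_mean", "pct_explained_order1", "pct_explained_order2", "pct_explained_mean", "pct_total_order1", "pct_total_order2", "response", "order_sensitive"))
  wr(results$correlations, "correlations.csv", c("x", "y", "r_squared"))
  wr(results$relationship_changes, "relationship_changes.csv", c("window_pair", "n_pairs", "n_changed", "fraction_changed"))

  cfg <- results$config
  manifest <- list(
    package = "thermotrait",
    version = as.character(utils::packageVersion("thermotrait")),
    seed = cfg$seed, T0 = cfg$T0,
    windows = vapply(cfg$windows, window_label, character(1)),
    mc_draws = cfg$mc_draws, alpha = cfg$alpha,
    simulate = cfg$simulate,
    input = if (is.null(cfg$input)) NA else cfg$input,
    n_observations = if (is.null(results$observations)) 0L
                     else nrow(results$observations))
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(paths, mp))
}
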