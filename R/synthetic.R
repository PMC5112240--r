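#' Published temperature-sensitivity traits for 19 isolate-enzyme pairs
#'
#' The packaged table of mean temperature optima (Topt) and points of
#' maximum temperature sensitivity (TSmax), with standard errors, for the
#' 19 working isolate-enzyme combinations of a seven-isolate,
#' three-enzyme soil assay (beta-glucosidase BG, leucine aminopeptidase
#' LAP, phosphatase PHOS).  Values are stored exactly as published,
#' including their mixed decimal precision; the two below-detection
#' combinations (Bacillus x BG, Comamonas x PHOS) are absent.
#'
#' @return A data frame with columns `isolate`, `enzyme`, `topt_c`,
#'   `topt_se`, `tsmax_c`, `tsmax_se` (all temperatures in Celsius).
#' @examples
#' nrow(table1_fixture())
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "table1_traits.csv", package = "thermotrait",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' MMRT parameters with a prescribed optimum and sensitivity point
#'
#' Inverts the trait map: given a temperature optimum and a point of
#' maximum temperature sensitivity, finds the unique
#' \eqn{(\Delta H^\ddagger, \Delta C_p^\ddagger)} pair producing them.
#' Topt fixes \eqn{\Delta H^\ddagger} for any \eqn{\Delta C_p^\ddagger}
#' via the closed form; TSmax then pins \eqn{\Delta C_p^\ddagger} by 1-D
#' root finding.  `dS` is chosen so the log rate at `T0` equals
#' `ln_rate_at_T0`, setting the activity scale.
#'
#' @param topt_c,tsmax_c Target traits, Celsius (`tsmax_c < topt_c`).
#' @param ln_rate_at_T0 Log activity at the reference temperature
#'   (rates in nmol L^-1 h^-1).
#' @param T0 Reference temperature, K.
#' @param dcp_range Search interval for `dCp`, J mol^-1 K^-1.
#' @param const Physical constants.
#' @return An [mmrt_params()] object.
#' @export
mmrt_params_from_traits <- function(topt_c, tsmax_c, ln_rate_at_T0 = 4.5,
                                    T0 = 298.15, dcp_range = c(-30000, -1200),
                                    const = phys_constants()) {
  if (tsmax_c >= topt_c) stop("tsmax_c must be below topt_c", call. = FALSE)
  topt_k <- celsius_to_kelvin(topt_c)
  tsmax_k <- celsius_to_kelvin(tsmax_c)
  dh_for <- function(dcp) dcp * T0 - topt_k * (const$R + dcp)
  gap <- function(dcp) {
    p <- mmrt_params(dh_for(dcp), 0, dcp, T0)
    tsmax(p, const, bracket_low = 150)$temperature_K - tsmax_k
  }
  dcp <- stats::uniroot(gap, dcp_range, tol = 1e-8)$root
  dh <- dh_for(dcp)
  # offset dS so that ln k(T0) = ln_rate_at_T0 (dCp terms vanish at T0)
  ds <- const$R * (ln_rate_at_T0 - log(const$kB_over_h * T0)) + dh / T0
  mmrt_params(dh, ds, dcp, T0)
}

#' Default assay design for the synthetic generator
#'
#' The layout of the emulated study: 7 isolates x 3 enzymes x 6
#' temperatures (4, 11, 25, 35, 45, 60 C) x 8 replicates, with log-scale
#' Gaussian noise of SD 0.2 and two combinations (Bacillus x BG,
#' Comamonas x PHOS) below detection.  True MMRT parameters for the 19
#' working combinations are derived by inverting the published
#' (Topt, TSmax) pairs of [table1_fixture()], so the generator's true
#' traits are the published ones; the seed drives the per-combination
#' activity scale (a log-rate level at 25 C drawn uniformly between about
#' 30 and 250 nmol L^-1 h^-1) and, downstream, the measurement noise.
#'
#' @param seed Integer seed (stored in the design and reused by
#'   [generate_rates()]).
#' @param noise_sd_ln SD of additive Gaussian noise on the log rate.
#' @param n_replicates Replicates per temperature.
#' @param detection_limit Rates below this (nmol L^-1 h^-1) count as below
#'   detection.
#' @return A list of class `tt_design` with fields `isolates`, `enzymes`,
#'   `temperatures_c`, `n_replicates`, `noise_sd_ln`, `true_params`
#'   (named list keyed `isolate:enzyme`), `true_traits` (data frame),
#'   `below_detection` (data frame of excluded combinations),
#'   `detection_limit`, `seed`.
#' @export
default_design <- function(seed, noise_sd_ln = 0.2, n_replicates = 8,
                           detection_limit = 0.5) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  fx <- table1_fixture()
  isolates <- c("Acinetobacter", "Bacillus", "Citrobacter", "Comamonas",
                "Enterobacter", "Flaviobacterium", "Pseudomonas")
  enzymes <- c("BG", "LAP", "PHOS")
  set.seed(seed)
  ln_levels <- stats::runif(nrow(fx), log(30), log(250))
  true_params <- vector("list", nrow(fx))
  names(true_params) <- paste(fx$isolate, fx$enzyme, sep = ":")
  for (i in seq_len(nrow(fx))) {
    true_params[[i]] <- mmrt_params_from_traits(fx$topt_c[i], fx$tsmax_c[i],
                                                ln_rate_at_T0 = ln_levels[i])
  }
  true_traits <- data.frame(
    isolate = fx$isolate, enzyme = fx$enzyme,
    topt_c = fx$topt_c, tsmax_c = fx$tsmax_c,
    dH = vapply(true_params, `[[`, numeric(1), "dH"),
    dS = vapply(true_params, `[[`, numeric(1), "dS"),
    dCp = vapply(true_params, `[[`, numeric(1), "dCp"),
    row.names = NULL)
  structure(list(
    isolates = isolates, enzymes = enzymes,
    temperatures_c = c(4, 11, 25, 35, 45, 60),
    n_replicates = n_replicates, noise_sd_ln = noise_sd_ln,
    true_params = true_params, true_traits = true_traits,
    below_detection = data.frame(isolate = c("Bacillus", "Comamonas"),
                                 enzyme = c("BG", "PHOS")),
    detection_limit = detection_limit, seed = seed),
    class = "tt_design")
}

#' @export
print.tt_design <- function(x, ...) {
  cat(sprintf("Assay design: %d isolates x %d enzymes x %d temperatures x %d replicates\n",
              length(x$isolates), length(x$enzymes), length(x$temperatures_c),
              x$n_replicates))
  cat(sprintf("  %d combinations below detection; noise sd(ln rate) = %g; seed = %d\n",
              nrow(x$below_detection), x$noise_sd_ln, x$seed))
  invisible(x)
}

#' Simulate replicated assay rates from a design
#'
#' For every retained combination, temperature and replicate the rate is
#' \eqn{\exp(\ln k_{MMRT}(true) + \epsilon)} with
#' \eqn{\epsilon \sim N(0, \sigma_{\ln})}: noise is Gaussian on the log
#' rate (log-normal rates), matching the ln-scale fits and keeping rates
#' strictly positive.  Below-detection combinations emit uniform rates
#' under the detection limit and carry `below_detection = TRUE`.
#' Reproducible from `design$seed`.
#'
#' @param design A [default_design()]-style `tt_design`.
#' @param keep_below_detection Keep the flagged rows (default `TRUE`);
#'   downstream fits filter them via the flag or the detection limit.
#' @return A data frame of observations: `isolate`, `enzyme`,
#'   `temperature_c`, `replicate`, `rate`, `below_detection`.
#' @export
generate_rates <- function(design, keep_below_detection = TRUE) {
  set.seed(design$seed)
  grid <- expand.grid(replicate = seq_len(design$n_replicates),
                      temperature_c = design$temperatures_c,
                      enzyme = design$enzymes, isolate = design$isolates,
                      stringsAsFactors = FALSE)
  grid <- grid[, c("isolate", "enzyme", "temperature_c", "replicate")]
  key <- paste(grid$isolate, grid$enzyme, sep = ":")
  bd_key <- paste(design$below_detection$isolate,
                  design$below_detection$enzyme, sep = ":")
  grid$below_detection <- key %in% bd_key
  retained_keys <- setdiff(unique(key), bd_key)
  missing_pars <- setdiff(retained_keys, names(design$true_params))
  if (length(missing_pars) > 0) {
    stop("no true parameters for combination(s): ",
         paste(missing_pars, collapse = ", "), call. = FALSE)
  }
  rate <- numeric(nrow(grid))
  # fixed row order + one seeded stream => byte-reproducible output
  for (k in unique(key)) {
    rows <- which(key == k)
    if (k %in% bd_key) {
      rate[rows] <- design$detection_limit *
        stats::runif(length(rows), 0.05, 0.9)
    } else {
      mu <- mmrt_ln_rate(design$true_params[[k]],
                         celsius_to_kelvin(grid$temperature_c[rows]))
      rate[rows] <- exp(mu + stats::rnorm(length(rows), 0, design$noise_sd_ln))
    }
  }
  grid$rate <- rate
  if (!keep_below_detection) {
    grid <- grid[!grid$below_detection, , drop = FALSE]
    rownames(grid) <- NULL
  }
  grid
}

#' Fluorometric standard curve
#'
#' Linear calibration of fluorescence against fluorophore concentration,
#' as read from MUB (for BG/PHOS) or MUC (for LAP) standard wells.
#'
#' @param standard `"MUB"` or `"MUC"`.
#' @param slope Fluorescence units per uM (> 0).
#' @param intercept Background fluorescence.
#' @param concentrations Standard concentrations, uM (default spanning
#'   2.5-100 uM).
#' @return A `standard_curve` list.
#' @export
standard_curve <- function(standard = c("MUB", "MUC"), slope = 120,
                           intercept = 50,
                           concentrations = c(2.5, 5, 10, 25, 50, 100)) {
  standard <- match.arg(standard)
  if (slope <= 0) stop("standard-curve slope must be positive", call. = FALSE)
  structure(list(standard = standard, slope = slope, intercept = intercept,
                 concentrations = concentrations), class = "standard_curve")
}

#' Fit a standard curve from its calibration wells
#'
#' Ordinary least squares of fluorescence on concentration.
#'
#' @param concentration Standard concentrations, uM.
#' @param fluorescence Measured fluorescence at those concentrations.
#' @param standard Label passed through to [standard_curve()].
#' @return A `standard_curve` with the fitted slope and intercept.
#' @export
fit_standard_curve <- function(concentration, fluorescence,
                               standard = "MUB") {
  fit <- stats::lm(fluorescence ~ concentration)
  standard_curve(standard = standard,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 concentrations = sort(unique(concentration)))
}

# nmol L^-1 h^-1 * h -> nmol L^-1; x 1e-3 -> umol L^-1 = uM.  The assay's
# well-volume arithmetic is collapsed into this single configurable factor.
DEFAULT_UM_PER_NMOL_L <- 1e-3

#' Emulate raw plate-reader records from rate observations
#'
#' Inverse of [calibrate_fluorescence()]: each rate implies a fluorophore
#' concentration (rate x incubation time x volume conversion) read through
#' the standard curve as `intercept + slope x concentration`.
#'
#' @param obs Rate observations (see [generate_rates()]).
#' @param curve A [standard_curve()].
#' @param incubation_h Incubation time in hours (> 0), scalar or per row.
#' @param conversion uM implied per (nmol L^-1 h^-1 x h); collapses the
#'   assay volume convention into one factor.
#' @return A data frame of plate records: `well`, `isolate`, `enzyme`,
#'   `temperature_c`, `replicate`, `fluorescence`, `incubation_h`.
#' @export
generate_fluorescence <- function(obs, curve = standard_curve(),
                                  incubation_h = 2,
                                  conversion = DEFAULT_UM_PER_NMOL_L) {
  obs <- validate_observations(obs)
  if (any(incubation_h <= 0)) stop("incubation time must be positive", call. = FALSE)
  conc <- obs$rate * incubation_h * conversion
  data.frame(well = seq_len(nrow(obs)),
             isolate = obs$isolate, enzyme = obs$enzyme,
             temperature_c = obs$temperature_c, replicate = obs$replicate,
             fluorescence = curve$intercept + curve$slope * conc,
             incubation_h = incubation_h, row.names = NULL)
}

#' Calibrate plate fluorescence into activity rates
#'
#' Converts fluorescence to fluorophore concentration through the standard
#' curve, `(fluorescence - intercept) / slope`, then to activity in
#' nmol L^-1 h^-1 by dividing by incubation time and the volume conversion
#' factor.  Negative implied concentrations are clamped to rate 0 and
#' flagged below detection.
#'
#' @param plates Plate records from [generate_fluorescence()] (columns
#'   `isolate`, `enzyme`, `temperature_c`, `replicate`, `fluorescence`,
#'   `incubation_h`).
#' @param curve A [standard_curve()]; its slope must be positive.
#' @param conversion See [generate_fluorescence()].
#' @return Rate observations with a `below_detection` flag.
#' @export
calibrate_fluorescence <- function(plates, curve,
                                   conversion = DEFAULT_UM_PER_NMOL_L) {
  if (curve$slope <= 0) stop("calibration error: slope must be positive", call. = FALSE)
  conc <- (plates$fluorescence - curve$intercept) / curve$slope
  rate <- conc / (plates$incubation_h * conversion)
  below <- rate <= 0
  rate[below] <- 0
  data.frame(isolate = plates$isolate, enzyme = plates$enzyme,
             temperature_c = plates$temperature_c,
             replicate = plates$replicate, rate = rate,
             below_detection = below, row.names = NULL)
}
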