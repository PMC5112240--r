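test_that("Arrhenius fit recovers noiseless generating parameters exactly", {
  p <- arrhenius_params(ln_A = 10, E_A = 60000)
  obs <- make_arrhenius_obs(p, n_rep = 1)
  fit <- fit_arrhenius(obs)
  expect_equal(fit$params$ln_A, 10, tolerance = 1e-8)
  expect_equal(fit$params$E_A, 60000, tolerance = 1e-8)
  expect_lt(fit$rss, 1e-16)
  expect_true(fit$converged)
})

test_that("window filtering is inclusive and a fit never uses outside observations", {
  obs <- make_mmrt_obs(ref_mmrt(), n_rep = 8)
  fit <- fit_arrhenius(obs, temperature_window(4, 25))
  expect_equal(fit$n_obs, 3 * 8)  # temps 4, 11, 25 only
  fit2 <- fit_arrhenius(obs, temperature_window(4, 60))
  expect_equal(fit2$n_obs, 6 * 8)
  expect_error(fit_arrhenius(obs[obs$temperature_c == 4, ]),
               "window must have low_c < high_c")
  expect_error(fit_arrhenius(obs, temperature_window(3, 5)),
               "distinct temperatures")
})

test_that("fitted activation energy is smaller on wider windows of curved data", {
  obs <- make_mmrt_obs(ref_mmrt(), n_rep = 2)
  ea <- vapply(list(temperature_window(4, 25), temperature_window(4, 35),
                    temperature_window(4, 60)),
               function(w) fit_arrhenius(obs, w)$params$E_A, numeric(1))
  expect_true(all(diff(ea) < 0))
})

test_that("nonpositive rates are dropped with a warning; all-dropped errors", {
  obs <- make_arrhenius_obs(arrhenius_params(5, 40000), n_rep = 2)
  obs$rate[c(3, 9)] <- 0
  expect_warning(fit <- fit_arrhenius(obs), "2 nonpositive")
  expect_equal(fit$n_obs, nrow(obs) - 2)
  obs$rate <- 0
  expect_error(suppressWarnings(fit_arrhenius(obs)), "no positive-rate")
})

test_that("MMRT starting values are finite and handle degenerate shapes", {
  obs <- make_arrhenius_obs(arrhenius_params(8, 55000), n_rep = 2)
  init <- init_mmrt(obs)
  expect_true(all(is.finite(unlist(init))))
  pred <- mmrt_ln_rate(init, celsius_to_kelvin(unique(obs$temperature_c)))
  expect_true(all(is.finite(pred)))
  # monotone decreasing data: rising limb collapses to one temperature
  obs_dec <- make_arrhenius_obs(arrhenius_params(8, -30000), n_rep = 2)
  init_dec <- suppressWarnings(init_mmrt(obs_dec))
  expect_true(all(is.finite(unlist(init_dec))))
  expect_error(init_mmrt(obs[obs$temperature_c %in% c(4, 11, 25), ]),
               "4 distinct temperatures")
})

test_that("MMRT Gauss-Newton recovers noiseless parameters and agrees with a linear-basis oracle", {
  truth <- ref_mmrt()
  obs <- make_mmrt_obs(truth, n_rep = 8)
  fit <- fit_mmrt(obs)
  expect_true(fit$converged)
  expect_equal(fit$params$dH, truth$dH, tolerance = 1e-4)
  expect_equal(fit$params$dCp, truth$dCp, tolerance = 1e-4)
  expect_lt(abs(fit$params$dS - truth$dS), 1e-3)

  # independent route: the MMRT curve is linear in (dH, dS, dCp), so an
  # lm() on the transformed basis must give identical coefficients and
  # covariance on noisy data
  obs_n <- make_mmrt_obs(truth, n_rep = 8, sd_ln = 0.2, seed = 5)
  fit_n <- fit_mmrt(obs_n)
  const <- phys_constants()
  tk <- celsius_to_kelvin(obs_n$temperature_c)
  y <- log(obs_n$rate) - log(const$kB_over_h * tk)
  x1 <- -1 / (const$R * tk)
  x2 <- rep(1 / const$R, length(tk))
  x3 <- -(tk - truth$T0) / (const$R * tk) + (log(tk) - log(truth$T0)) / const$R
  ref <- stats::lm(y ~ 0 + x1 + x2 + x3)
  expect_equal(unname(fit_n$coef), unname(coef(ref)), tolerance = 1e-7)
  expect_equal(unname(diag(fit_n$covariance)), unname(diag(vcov(ref))),
               tolerance = 1e-6)
})

test_that("MMRT fit of zero-curvature data returns dCp near zero", {
  truth <- mmrt_params(50000, 10, 0)
  obs <- make_mmrt_obs(truth, n_rep = 4)
  fit <- fit_mmrt(obs)
  expect_lt(abs(fit$params$dCp), 1e-6)
})

test_that("doubling replication roughly halves coefficient variances", {
  truth <- ref_mmrt()
  v8 <- fit_mmrt(make_mmrt_obs(truth, n_rep = 8, sd_ln = 0.2,
                               seed = 1))$covariance["dCp", "dCp"]
  v32 <- fit_mmrt(make_mmrt_obs(truth, n_rep = 32, sd_ln = 0.2,
                                seed = 2))$covariance["dCp", "dCp"]
  expect_gt(v8 / v32, 2)   # expect ~4 with sampling slack
  expect_lt(v8 / v32, 8)
})

test_that("Monte Carlo trait errors are deterministic, zero under zero covariance, and scale with replication", {
  obs <- make_mmrt_obs(ref_mmrt(), n_rep = 8, sd_ln = 0.2, seed = 3)
  fit <- fit_mmrt(obs)
  a <- mc_trait_se(fit, n_draws = 500, seed = 21)
  b <- mc_trait_se(fit, n_draws = 500, seed = 21)
  expect_identical(a, b)
  expect_gt(a$topt_se, 0)
  expect_lt(a$tsmax$temperature_K, a$topt$temperature_K)

  fit0 <- fit
  fit0$covariance[] <- 0
  z <- mc_trait_se(fit0, n_draws = 100, seed = 1)
  expect_equal(z$topt_se, 0)
  expect_equal(z$tsmax_se, 0)
  expect_equal(z$n_failed_draws, 0)

  # SEs shrink roughly as 1/sqrt(replicates): 8 vs 32 reps -> ratio ~2
  fit32 <- fit_mmrt(make_mmrt_obs(ref_mmrt(), n_rep = 32, sd_ln = 0.2,
                                  seed = 4))
  se8 <- mc_trait_se(fit, n_draws = 1000, seed = 5)$topt_se
  se32 <- mc_trait_se(fit32, n_draws = 1000, seed = 5)$topt_se
  expect_gt(se8 / se32, 1.3)
  expect_lt(se8 / se32, 3.5)
  expect_error(mc_trait_se(fit), "seed is required")
})

test_that("point estimates come from the fit, not the draw mean", {
  obs <- make_mmrt_obs(ref_mmrt(), n_rep = 8, sd_ln = 0.2, seed = 8)
  fit <- fit_mmrt(obs)
  est <- mc_trait_se(fit, n_draws = 50, seed = 2)
  expect_equal(est$topt$temperature_K, topt(fit$params)$temperature_K)
  expect_equal(est$tsmax$temperature_K, tsmax(fit$params)$temperature_K,
               tolerance = 1e-9)
})
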