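test_that("the default design reproduces the factorial layout and exclusions", {
  d <- default_design(seed = 1)
  expect_equal(length(d$isolates) * length(d$enzymes), 21)
  expect_equal(length(d$true_params), 19)
  expect_equal(nrow(d$below_detection), 2)
  expect_equal(d$temperatures_c, c(4, 11, 25, 35, 45, 60))
  expect_equal(d$n_replicates, 8)
  # seed determinism
  expect_identical(default_design(seed = 7), default_design(seed = 7))
  expect_false(identical(default_design(seed = 7)$true_params,
                         default_design(seed = 8)$true_params))
})

test_that("true design parameters reproduce the published traits", {
  d <- default_design(seed = 3)
  fx <- table1_fixture()
  for (i in seq_len(nrow(fx))) {
    p <- d$true_params[[paste(fx$isolate[i], fx$enzyme[i], sep = ":")]]
    expect_equal(topt(p)$temperature_C, fx$topt_c[i], tolerance = 1e-5)
    expect_equal(tsmax(p, bracket_low = 160)$temperature_C, fx$tsmax_c[i],
                 tolerance = 1e-3)
  }
})

test_that("generated rates have the declared shape, determinism, and noise model", {
  d <- default_design(seed = 5)
  obs <- generate_rates(d)
  expect_equal(nrow(obs), 21 * 6 * 8)
  expect_equal(sum(!obs$below_detection), 19 * 6 * 8)
  expect_identical(obs, generate_rates(default_design(seed = 5)))
  # detection-limit filter removes exactly the flagged combinations
  bd <- obs[obs$below_detection, ]
  expect_equal(sort(unique(paste(bd$isolate, bd$enzyme))),
               c("Bacillus BG", "Comamonas PHOS"))
  expect_true(all(bd$rate < d$detection_limit))
  retained <- generate_rates(d, keep_below_detection = FALSE)
  expect_equal(nrow(retained), 912)

  # zero noise: ln rates exactly on the true curves
  d0 <- default_design(seed = 5)
  d0$noise_sd_ln <- 0
  o0 <- generate_rates(d0, keep_below_detection = FALSE)
  k <- "Citrobacter:LAP"
  oi <- o0[paste(o0$isolate, o0$enzyme, sep = ":") == k, ]
  expect_equal(log(oi$rate),
               mmrt_ln_rate(d0$true_params[[k]],
                            celsius_to_kelvin(oi$temperature_c)),
               tolerance = 1e-12)
})

test_that("the full noiseless pipeline round-trips every combination's traits", {
  d <- default_design(seed = 11)
  d$noise_sd_ln <- 0
  obs <- generate_rates(d, keep_below_detection = FALSE)
  key <- paste(obs$isolate, obs$enzyme, sep = ":")
  for (k in names(d$true_params)) {
    fit <- fit_mmrt(obs[key == k, , drop = FALSE])
    expect_lt(abs(topt(fit$params)$temperature_K -
                    topt(d$true_params[[k]])$temperature_K), 0.01)
  }
})

test_that("the published-trait fixture carries the 19 printed rows", {
  fx <- table1_fixture()
  expect_equal(nrow(fx), 19)
  expect_equal(fx$topt_c[fx$isolate == "Enterobacter" & fx$enzyme == "BG"],
               33.5)
  expect_equal(min(fx$topt_c), 33.5)
  expect_equal(max(fx$topt_c), 60.7)
  expect_equal(fx$tsmax_c[fx$isolate == "Bacillus" & fx$enzyme == "LAP"],
               40.25)
  expect_equal(range(fx$tsmax_c), c(18.2, 40.25))
  # the two below-detection combinations are absent
  expect_false(any(fx$isolate == "Bacillus" & fx$enzyme == "BG"))
  expect_false(any(fx$isolate == "Comamonas" & fx$enzyme == "PHOS"))
})

test_that("fluorescence generation and calibration are exact inverses", {
  obs <- generate_rates(default_design(seed = 2), keep_below_detection = FALSE)
  obs <- obs[1:100, ]
  curve <- standard_curve("MUB", slope = 150, intercept = 80)
  plates <- generate_fluorescence(obs, curve, incubation_h = 3)
  back <- calibrate_fluorescence(plates, curve)
  expect_equal(back$rate, obs$rate, tolerance = 1e-9)
  expect_false(any(back$below_detection))

  # zero rate -> fluorescence at the intercept, flagged on the way back
  obs0 <- obs[1, ]
  obs0$rate <- 0
  p0 <- generate_fluorescence(obs0, curve, incubation_h = 3)
  expect_equal(p0$fluorescence, curve$intercept)
  expect_true(calibrate_fluorescence(p0, curve)$below_detection)

  # doubling incubation doubles fluorescence above the intercept
  p1 <- generate_fluorescence(obs, curve, incubation_h = 2)
  p2 <- generate_fluorescence(obs, curve, incubation_h = 4)
  expect_equal(p2$fluorescence - curve$intercept,
               2 * (p1$fluorescence - curve$intercept), tolerance = 1e-9)
  expect_error(generate_fluorescence(obs, curve, incubation_h = 0),
               "positive")
})

test_that("a standard curve refit from its own wells is exact", {
  curve <- standard_curve("MUC", slope = 95.5, intercept = 42.1)
  fl <- curve$intercept + curve$slope * curve$concentrations
  refit <- fit_standard_curve(curve$concentrations, fl, standard = "MUC")
  expect_equal(refit$slope, curve$slope, tolerance = 1e-9)
  expect_equal(refit$intercept, curve$intercept, tolerance = 1e-9)
  expect_error(standard_curve("MUB", slope = -1), "positive")
})

test_that("trait inversion produces parameters with the requested traits", {
  p <- mmrt_params_from_traits(40, 24, ln_rate_at_T0 = 4)
  expect_equal(topt(p)$temperature_C, 40, tolerance = 1e-6)
  expect_equal(tsmax(p, bracket_low = 160)$temperature_C, 24, tolerance = 1e-4)
  expect_equal(mmrt_ln_rate(p, 298.15), 4, tolerance = 1e-9)
  expect_error(mmrt_params_from_traits(30, 35), "below topt")
})
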