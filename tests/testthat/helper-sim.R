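# Build replicated observation tables from known model parameters.

assay_temps <- c(4, 11, 25, 35, 45, 60)

make_mmrt_obs <- function(params, temps_c = assay_temps, n_rep = 8,
                          sd_ln = 0, seed = NULL, isolate = "I1",
                          enzyme = "BG") {
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(temperature_c = temps_c, replicate = seq_len(n_rep))
  mu <- mmrt_ln_rate(params, celsius_to_kelvin(grid$temperature_c))
  eps <- if (sd_ln > 0) stats::rnorm(nrow(grid), 0, sd_ln) else 0
  data.frame(isolate = isolate, enzyme = enzyme,
             temperature_c = grid$temperature_c,
             replicate = grid$replicate, rate = exp(mu + eps))
}

make_arrhenius_obs <- function(params, temps_c = assay_temps, n_rep = 8,
                               sd_ln = 0, seed = NULL, isolate = "I1",
                               enzyme = "BG") {
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(temperature_c = temps_c, replicate = seq_len(n_rep))
  mu <- arrhenius_ln_rate(params, celsius_to_kelvin(grid$temperature_c))
  eps <- if (sd_ln > 0) stats::rnorm(nrow(grid), 0, sd_ln) else 0
  data.frame(isolate = isolate, enzyme = enzyme,
             temperature_c = grid$temperature_c,
             replicate = grid$replicate, rate = exp(mu + eps))
}

# reference MMRT parameter set used across tests
ref_mmrt <- function() mmrt_params(dH = 50000, dS = 0, dCp = -5000)
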