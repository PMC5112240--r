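# thermotrait

Temperature sensitivity of enzyme activity as a measurable microbial
trait, via Macromolecular Rate Theory (MMRT).

Soil microbes secrete extracellular enzymes whose activity depends
strongly on temperature. The classical Arrhenius description,
ln *k* = ln *A* − *E*<sub>A</sub>/(*RT*), predicts a monotone increase and
makes the activation energy *E*<sub>A</sub> the temperature-sensitivity
metric — but measured rate curves bend over and peak. MMRT extends
transition-state theory with a heat capacity of activation
ΔC<sub>p</sub><sup>‡</sup>:

ln *k* = ln(*k*<sub>B</sub>*T*/*h*) − [ΔH<sup>‡</sup> + ΔC<sub>p</sub><sup>‡</sup>(*T* − *T*<sub>0</sub>)]/(*RT*) + [ΔS<sup>‡</sup> + ΔC<sub>p</sub><sup>‡</sup>(ln *T* − ln *T*<sub>0</sub>)]/*R*

A negative ΔC<sub>p</sub><sup>‡</sup> bends the curve concave-down, giving
two further traits in closed or near-closed form: the temperature optimum
*T*<sub>opt</sub> = (ΔC<sub>p</sub><sup>‡</sup>*T*<sub>0</sub> − ΔH<sup>‡</sup>)/(*R* + ΔC<sub>p</sub><sup>‡</sup>)
and the point of maximum temperature sensitivity TS<sub>max</sub>, the
inflection of *k*(*T*) on the rising limb (always below
*T*<sub>opt</sub>).

The package is written for microbial ecologists and enzyme kineticists
who assay rates across temperatures in replicated designs and want to

* fit both models to replicate-level ln rates (`fit_mmrt()`,
  `fit_arrhenius()`, windowed refits),
* extract ΔC<sub>p</sub><sup>‡</sup>, *T*<sub>opt</sub> and
  TS<sub>max</sub> with Monte Carlo standard errors propagated from the
  fit covariance (`mc_trait_se()`),
* compare the models with AICc, adjusted R², lack-of-fit decomposition,
  percent prediction error and the window dependence of *E*<sub>A</sub>
  (`compare_models()`, `lack_of_fit()`, `percent_error()`),
* run the trait-level statistics: variance partitioning across isolate
  and enzyme, Holm-adjusted pairwise Z-tests with compact letter
  displays, trait correlations, and window-to-window relationship-change
  fractions (`anova_partition()`, `pairwise_z()`,
  `compact_letter_display()`, `relationship_change()`).

A synthetic generator (`default_design()`, `generate_rates()`,
`generate_fluorescence()`/`calibrate_fluorescence()`) emulates a
7-isolate × 3-enzyme (BG, LAP, PHOS) × 6-temperature × 8-replicate
fluorometric microplate assay, with true MMRT curves anchored to the
packaged table of published traits (`table1_fixture()`), so the entire
pipeline is testable without any external data.

## Worked example

```r
library(thermotrait)

design <- default_design(seed = 42)       # the emulated assay layout
obs <- generate_rates(design, keep_below_detection = FALSE)

key <- paste(obs$isolate, obs$enzyme, sep = ":")
bg <- obs[key == "Citrobacter:BG", ]

fit <- fit_mmrt(bg)                        # full 4-60 C window
round(fit$coef)
#>    dH    dS   dCp
#> 40828   -70 -3392

mc_trait_se(fit, n_draws = 1000, seed = 9)
#> Topt  = 37.80 C (SE 0.48)
#> TSmax = 22.40 C (SE 0.31)
#> [1000 draws, 0 failed, seed 9]

cmp <- compare_models(bg)
cmp$comparison[, c("delta_aicc", "preferred")]
#>   delta_aicc preferred
#> 1   123.0705      MMRT
round(cmp$ea_profile$E_A / 1000, 1)        # kJ/mol by window 4-25, 4-35, 4-60
#> [1] 79.1 63.2 28.1
```

The fitted heat capacity of activation is ≈ −3400 J mol⁻¹ K⁻¹ (a
moderately curved response); the optimum near 37.8 °C and the maximum
sensitivity near 22.4 °C carry sub-degree Monte Carlo SEs; AICc prefers
MMRT over full-window Arrhenius by ≈ 120 units; and the fitted Arrhenius
activation energy falls from 79 to 28 kJ mol⁻¹ as the fitting window
widens from 4–25 to 4–60 °C — the window dependence that makes
*E*<sub>A</sub> an unreliable cross-study trait.

The full analysis is organised as numbered drivers over the package:

```sh
Rscript analysis/01_simulate.R          # writes results/rates.csv
Rscript analysis/02_fit_traits.R        # fits + traits tables
Rscript analysis/03_model_comparison.R  # AICc, LOF shares, EA windows
Rscript analysis/04_trait_statistics.R  # ANOVA, pairwise letters, correlations
```

Sample output of step 3 on the seed-42 simulation:

```
model preference over 4-60 C (AICc): MMRT 19
pooled lack-of-fit % of total variation (4-35 C data): MMRT 0.2, Arrhenius 4-35 3.6, Arrhenius 4-25 9.9
mean activation energy by window (kJ/mol): 4-25 72.6, 4-35 60.4, 4-60 31.5
```

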