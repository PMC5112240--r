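---
title: "Thermal traits of enzyme activity: models, fitting and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermal traits of enzyme activity: models, fitting and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermotrait)
```

## The scientific problem

Extracellular enzyme activity rises with temperature, peaks, and falls.
Two models compete to describe the rising part and what lies beyond it:

* **Arrhenius**: $\ln k = \ln A - E_A/(RT)$ — monotone in $T$, with the
  activation energy $E_A$ (J mol$^{-1}$) as the single temperature-sensitivity
  parameter.
* **Macromolecular rate theory (MMRT)**: transition-state theory extended
  with a heat capacity of activation $\Delta C_p^\ddagger$,

  $$\ln k = \ln\frac{k_B T}{h}
    - \frac{\Delta H^\ddagger_{T_0} + \Delta C_p^\ddagger (T - T_0)}{RT}
    + \frac{\Delta S^\ddagger_{T_0} + \Delta C_p^\ddagger(\ln T - \ln T_0)}{R}.$$

  A negative $\Delta C_p^\ddagger$ makes the Gibbs energy of activation
  temperature dependent and bends the log-rate curve concave-down, so rates
  peak at a **temperature optimum** $T_{opt}$ without invoking denaturation.

From a fitted MMRT curve the package extracts three thermal traits:

* $\Delta C_p^\ddagger$ — degree of curvature; more negative values mean a
  more rigid transition state and a sharper peak;
* $T_{opt} = (\Delta C_p^\ddagger T_0 - \Delta H^\ddagger)/(R + \Delta C_p^\ddagger)$,
  the closed-form root of $d\ln k/dT$ (it exists when
  $\Delta C_p^\ddagger < -R$);
* $TS_{max}$, the **point of maximum temperature sensitivity** — the
  temperature where $dk/dT$ is greatest, i.e. the inflection of $k(T)$ on
  the rising limb, found as the root of $g(T)^2 + g'(T) = 0$ with
  $g = d\ln k/dT$.  It always precedes $T_{opt}$ and typically falls in
  environmentally relevant ranges.

The package implements the whole analysis around these traits: replicated
least-squares fits of both models, Monte Carlo uncertainty for the derived
traits, model comparison (AICc, adjusted $R^2$, lack of fit, percent
error, window dependence of $E_A$), and trait-level statistics (variance
partitioning, Holm-adjusted pairwise $Z$-tests with compact letters,
correlations, relationship-change fractions).

## Units, reference temperature, and what is comparable

Rates enter as activities in nmol L$^{-1}$ h$^{-1}$, not true first-order
rate constants.  The unit mismatch with the Eyring prefactor $k_BT/h$ is a
*constant* offset in $\ln k$ and is absorbed into $\Delta S^\ddagger$.
Consequently $\Delta S^\ddagger$ (and through it $\Delta H^\ddagger$ at a
different $T_0$) is only comparable within a fixed unit convention, while
$\Delta C_p^\ddagger$, $T_{opt}$, $TS_{max}$ and all fitted curves are
invariant to both the unit convention and the choice of $T_0$.  The
default reference temperature is $T_0 = 298.15$ K (25 °C, the culturing
temperature of the emulated assay); it is fixed during fitting, never
estimated.

Data tables carry temperatures in °C, matching assay practice; all model
math converts to Kelvin internally, and trait points report both scales.

## Fitting

Both models are fit to **replicate-level** ln rates, not temperature
means.  This choice preserves the pure-error degrees of freedom that the
lack-of-fit test needs; fitting means would shrink the reported SEs and
make the lack-of-fit decomposition impossible.  Window endpoints are
inclusive; non-positive rates (below-detection activity) are dropped with
a warning before any ln-scale fit.

The Arrhenius fit is ordinary least squares on $1/T$.  The MMRT fit is a
Gauss–Newton iteration with step halving over
$(\Delta H^\ddagger, \Delta S^\ddagger, \Delta C_p^\ddagger)$; because the
MMRT curve is *linear* in these three coefficients, the first full step
lands on the least-squares solution and the iteration terminates at the
next residual check — the damped loop and a multi-start fallback
($\Delta C_p^\ddagger \in \{-1000, -5000, -12000\}$) exist to guard
degenerate designs, and the `converged` flag is honest.  Starting values:
$\Delta H^\ddagger$ from an Arrhenius fit to the rising limb
($E_A - R\bar T$), $\Delta C_p^\ddagger = -5000$ J mol$^{-1}$ K$^{-1}$,
$\Delta S^\ddagger$ matched to the mean ln rate nearest $T_0$.  The
coefficient covariance is $s^2 (J^\top J)^{-1}$ with $s^2 = rss/(n-3)$.
Convergence: relative RSS change below $10^{-10}$ or coefficient step
below $10^{-8}$, at most 200 iterations.  The test suite cross-checks the
Gauss–Newton solution against an independent `lm()` on the linearized
basis.

### Monte Carlo trait uncertainty

`mc_trait_se()` draws 1000 coefficient vectors (default; a seed is
mandatory) from a multivariate normal at the estimates with the fit
covariance and recomputes $T_{opt}$ and $TS_{max}$ per draw; the SEs are
the sample standard deviations of the successful draws.  Draws with
$\Delta C_p^\ddagger \ge -R$ have no interior optimum; they are counted
and *excluded*, not clamped — clamping would bias the SEs toward zero.
If more than half the draws fail, the uncertainty is reported as
degenerate instead of a number.  Point estimates always come from the
fitted coefficients, not the draw means.

### Numerical choices

* Root finding for $TS_{max}$ is plain bisection to $10^{-6}$ K —
  deterministic and bracket-safe.  The default lower bracket of 250 K is
  far below any assay temperature and brackets the inflection for
  assay-like curvature; the trait-inversion helper widens it to 150–160 K
  because very flat curves push the inflection low.
* $T_{opt}$ uses its closed form; the tests require agreement with a
  dense-grid argmax.
* AICc uses the least-squares form with the error variance counted in the
  parameter total ($p = $ coefficients $+ 1$); the equivalence threshold
  is $|\Delta AICc| < 2$ with an exact tie resolved toward the model with
  fewer coefficients.  Both are stated explicitly because software
  conventions differ; both are configurable.
* The lack-of-fit F uses $df_{lof} = (\#\text{temperatures}) -
  (\#\text{coefficients})$ and $df_{pure} = n - \#\text{temperatures}$.
* Percent error is computed on the natural rate scale (the claim under
  test concerns reaction rates, not their logs); an `"ln"` option exists.

## The synthetic assay generator

No raw assay data are available, so the generator reproduces the study
*design*: 7 isolates × 3 enzymes (BG, LAP, PHOS) × 6 temperatures
(4, 11, 25, 35, 45, 60 °C) × 8 replicates, with two combinations
(Bacillus × BG, Comamonas × PHOS) below detection, leaving 19 of 21.

Choices made where the emulated study is silent:

* **True parameters.**  Rather than sampling arbitrary parameters inside
  plausible ranges, each combination's true
  $(\Delta H^\ddagger, \Delta C_p^\ddagger)$ is obtained by *inverting*
  the published $(T_{opt}, TS_{max})$ pair for that combination
  (`mmrt_params_from_traits()`): $T_{opt}$ fixes $\Delta H^\ddagger$
  given $\Delta C_p^\ddagger$, and $TS_{max}$ then pins
  $\Delta C_p^\ddagger$ by 1-D root finding.  The generator's true traits
  are therefore exactly the published ones (Topt 33.5–60.7 °C, TSmax
  18.2–40.25 °C), which is the strongest sense in which simulated data
  can "mimic" the study.  The seed drives the per-combination activity
  scale — a 25 °C rate level drawn uniformly on the log scale between 30
  and 250 nmol L$^{-1}$ h$^{-1}$, a typical span for fluorometric
  microplate assays — and the measurement noise.
* **Noise.**  Gaussian on ln rate (log-normal rates), SD 0.2.  Fits are
  performed on ln rate and rates are strictly positive, so a log-scale
  noise model is the natural choice; 0.2 was chosen because it makes the
  simulated per-combination $T_{opt}$ SEs (median ≈ 0.7 °C, range
  0.3–2 °C) match the magnitude of the published ones (median 0.9 °C,
  range 0.4–2.7 °C).  It is a calibration default, not a measured value.
* **Calibration emulation.**  The fluorometric step (MUB/MUC standard
  curves, 2.5–100 µM) is emulated as an exact linear inverse pair:
  `generate_fluorescence()` maps rates to plate fluorescence through a
  standard curve and one configurable volume/time conversion factor, and
  `calibrate_fluorescence()` maps back.  The assay's detailed well
  arithmetic (40 µL substrate + 160 µL mixture, 1–23 h incubations) is
  deliberately collapsed into that single factor — the published
  description does not determine it, and every downstream statistic is
  invariant to it.

What the generator does **not** emulate: enzyme denaturation kinetics,
substrate depletion over long incubations, plate-position effects, or
between-combination noise heterogeneity.  Passing tests on synthetic data
therefore demonstrate that the estimation and comparison machinery is
correct under the stated noise model — not that real assay noise is
log-normal with SD 0.2.

## Trait-level statistics

* **Pairwise tests** use the two-sample approximate $Z$ on fit-derived
  SEs.  Comparison families follow the panel semantics of grouped bar
  figures: isolates within one enzyme (and within one window for $E_A$);
  enzymes within one isolate are a separate, explicitly requested family.
  The Holm adjustment runs within each family.
* **Compact letters** are assigned greedily in descending-estimate order
  with an absorption pass, so two members share a letter iff their
  difference is not significant.
* **Variance partitioning** uses sequential SS from `lm()`.  The 19-cell
  trait matrix is unbalanced, so sequential SS depend on factor order;
  the partition is computed in both orders, both are reported along with
  their mean, and divergence above one percentage point is flagged.  A
  single unambiguous percentage (as a balanced design would give) does
  not exist here.
* **Relationship changes** between two windows count the pairs whose
  Holm-adjusted significance flag differs.
* $\alpha = 0.05$ throughout, configurable.

## Pooling and the published table

The packaged fixture (`table1_fixture()`) stores the 19 published
per-combination $T_{opt}$/$TS_{max}$ values exactly as printed, with
their mixed decimal precision.  The published pooled rows are *not*
reproduced: the printed pooled values are not the column means of the
printed rows (e.g. the LAP $T_{opt}$ column mean is ≈ 42.8 against a
printed pooled 42.6), and the pooling method is not stated, so the
package does not guess one.  Squared correlation of the printed
$T_{opt}$ and $TS_{max}$ columns gives 0.82; the value computed from
unrounded fits in the original analysis is 0.84.

## Problem sizes used in the shipped checks

The packaged simulation studies run the full design (19 combinations,
48 observations each): 200 simulated data sets for parameter recovery and
model selection, and 51 for the lack-of-fit ordering (each of whose seeds
needs three extra window fits per combination).  These sizes put the
Monte Carlo error of the reported percentages around one point, which is
adequate to the qualitative claims they check.

## Known limitations

* $\Delta H^\ddagger$/$\Delta S^\ddagger$ are $T_0$- and unit-referenced;
  only compare them across fits sharing both conventions.
* $T_{opt}$ estimates for combinations whose optimum sits near or above
  the top assay temperature (60 °C) are extrapolations with SEs of
  1–2 °C or more — visible in both the published SEs and the simulation
  study, where about a fifth of fitted optima land more than 1 °C from
  the truth, concentrated in those hot combinations.
* The lack-of-fit percentages depend on the evaluation set.  Comparing
  window-limited fits fairly requires a common evaluation window
  (here 4–35 °C, where all three models are meant to apply); within-own-
  window decompositions are also available and smaller for narrower
  windows.
* Below-detection handling is a hard exclusion; no censored-data model is
  attempted.
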