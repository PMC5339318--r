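---
title: "Methods: thermal preference, shredding efficiency, and capacity projection"
author: "thermoshred"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermal preference, shredding efficiency, and capacity projection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoshred)
```

# The scientific problem

Freshwater amphipod shredders convert coarse leaf litter into fine
particulate organic matter, a rate-limiting step in stream energy flow. When
an invasive amphipod (*Dikerogammarus villosus*) displaces a native one
(*Gammarus pulex*), ecosystem consequences depend jointly on each species'
per-capita shredding, its thermal sensitivity, its mortality under warming,
and its behavioural ability to select favourable microclimates. This package
implements the full quantitative chain that links those pieces: preferendum
estimation from gradient-track behaviour, Boltzmann–Arrhenius activation
energies of shredding, preference–performance coupling, and population-level
capacity projection — together with seeded synthetic-data generators so that
every estimator can be validated against known ground truth.

# Thermal preferenda by the acute method

Each animal acclimated to temperature $T_{acc}$ is observed on a 4–24 °C
gradient track; the water temperature at its position is recorded at fixed
intervals. Analysis proceeds in three steps:

1. **Individual medians.** The median of an individual's recorded
   temperatures is its selected temperature; using one number per animal
   avoids pseudoreplication from autocorrelated position records
   (`median_selected_temperature()`, `individual_medians()`).
2. **Acute preferenda.** Group means ($\pm$ SE) of the medians per species
   and acclimation temperature (`acute_preferenda()`). A group of one animal
   reports an undefined SE, never zero.
3. **Final preferendum.** Regressing acute means on acclimation temperature
   gives the acute preference line $a + b\,T_{acc}$; its intersection with
   the line of equality (preferred = acclimation) is the final preferendum
   $a/(1-b)$, defined whenever $|b| \ne 1$ (`final_preferendum()`). Because
   the intersection is a non-linear function of the correlated estimates
   $(a, b)$, the confidence interval is a parametric bootstrap (default
   1000 draws) from their joint normal sampling distribution rather than a
   delta-method approximation.

Spatial artefacts are excluded by a control run on a uniform-temperature
track: positions are binned into 10 cm sections (half-open bins, the last
closed) and tested against uniformity with Pearson's chi-squared on 11 df
(`control_uniformity_test()`). The upper-tail probability is the regularised
incomplete gamma function; the package uses R's `pchisq` and the test suite
verifies it against an independent series/continued-fraction implementation
to 1e-10.

## Candidate models and AICc averaging

Median preferenda are modelled against species, acclimation temperature
(continuous), their interaction, and optionally sex and body size.
`fit_preference_models()` fits the candidate set of all marginality-respecting
subsets by Gaussian least squares, ranks by the small-sample criterion
$AICc = -2\ln L + 2k + 2k(k+1)/(n-k-1)$ (`aicc()`), retains models within
$\Delta AICc < 4$ of the best, and averages coefficients with Akaike weights
$w_i = e^{-\Delta_i/2}/\sum_j e^{-\Delta_j/2}$
(`akaike_weights_and_average()`). Averaging uses **zero substitution** (a
model omitting a term contributes zero for it); conditional averaging was the
alternative, but zero substitution is the more conservative default for
effect sizes and is what `delta_cutoff`-style selection commonly pairs with.
The original analysis of this design used linear mixed models with
experimental track and run time as random effects; this package deliberately
fits the fixed-effects structure only (track/run can enter as fixed blocking
factors), because the scientific content exercised here — the candidate set,
AICc ranking, weights, averaging, and the sign of the species × acclimation
interaction — is unchanged, while REML machinery is out of scope. This is a
known limitation for data with strong track-level heterogeneity.

# Shredding efficiency and its temperature dependence

A replicate pot holds two animals and a pre-weighed batch of dried leaf
discs for 72 h, with deaths checked every 24 h. Consumption is standardised
by **amphipod-days** — the number of animals alive each day summed over the
trial (`amphipod_days()`). Because deaths are discovered at daily checks,
the death day itself is ambiguous; the default convention counts a death at
the day-$d$ check as $d$ part-lived days (`death_day_counts = "partial"`,
with `"none"` available), a choice that changes efficiencies by construction
and is therefore exposed in the interface. Replicates with a moulted animal
are excluded outright (moulting suppresses feeding), and zero amphipod-day
replicates are excluded rather than yielding infinite rates. Animal-free
control pots lose under 2% of leaf mass, so the default background
correction is zero; `control_loss_fraction = "empirical"` subtracts the mean
per-temperature control loss instead.

Body length and wet mass are collinear size measures; both are standardised
and combined into the first principal component (`body_size_index()`), whose
explained variance is $(1+r)/2$ for correlation $r$. A one-way ANOVA of PC1
scores by species (`size_match_test()`) verifies size-matching. The species ×
temperature two-way ANOVA (`two_way_anova()`) treats temperature as a
categorical factor (8 levels), uses Type-I sums of squares on the balanced
design, removes a non-significant interaction by stepwise deletion, and falls
back to Type-II sums of squares with a warning when cells are empty.

## Boltzmann–Arrhenius activation energies

Temperature is standardised as $x(T) = 1/(kT_c) - 1/(kT)$ with
$k = 8.62\times10^{-5}$ eV K$^{-1}$ and $T_c = 288.15$ K (15 °C), so $x$ is
zero at the reference and increases with warmth (`boltzmann_x()`). The
activation energy $E_a$ is the slope of $\ln(\text{mean rate})$ on $x$
(`arrhenius_fit()`), fitted to **one point per temperature**: per-temperature
means are taken first and logged afterwards. This ordering reproduces the
high $R^2$ values and the ANCOVA denominator df of 12 seen with 2 species ×
8 temperatures, and makes the regression robust to replicate-level zeros.
Confidence intervals use the t distribution on $n-2$ df. Rates default to
mass-specific units (g leaf g body$^{-1}$ day$^{-1}$,
`mean_rates_by_temperature(mass_specific = TRUE)`) because the capacity
projection multiplies rate by mean body mass; per-capita units are a switch
away.

Metabolic theory predicts $E_a \approx 0.60$–$0.70$ eV for consumer–resource
interactions. `mte_band_check()` classifies a fit as `within` (estimate in
band), `overlapping-CI` (only the CI touches the band) or `outside`.

`species_ancova()` tests whether the temperature–shredding relationship
differs between species. The default `"overall"` comparison is the F test of
the full 4-parameter species model (species-specific intercepts and slopes)
against the intercept-only model — numerator 3 df, denominator $n-4$, i.e.
$F_{3,12}$ for 16 points, matching the df bookkeeping of the original
analysis; `"common-line"` (2 df) and `"interaction-only"` (1 df) give the
sharper nested contrasts.

# Preference–performance coupling

Each experimental temperature owns a ±1 °C **zone**; habitat use is the mean
number of position records per 15 °C-acclimated individual falling in a
zone, and performance is the mean leaf mass consumed per individual over
72 h at the corresponding temperature (`zone_summaries()`). The per-individual
divisor is survivor exposure, `amphipod_days / trial_days`, so mortality
shrinks the denominator rather than inflating apparent consumption. Zones
overlap at 9.0 °C (between 8 and 10) and 16.5 °C (between 15.5 and 17.5);
records at an overlap go to the nearer centre, exact ties to the lower, and
the upper zone edge is otherwise exclusive, so each record maps to at most
one zone.

Both axes carry measurement error, so the model
$\text{performance} = \alpha + \beta/\text{use}$ is fitted by **orthogonal**
non-linear least squares (`onls_fit()`): the objective is the sum of squared
two-axis distances, each axis standardised by its pooled SE (unit weights if
SEs are absent). The foot point of each datum is found by bounded 1-D
minimisation nested inside a Nelder–Mead search over $(\alpha, \beta)$,
started from the OLS fit of $y \sim 1/u$ plus four fixed dispersed starts (no
randomness, so fits are reproducible by construction). The standard error of
$\beta$ comes from the curvature (numerical Hessian) of the orthogonal
objective with $\hat\sigma^2 = RSS/(n-2)$, and the t test uses $n-2$ df —
6 for the 8-temperature design, which reproduces both published p-values
from their t statistics. A negative $\beta$ means performance *rises to the
asymptote* $\alpha$ with increasing use: the animal concentrates its time
where it performs best. The test suite checks the optimiser against a
brute-force grid-refinement oracle on small instances (≤ 1e-3 relative) and
verifies that the orthogonal RSS never exceeds the vertical RSS.

# Population-level capacity

`project_capacity()` applies the exact identity

$$\text{capacity}(T) = \underbrace{3\,e^{\,\hat{a} + \hat{E}_a x(T)}}_{\text{g leaf g}^{-1}\,(72\,h)^{-1}} \times \text{mean mass} \times \text{survival}(T) \times N$$

for a hypothetical population of $N = 100$ animals (default mean masses
0.0305 g and 0.0682 g for the native and invasive species). Survival per
temperature is an input column — in the synthetic study it comes from
`survival_rate()` (Wilson 95% intervals), never from digitised figures.
`capacity_trend()` reports the Pearson correlation of capacity with
temperature over the 8 design temperatures with
$t = r\sqrt{n-2}/\sqrt{1-r^2}$, and `species_capacity_ratio()` the percent
difference between species at a temperature. A capacity that is constant to
within 1e-10 relative is reported as $r = 0$ with a flag rather than NaN.

# The synthetic-data generators

The generators (`generate_position_traces()`, `generate_control_traces()`,
`generate_body_sizes()`, `generate_shredding_trials()`) emulate the two
experimental designs with known ground truth, and their defaults are the
study conditions:

* Gradient runs: 3 acclimation temperatures (5, 15, 20 °C) × 30 animals per
  species, 15 records each (observations every 3 min over 45 min, intervals
  ending at 45). Recorded temperatures are i.i.d. truncated-normal draws
  around the acute preference line — there is no locomotion model, because
  every downstream estimator uses only the marginal distribution of recorded
  temperatures. Default lines: $12.06 + 0.1\,T_{acc}$ (native, final
  preferendum 13.4 °C) and $15.73 - 0.1\,T_{acc}$ (invader, 14.3 °C), with
  within-individual sd 2 °C.
* Controls: 6 animals × 30 uniform positions per species (180 records).
* Shredding trials: 8 temperatures (5–22.5 °C) × 2 size classes × 10 pots of
  2 animals over 3 days; leaf batches of 16.00 ± 3.27 mg (treated as an SD)
  truncated positive. Consumption is mass-specific on an Arrhenius line
  (defaults from the size-matched regressions: intercept −4.53 / $E_a$ 0.40
  for the native, −5.57 / 0.83 for the invader; ln-scale animal noise
  sd 0.3). Mortality is per-animal per-day logistic in temperature; the
  published survival curves are plotted but never printed, so the logit
  parameters are free configuration chosen to make warming clearly more
  lethal to the native species. Moults occur with probability 0.05 per
  animal. Size-matched replicates draw both species from a common size
  target (13.3 mm, 0.038 g, halved CV) — the matched design is only matched
  if the generator actually matches — while full-range replicates use each
  species' own bivariate lognormal (default log-scale length–mass
  correlation 0.876, so PC1 explains ≈ 93.8%).
* Body lengths are in millimetres throughout.

Each generator seeds its own RNG stream from the master seed (streams are
split per experiment), so identical seed and configuration reproduce
byte-identical tables, and enabling one generator never shifts another's
draws.

**What the generators do not emulate:** behavioural interaction between
paired animals, spatially explicit gradient dynamics, water chemistry,
food-depletion kinetics (consumption beyond the leaf supply is floored and
flagged `depleted`), growth, and track-level random heterogeneity. Passing
recovery tests therefore demonstrates that the estimators are correct for
data whose error structure matches these assumptions, not that real
gradient-track data are free of the excluded effects.

# Numerical choices and degenerate inputs

* Truncated normals use inverse-CDF sampling (no rejection loops), keeping
  the RNG stream advance deterministic.
* `final_preferendum()` raises an error when $|1-b|$ < 1e-6 (preference
  parallel to the line of equality).
* Chi-squared bins are half-open with the last closed, so every position
  maps to exactly one bin; an expected count below 1 triggers a validity
  warning.
* The ONLS inner search is bounded to $[10^{-4}\,\mathrm{med}(u),\,4\max(u)]$
  and the datum's own abscissa is always considered, which guarantees the
  orthogonal RSS cannot exceed the vertical RSS.
* The two-way ANOVA refuses to report F statistics when the residual sum of
  squares is zero to machine precision.
* Pairwise Welch t-tests with Holm correction (`pairwise_welch()`) are
  provided as a labelled approximation to post-hoc comparison and are off by
  default; studentized-range (Tukey) machinery is intentionally not
  implemented.
* All temperatures are °C in every table; kelvin appears only inside
  `boltzmann_x()`.

# Problem sizes used in validation

The bundled validation suite runs the estimators at the design's native
scale (30 animals per group; 10 replicates per cell) and uses 40–200 seeded
replicates for recovery checks, 1000 for CI-coverage and type-I-error rate
checks. The script `scripts/acceptance.R` re-derives activation energies
(200 replicates, per-temperature ln-rate noise sd 0.1) and final preferenda
(200 replicates of the full 90-animal trace design) from scratch at any
seed.

# Session info

```{r}
sessionInfo()
```
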