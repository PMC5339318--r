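# thermoshred

Quantitative thermal biology and ecosystem function of freshwater amphipod
shredders — built around the contrast between the native *Gammarus pulex*
and the invasive "killer shrimp" *Dikerogammarus villosus*.

Leaf-shredding amphipods control the conversion of coarse leaf litter into
fine particulate organic matter in streams. Whether replacement of a native
shredder by an invader degrades that function depends on four measurable
pieces, all implemented here:

1. **Thermal preferenda (acute method).** Per-individual median selected
   temperatures on a 4–24 °C gradient track → acute preferenda per
   acclimation group → the **final preferendum** as the intersection of the
   acute preference line `a + b·T_acc` with the line of equality,
   `a / (1 − b)`, with a parametric-bootstrap CI. Control-track spatial
   uniformity is tested by chi-squared over 10 cm bins, and candidate
   preference models (species × acclimation × sex × size) are ranked by
   AICc with Akaike-weight model averaging over the ΔAICc < 4 set.
2. **Shredding efficiency.** Dry leaf mass consumed per **amphipod-day**
   (animals alive each day, summed), with moult exclusions, control-loss
   correction, a PCA body-size index, and species × temperature two-way
   ANOVA with stepwise deletion.
3. **Metabolic-theory (Arrhenius) analysis.** ln mean shredding rate
   regressed on the Boltzmann-standardised temperature
   `x(T) = 1/(k·288.15) − 1/(k·T)` (k = 8.62e-5 eV/K); the slope is the
   activation energy `E_a` (eV), classified against the 0.60–0.70 eV band
   predicted by the metabolic theory of ecology, plus a species ANCOVA.
4. **Preference–performance coupling and capacity projection.** Habitat use
   per ±1 °C temperature zone vs per-capita performance, fitted by
   **orthogonal** non-linear least squares (`performance ~ α + β/use`, both
   axes measured with error); then population-level shredding capacity
   `rate × mean mass × survival × 100` across temperature, with Pearson
   trend tests and species ratios.

Seeded synthetic-data generators emulate both experimental designs
(gradient runs: 3 acclimation temperatures × 30 animals × 15 records;
shredding: 8 temperatures × 2 size classes × 10 pots of 2 animals over
72 h) so every estimator is validated by parameter recovery against known
ground truth. See `vignettes/thermoshred-methods.Rmd` for the full model
descriptions, conventions and limitations.

## Worked example

```r
library(thermoshred)

# full synthetic study with the default (study-condition) parameters
res <- run_pipeline(seed = 42)

res$final_preferenda$G.pulex
#> Final thermal preferendum (G.pulex): 13.49 degC
#>   acute line: pref = 12.345 +0.085 * T_acc
#>   bootstrap CI: (13.29, 13.69) degC

res$uniformity$G.pulex
#> Spatial uniformity: chi2 = 11.07, df = 11, p = 0.438

res$arrhenius[["D.villosus.matched"]]
#> Arrhenius fit (D.villosus, size-matched): E_a = 0.85 eV (0.74, 0.97),
#>   intercept -5.53 (-5.63, -5.44), R2 = 0.98, n = 8

res$ancova
#> F(3,12) = 430.9, p = 1.8e-12
```

The generating truths behind this run were a final preferendum of 13.4 °C
(`a = 12.06`, `b = 0.1`) for *G. pulex* and an activation energy of 0.83 eV
(intercept −5.57) for size-matched *D. villosus*: the pipeline recovers
13.49 °C and 0.85 eV from one simulated study, and converges to the
generating values when averaged over seeds (see the tests and the
acceptance script). The uniformity p of 0.438 on df = 11 correctly finds no
positional bias in the uniform-temperature control. `run_pipeline(outdir =
...)` additionally writes every stage's table (`preferenda.csv`,
`efficiencies.csv`, `arrhenius.csv`, `projection.csv`, ...) plus a
`ground_truth.json` sidecar.

Individual stages are ordinary functions on data frames —
`individual_medians()`, `acute_preferenda()`, `final_preferendum()`,
`shredding_efficiency()`, `arrhenius_fit()`, `mte_band_check()`,
`zone_summaries()`, `onls_fit()`, `project_capacity()` — and can be applied
directly to field or laboratory tables in the documented CSV schemas
(`validate_position_traces()`, `validate_shredding_trials()`).

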