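# bactoSeries

Seasonal and decadal analysis of flow-cytometric bacterioplankton time
series.

Coastal heterotrophic bacterioplankton resolve, in flow cytometry, into
low (LNA) and high (HNA) nucleic-acid content groups with distinct
ecology (LNA dominated by the SAR11 clade). A decade of monthly
observations of their abundance, mean cell size and biomass tests two
ecological rules — the temperature–size rule (warmer water → smaller
cells) and the abundance–size rule (more cells → smaller cells) — on
both the seasonal and the interannual scale. `bactoSeries` implements
the full analysis chain as a tested, reusable R package:

- **Synthetic data** (`generateSeries`, `generateCytogram`,
  `generateProfile`, `generateExperiment`, `syntheticScenario`): every
  pipeline input with known ground truth, so the whole chain is
  verifiable without any external data.
- **Hydrography** (`mixedLayerDepth`, `stratificationIndex`,
  `umlAverage`, `umlSummary`): mixed-layer depth by the ≥ 0.05 kg m⁻³
  per 5 m density criterion, per-metre surface-to-75 m stratification
  index, and upper-mixed-layer averages from CTD casts.
- **Cytometry stocks** (`gateLnaHna`, `cytometryAbundance`,
  `ralsToVolume`, `biomassPerCell`, `biomassConcentration`,
  `populationStats`): reproducible LNA/HNA gating with a photosynthetic
  red-fluorescence guard, abundance from calibrated flow volumes, cell
  size from a scatter→diameter power law (spherical volume), and carbon
  via pg C cell⁻¹ = 0.12 × V^0.72.
- **Decomposition** (`decomposeSeries`, `fitTrend`, `periodogram`,
  `fisherGTest`, `fitHarmonics`, `fitAr`, `tMax`): the additive model

  x_t = x̄ + (a + b·t) + Σᵢ Aᵢ·cos(2πt/Tᵢ − θᵢ) + η_t,  η_t = φ·η_{t−lag} + ε_t

  with harmonic components retained by the exact Fisher G-test, one
  autoregressive term, and a percent-variance ledger whose components
  sum to its total by construction. The harmonic maximum falls at
  t_max = θT/2π months into the cycle.
- **Residuals** (`prewhiten`, `correlateResiduals`,
  `correlationMatrix`): pre-whitened Pearson cross-correlations with
  the ***/**/* star convention, free of seasonal confounding.
- **Experiments** (`sizeTemperatureSlope`, `monthlySlopes`,
  `crossGroupSlopeRegression`, `windowMeanSeries`, `annualTrend`,
  `projectedSizeChange`): model I cell-size-vs-temperature slopes from
  incubations at in situ ±3 °C, April–July window trends over
  April–March analysis years, and warming projections of community size
  change.
- **Orchestration** (`runPipeline`, `pipelineConfig`, CSV/YAML readers
  and writers, `inst/scripts/bactoseries-cli.R`): end-to-end runs with
  seeded determinism and a config-hash-stamped run log.

## Worked example

Decompose a synthetic decade of upper-mixed-layer temperature whose
ground truth is the monitored site's annual cycle (mean 15.7 °C,
amplitude 3.89, phase 4.26 rad, lag-1 autocorrelation 0.34):

```r
library(bactoSeries)
s   <- generateScenarioSeries("temperature", seed = 1)
fit <- decomposeSeries(s)
fit
#> SeriesDecomposition of 'temperature' (n = 120, alpha = 0.05)
#>   climatological mean: 15.91
#>   harmonic: T = 12 mo, A = 4.217, theta = 4.289, Tmax = 8.19, %var = 86.18
#>   AR: lag 1, phi = 0.299, %var = 1.13
#>   total %var explained: 87.31
```

The fitted annual component peaks 8.2 months into the cycle (the
ground truth is θT/2π = 4.26·12/2π = 8.14, i.e. a mid-August maximum
for an April-anchored series), the lag-1 autocorrelation is recovered
near 0.34, and the ledger total is exactly the sum of its parts.
Pre-whitened residuals for cross-variable correlation come from
`prewhiten(s, fit)` (residual mean ~0). Standing stocks from a
synthetic cytogram:

```r
populationStats(generateCytogram(1000, seed = 1))
#>   group abundance   size biomass
#> 1   LNA     16650 0.0306   0.162
#> 2   HNA     16683 0.0415   0.202
#> 3 total     33333 0.0361   0.366
```

— abundances in cells mL⁻¹ (total = LNA + HNA exactly), sizes in µm³
(total is the abundance-weighted group mean), biomass in µg C L⁻¹
through the allometric carbon conversion.

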