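# musselclim

Climate-suitability analysis for the freshwater pearl mussel
(*Margaritifera margaritifera*) from shell morphometrics.

The freshwater pearl mussel is a critically endangered, cold-adapted,
extremely long-lived bivalve of oligotrophic European rivers. Its shell
convexity — the width-to-length ratio, scaled to percent,

    SCI = 100 · W / L

— increases with water (and hence summer air) temperature, because warm
summers widen the annual shell growth increments. Population mean SCI
therefore works as a cheap, collection-friendly thermal indicator that can
be read off both recent samples and centuries-old museum lots.

`musselclim` implements the full analysis chain around that idea:

- **Morphometrics** — per-shell SCI and the integrated index
  SCI_I = 100 · W / √(π·L·H); a 50-mm ontogenetic filter; population
  aggregation (population means are the inference unit); pooled-variance
  t-tests; Lilliefors normality checks with Monte-Carlo p-values;
  ANCOVA-style width~length GLMs with Type III sums of squares and
  backward simplification; a separate-slopes latitude × period test.
- **Climate extraction** — from gridded monthly air temperature (long
  CSV, CRU-TS-style 0.5° layout): mean summer (June–August) temperature
  over the k ∈ {10, 20, 30, 40, 50} years before collection (MST_k),
  seasonal/annual/monthly means, effective temperature sums above 5/10 °C,
  and thermal growing-season length.
- **Calibration** — ordinary least squares of population mean SCI on
  MST20 (and of maximum age A_max on SCI), predictor ranking, seeded
  5-fold cross-validation reporting MAPE, Tofallis's log accuracy ratio
  mean|ln(pred/obs)| and min-max accuracy, Moran's *I* spatial
  autocorrelation with inverse great-circle-distance weights, and
  explicit/studentized-residual outlier handling.
- **Growth** — von Bertalanffy constants via the Ford–Walford plot
  (L_{t+1} = a + b·L_t, K = −ln b, L∞ = a/(1−b)), logarithmic increment
  trend as fallback, age from the inverted growth curve.
- **Suitability** — thresholds A4 (viable mean) < A3 = (A2+A4)/2 ≤ A2
  (declining mean) < A1 = A2 + 1.96·s.e.m.; classification of each range
  cell as viable (SCI ≤ A3), declining (A3 < SCI ≤ A1) or unsuitable
  (SCI > A1) for past periods and future scenario grids;
  cosine-of-latitude area shares; per-site SCI and longevity
  reconstructions back through the instrumental record.
- **Synthetic data** — a fully seeded world generator (latitudinal
  temperature gradient + warming trend, calibration-linked shell
  populations, temperature-linked ring series) so every stage is testable
  without external data.
- **Pipeline** — `run_pipeline()` sequences all stages, writes CSV
  reports and a JSON manifest; `inst/scripts/musselclim` is a thin
  command-line wrapper with per-stage subcommands.

## Worked example

Simulate a study-scale synthetic world (49 recent + 13 historical
populations on a warming 0.5° grid), refit the temperature calibration,
derive thresholds and map the area shift:

```r
library(musselclim)

spec  <- world_spec(seed = 42)
grid  <- generate_climate(spec)
world <- generate_populations(spec, grid)

pops   <- aggregate_populations(filter_shells(world$shells))
recent <- merge(pops[pops$period == "recent" & !pops$excluded, ],
                world$populations[, c("population_id", "mst20")],
                by = "population_id")

cal <- fit_calibration(recent$mst20, recent$mean_sci,
                       xlab = "MST20", ylab = "SCI")
print(cal)
#> Linear calibration: SCI = 16.827 + (0.771 x MST20)
#>   Pearson r = 0.75, F(1,47) = 59.9, p = 6.23e-10, n = 49, residual sd = 1.310

cv <- kfold_cv(recent$mst20, recent$mean_sci, k = 5, seed = 42)
#> pooled MAPE 3.62%, Tofallis 0.0360, min-max 0.9651

morans_i(residuals(cal$model), recent$lat, recent$lon)
#> Moran's I (inverse great-circle distance weights), n = 49
#>   observed I = -0.08, expected I = -0.02, variance = 0.00, z = -1.76, p = 0.08

th <- derive_thresholds(pops[pops$status == "viable", ],
                        pops[pops$status == "declining", ])
mask <- expand.grid(lat = grid$lat, lon = grid$lon)
maps <- lapply(list(`1901-1920` = c(1901, 1920), `1991-2010` = c(1991, 2010)),
               function(p) classify_cells(project_sci(grid, mask, p, cal), th))
area_summary(maps)
#>      period    viable declining unsuitable no_data
#> 1 1901-1920 0.4405773 0.4384953  0.1209274       0
#> 2 1991-2010 0.3146724 0.4018912  0.2834364       0
```

The fitted line recovers the generative calibration (true slope 0.666
SCI/°C) within its standard error; the cross-validated error is a few
percent of the index; the residuals show no significant spatial
autocorrelation; and under the simulated 20th-century warming the
viable area share drops from 44% to 31% while the unsuitable share more
than doubles — the qualitative range-contraction signal the thresholds
are designed to expose.

Real shell tables, climate grids, ring series and range masks enter
through `read_shells()`, `read_climate_csv()`, `read_rings()` and
`read_mask()`; `run_pipeline(pipeline_config(...))` drives the whole
chain and records a manifest.

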