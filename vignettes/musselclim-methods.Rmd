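---
title: "Shell convexity as a thermal indicator: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shell convexity as a thermal indicator: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(musselclim)
```

## The model

The freshwater pearl mussel (*Margaritifera margaritifera*) lays down one
shell growth increment per year, and warm summers widen those increments.
Shell convexity — width relative to length,
$\mathrm{SCI} = 100\,W/L$ — integrates this thermal signal over the
decades an individual grows, so the *population mean* SCI tracks the mean
summer air temperature of the decades before collection. The package
builds a complete analysis around three linked regressions:

1. **Thermal calibration.** Population mean SCI is regressed on the mean
   June–August air temperature of the 20 years preceding sample
   collection ($\mathrm{MST}_{20}$):
   $\mathrm{SCI} = \beta_0 + \beta_1\,\mathrm{MST}_{20}$.
   The 20-year window reflects the species' slow growth and longevity; the
   windows 10–50 years are all computed, and `compare_predictors()` ranks
   the full battery (seasonal/annual/monthly means, degree-day sums,
   growing-season length) by absolute Pearson correlation.
2. **Longevity calibration.** Population maximum age, estimated from the
   largest shell via the inverted von Bertalanffy curve, declines with
   SCI: $A_{\max} = \gamma_0 + \gamma_1\,\mathrm{SCI}$, $\gamma_1 < 0$.
   Faster, warmer growth means shorter lives.
3. **Suitability thresholds.** With $A_4$ and $A_2$ the mean SCI of
   field-assessed viable and declining populations, the class boundaries
   are $A_3 = (A_2 + A_4)/2$ (viable/declining) and
   $A_1 = A_2 + 1.96\,\mathrm{s.e.m.}$ (declining/unsuitable, the 95%
   upper confidence bound of the declining mean). Projecting the thermal
   calibration onto a gridded climatology and cutting at $A_3$ and $A_1$
   classifies every range cell as viable, declining or unsuitable for any
   20-year period or scenario grid. No lower SCI bound is imposed:
   the species is cold-adapted, so arbitrarily cool cells remain viable.

Population means, not individual shells, are the unit of all
inter-population inference; a shell shorter than 50 mm is excluded
before aggregation to limit ontogenetic allometry (the boundary is
inclusive: exactly 50 mm is kept).

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `min_length_mm` | 50 | mm | ontogenetic filter; strict-less exclusion |
| MST window `k` | 20 | yr | matches shell growth integration time; 10–50 supported |
| summer months | Jun–Aug | — | boreal convention |
| ETS bases | 5, 10 | °C | standard thermal-sum bases |
| CV folds | 5 | — | seeded uniform partition; `k = n` gives deterministic leave-one-out |
| outlier threshold | 2.5 | — | externally studentized residual flag |
| threshold multiplier | 1.96 | — | normal 95% bound, used as printed rather than a t quantile |
| minimum n per sample | 11 recent / 5 historical | shells | museum lots are smaller; sub-minimum samples are flagged, not silently used |

## Conventions and numerical choices

- **Windows.** $\mathrm{MST}_k$ averages the $k$ calendar years strictly
  *before* the collection year; the collection year itself is excluded
  (a shell collected in June has not recorded that summer). Winter (DJF)
  takes December from the preceding calendar year, so the first winter of
  a window reaches one year further back.
- **Grid cells** are half-open, $[\mathrm{south}, \mathrm{north}) \times
  [\mathrm{west}, \mathrm{east})$: a point on an edge belongs to the
  north/east cell. February always counts 28 days — the leap-day bias on
  degree-day sums is below 0.1% and determinism is worth more.
- **Missing months propagate.** Any missing month inside a window makes
  the site value `NA` with an explicit `reason` attribute; nothing is
  interpolated.
- **$\mathrm{SCI_I}$** uses the sagittal area *as defined*,
  $\pi L H$ without the geometric 1/4; the constant is absorbed into the
  index scale, and $\mathrm{SCI_I} = \mathrm{SCI}\sqrt{L/(\pi H)}$ holds
  exactly, which the tests exploit. Since $\mathrm{SCI_I}$ is an algebraic
  function of SCI it is reported but not used as a separate predictor.
- **t-tests** are pooled-variance Student's tests (df $= n_1 + n_2 - 2$),
  not Welch. **GLMs** report Type III (marginal) sums of squares with
  sum-to-zero contrasts and are simplified by sequential exclusion of
  non-significant terms at $\alpha = 0.05$, interaction first; population
  means enter unweighted (weighting by shell count is deliberately not
  done — sample size is uncorrelated with the index). The
  **separate-slopes** comparison tests period-specific intercepts and
  latitude slopes against a single common line, an F-test with 2
  numerator df.
- **Lilliefors** p-values come from Monte-Carlo simulation of the null
  (default $10^4$ draws under a fixed internal seed) because closed-form
  approximations are inexact; the statistic itself matches the standard
  implementation to $10^{-10}$.
- **Cross-validation accuracy.** Tofallis's relative accuracy measure is
  implemented as the mean absolute log accuracy ratio
  $\mathrm{mean}\,|\ln(\hat y / y)|$ — the log-ratio form is the one whose
  magnitude matches the reported scale — and min-max accuracy as
  $\mathrm{mean}\,[\min(y, \hat y)/\max(y, \hat y)]$, its standard
  definition. Fold sizes differ by at most one, remainders spread one per
  fold.
- **Moran's *I*** uses unstandardized inverse great-circle distances
  (km, haversine) as weights — the default of the GIS tooling this
  diagnostic emulates — with the normality-assumption variance and a
  two-sided normal p. Coincident sites are capped at a 1-km minimum
  distance with a warning. With such heavy-tailed weights the permutation
  distribution of *I* is noticeably skewed at $n \approx 50$, so the
  normal p agrees with a 999-permutation p *on average* (mean
  $|\Delta p| \approx 0.03$ on null data) but can deviate more on a
  single dataset; the test suite asserts the averaged agreement, and
  analyses for which the distinction matters should prefer the
  permutation route.
- **Ford–Walford** requires the Walford slope $b \in (0,1)$; otherwise
  growth is non-asymptotic and the logarithmic increment trend
  $\Delta L_t = c + d \ln t$ is used as a descriptive fallback, with the
  population flagged growth-uncertain. In the pipeline the per-population
  maximum age is taken as the age at 95% of asymptotic length,
  $\ln(20)/K$ — a deterministic proxy for "the age of the longest shell"
  that does not depend on which individual happened to be sampled.
- **Classification** is inclusive on the cool side
  ($\mathrm{SCI} \le A_3$ viable, $\le A_1$ declining): the printed
  two-decimal boundary pair 28.37/28.38 is a rounding artifact of one
  continuous cut. Area shares weight cells by $\cos(\mathrm{latitude})$
  so they approximate true area fractions on the sphere.
- **Climate input** is a long-format monthly CSV
  (`year, month, lat_center, lon_center, tmean_c`); scenario grids are
  read the same way and matched to mask cells by nearest-neighbour cell
  lookup. NetCDF archives should be exported to this layout first (a
  one-line `xarray`/`cdo` step); the package deliberately contains no
  binary-format reader.

## The synthetic world

`world_spec()` fixes every generator parameter and a single root seed;
identical specs give byte-identical worlds, and the generators restore
the caller's RNG stream. The defaults are the study conditions:

- **Climate**: 0.5° grid, 1901–2013, monthly values from an annual
  sinusoid (amplitude 9 °C, peak July) around a mean that declines
  0.28 °C per degree latitude from 18 °C summer level at 45°N, warms
  0.1 °C/decade, and carries year-level Gaussian noise (sd 0.5 °C)
  shared by the 12 months of a cell-year. Over 45–70°N this yields site
  $\mathrm{MST}_{20}$ spanning roughly 11–18 °C. The sinusoid is anchored
  so the June–August mean equals the closed-form summer level exactly
  when noise is off, which the closed-form tests use.
- **Populations**: 49 recent (collection 1984–2013) and 13 historical
  (1905–1940) samples, one grid cell each. True mean SCI = calibration
  line at the site's $\mathrm{MST}_{20}$ + Normal(0, 1.1²) population
  noise; the 1.1 SCI-unit sd is back-solved so the refitted Pearson *r*
  is near 0.76 at $n = 49$. Shells: length lognormal 80 ± 10 mm (so the
  50-mm filter removes under 0.2%), height = 0.5·L ± 3%, width set from
  the population's true SCI with 5% multiplicative noise — per-shell SCI
  is an unbiased copy of the target. Status labels compare the latent
  mean against the 28.37/30.04 cutoffs. The age-calibration simulator
  uses Normal(0, 29²)-year noise at $n = 30$, back-solved the same way
  for *r* ≈ −0.80.
- **Growth**: for nine populations, five ring series each, at least 16
  rings, $K = -0.02 + 0.008\,\mathrm{MST}_{20}$ (± 0.01) per year —
  about 0.07–0.12 over the climate span — with $L_\infty$ uniform on
  90–140 mm and increment-level measurement noise floored so series stay
  strictly increasing.

What the generator does *not* emulate: real European geography and
coastlines, spatially correlated climate anomalies, within-river
pseudo-replication, allometric drift with age beyond the 50-mm cut,
non-thermal drivers (host-fish availability, eutrophication, water
chemistry), and observation error in field status assessment. Passing
tests therefore demonstrate that the machinery recovers what it assumes —
correct formulas, unbiased fits, calibrated diagnostics, monotone
classification — not that temperature is the sole driver in real rivers.

## Verification scale

The test-suite and acceptance experiments run at the study's own sizes:
500 replicates for parameter recovery of both calibrations ($n = 49$ and
$n = 30$), 200 seeds for the cross-validation battery, 200 replicates for
GLM specificity and Ford–Walford bias, 500 for null calibrations of the
t-test, separate-slopes and correlation procedures, ten 999-permutation
null datasets for the Moran agreement check, and a full synthetic world
(50 × 30 to 50 × 70 cells, 113 years) for the end-to-end warming
direction check. These sizes keep every experiment's Monte-Carlo error
well inside the asserted tolerances.

## Known limitations

- The thermal model is deliberately univariate; it bounds what climate
  alone can explain and will misclassify cells where non-thermal
  limitation dominates (the package exposes, but cannot validate,
  scenario projections).
- A 0.5° cell averages away the cold-stream heterogeneity of mountain
  terrain; anomalous high-altitude samples are expected and are the
  reason the calibration supports explicit exclusion lists alongside
  studentized-residual flagging.
- The monthly degree-day approximation undercounts relative to daily
  data when monthly means straddle the base temperature.
- Maximum-age estimates inherit all Ford–Walford assumptions (stationary
  growth, asymptotic trajectory); the logarithmic fallback is
  descriptive, not mechanistic.
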