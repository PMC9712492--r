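# montaneN

Elevational gradients in the tropical montane forest soil nitrogen
cycle: terrain classification, mixed-effect gradient models, apparent
temperature sensitivity (Q₁₀), and soil N pool upscaling — with a
synthetic-data generator so the whole pipeline runs and is tested
without any external download.

## The science

Surface mineral soils (0–20 cm) along tropical elevational transects
show a steep rise in nitrogen concentration and a fall in δ¹⁵N
(≈ −2 ‰ km⁻¹) with elevation. Because mean annual temperature (MAT)
drops ≈ 5.1 °C km⁻¹, these gradients carry a temperature signal: fitting

    N = a · exp(k · MAT)

and evaluating Q₁₀ = (N₂/N₁)^(10/(MAT₂−MAT₁)) between 10 and 20 °C gives
the apparent multiplicative decline of soil N per 10 °C of warming
(≈ 1.9 for published curve constants |k| = 0.066 °C⁻¹). Low δ¹⁵N at
high elevation indicates weak fractionating (gaseous) N losses and
microbial N limitation; C:N ratios cross the immobilisation threshold
(~20–25) along the same gradient.

The package implements, for samples-by-variables tables (tibbles in,
tibbles out) and lightweight planar rasters:

* **Terrain** — six-tier montane/lowland classification from elevation,
  Horn slope and local elevation range (max − min elevation within a
  5 km radius), plus the humid-forest mask (tree cover > 10 %,
  MAP > 1200 mm).
* **Inference** — `lme4` mixed models of soil responses on elevation or
  climate with transect(-within-region) random intercepts (ML, so AIC
  is comparable), ΔAIC ≤ 2 all-subsets selection, LMG hierarchical
  partitioning, marginal/conditional R², Monte-Carlo 95 % bands, MAE,
  and Welch's t for the montane/lowland pool contrast.
* **Temperature sensitivity** — nonlinear exponential MAT fits and
  `q10()`.
* **Mapping** — coefficient × grid projection, pool conversion
  (%N × bulk density × 0.2 m, kg N m⁻²), regional aggregation in Pg N,
  and `pool ± t*·SE` confidence intervals.
* **Synthetic data** — seeded landscapes and transect tables with the
  mixed-model structure above (16 transects, 3 regions, 0–3660 m,
  lognormal N noise, random transect intercepts).

Fitted objects support `tidy()`, `glance()` and `autoplot()`.

## Worked example

```r
library(montaneN)

cfg <- synth_config(seed = 1, samples_per_transect = 50)
samples <- filter_samples(gen_transects(cfg), quiet = TRUE)

fit <- fit_gradient_model(samples, "d15n_permil")
fit
#> <gradient_fit> d15n_permil ~ elev_km, n = 800
#>   AIC 1241.49 | R2m 0.838 | R2c 0.924 | resid var 0.2517
tidy(fit)
#> # A tibble: 2 × 4
#>   term        estimate std.error statistic
#>   <chr>          <dbl>     <dbl>     <dbl>
#> 1 (Intercept)     7.93    0.147       53.8
#> 2 elev_km        -1.97    0.0232     -85.2
```

The fixed elevational slope (−1.97 ± 0.02 ‰ km⁻¹) recovers the
generating −2 ‰ km⁻¹; the conditional R² (0.92) exceeds the marginal
(0.84) by the share of variance absorbed by transect intercepts.

```r
ef <- fit_exponential(samples$mat_c, samples$n_pct)
q10(ef)
#> [1] 1.449814
```

A single raw-scale exponential fit under lognormal noise is wide
(sampling SD ≈ 0.35 at this size, and pooling across transects slightly
attenuates |k|); averaged over replicate datasets the estimate sits at
≈ 1.9–2.0, the published regime. The full pipeline — simulate, filter,
classify, fit, Q₁₀, map, pools — runs as:

```r
run_pipeline(cfg, out_dir = "run")   # CSV/ASC/JSON artifacts + manifest
```

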