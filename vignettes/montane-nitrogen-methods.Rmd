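---
title: "Methods: elevational gradients in tropical montane forest soil nitrogen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: elevational gradients in tropical montane forest soil nitrogen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(montaneN)
```

## The scientific problem

Tropical mountains compress latitudinal climate variation into a few
kilometres of relief: mean annual temperature (MAT) falls roughly 5.1 °C
for every kilometre of elevation, while precipitation shows no coherent
elevational trend in the humid tropics. Surface mineral soils along these
gradients record the imprint of microbial nitrogen cycling: soil N
concentration rises steeply with elevation while its stable isotope ratio
(δ¹⁵N) falls by about 2 ‰ km⁻¹, a signature of weaker fractionating
(chiefly gaseous) N losses and slower microbial N processing in cooler
montane soils. montaneN packages that analysis end to end:

1. **Terrain**: classify montane versus lowland terrain from a DEM using
   slope and local elevation range (LER), and mask humid tropical forest.
2. **Inference**: fit linear mixed-effect models of soil responses
   (log %N, C:N, δ¹⁵N) against elevation and climate, with transect
   identity (optionally nested within region) as a random intercept;
   select models by ΔAIC; decompose explained variance by hierarchical
   partitioning; put Monte-Carlo confidence bands around fitted
   gradients.
3. **Temperature sensitivity**: fit `response = a·exp(k·MAT)` and derive
   the apparent Q₁₀, the multiplicative decline of soil N per 10 °C.
4. **Mapping**: project fitted coefficients over gridded predictors,
   convert N concentration to areal pools (%N × bulk density × 0.2 m),
   aggregate by region × terrain class in Pg N, and attach t-based 95 %
   confidence intervals (`pool ± t*·SE`).

Because the original gridded inputs (a global ~1 km DEM, tree cover,
modelled bulk density) and the compiled transect tables are external
data products, the package carries a synthetic-data module that emulates
the statistical structure of the study system, so every stage is
exercised and tested without any download.

## The synthetic study system

`synth_config()` fixes the generator. Defaults were chosen once to match
the study conditions and are not tuned thereafter:

* 16 transects across 3 tropical regions, 11 samples per transect
  (≈176 observations, the scale of the compiled N dataset), elevations
  spanning 0–3660 m;
* MAT = 26 °C at sea level minus 5.1 °C km⁻¹ — the lapse is exact in the
  generator, so the MAT grid is a deterministic function of the DEM;
* δ¹⁵N = 8 ‰ at sea level, slope −2 ‰ km⁻¹ (range ≈ 0.7–8 ‰ plus noise,
  matching the observed −0.3 to 10.1 ‰ span);
* log %N = log(0.3) at sea level, slope +0.34 km⁻¹. The N slope is
  0.066 °C⁻¹ × 5.1 °C km⁻¹, i.e. the generator operates in the published
  temperature-sensitivity regime (Q₁₀ ≈ e^0.66 ≈ 1.9);
* per-transect random intercepts (σ = 0.5) and residual noise (σ = 0.5),
  drawn independently for the two responses. The source study reports no
  variance magnitudes, so these are free parameters of the emulation:
  0.5 log-units of lognormal spread for %N (geometric σ ≈ 1.6–2,
  consistent with the reported geometric σ ≈ 2 of pool data) and 0.5 ‰
  at the transect level for δ¹⁵N;
* N is generated on the log scale (lognormal noise, always positive);
  δ¹⁵N on the raw scale (it can be negative). C:N rises from ~12 at sea
  level by 6 km⁻¹ so the gradient crosses the microbial
  immobilisation threshold (C:N ≈ 20–25);
* rasters: a smoothed random DEM spanning the elevation range, MAP drawn
  independently of elevation in 1200–8000 mm, tree cover in [0, 100] %,
  bulk density declining mildly with elevation from ~1.2 g cm⁻³, and a
  three-region mask.

What the generator does **not** emulate: real spatial covariance of
tropical climate, cloud forests, disturbance, organic horizons, or
correlated transect intercepts across responses (the cross-response
correlation is zero by default). Passing tests therefore demonstrate
that the estimators recover known structure under the stated noise
model — not that the published field estimates are correct.

## Terrain classification choices

The six-tier rule set is applied with strict (`>`) comparisons exactly
as stated: montane is elevation > 2500 m; 1500–2499 m with slope > 2°;
1000–1499 m with slope > 5° or LER > 300 m; 300–999 m with LER > 300 m;
everything below 300 m is lowland. Elevation bands are applied to real
values as [300, 1000), [1000, 1500), [1500, 2500). Two consequences are
worth knowing:

* a cell at exactly 2500 m belongs to no montane rule (the band is
  half-open and the top rule strict), a single-point gap of the boundary
  convention;
* the rules are not elevation-monotone for gentle, high-relief cells
  (slope ≤ 2°, LER > 300 m): such a cell is montane at 300–1499 m but
  lowland at 1500–2499 m, because only slope qualifies in that band.

Slope uses Horn's 3 × 3 finite-difference operator (the source is silent
on the operator; Horn is the common GIS default) with edge-clamped
neighbourhoods, and a cell is nodata if any neighbour is nodata. LER
takes max − min over all valid cells whose centre lies within the 5 km
radius (planar centre-to-centre distance on the projected grid;
geodesic windows are out of scope at 1 km resolution). Both are
cross-checked cell-for-cell against independent brute-force evaluators
in the test suite.

## Mixed-model choices

* **Maximum likelihood, not REML**, so AIC is comparable across fixed
  structures during all-subsets selection.
* **Grouping**: the default is transect nested within region
  (`(1 | region/transect_id)`); a single transect-level intercept is
  available via `grouping = "transect_id"`, since both framings are in
  common use for this design. With fewer than two groups the model
  collapses to OLS with a message — this keeps the noise-free
  single-transect limit (an exact line) inside the same interface.
* **Singular fits** (zero estimated group variance) are returned with a
  flag, not an error: they are the correct answer when the generator's
  among-transect variance is zero.
* **R²**: marginal and conditional R² are the variance-ratio
  definitions — fixed-effect prediction variance, and fixed plus summed
  random-intercept variance, each over the total including residual
  variance. `r2_conditional ≥ r2_marginal` holds on every fit.
* **Internal standardization**: numeric fixed predictors are centred
  and scaled before optimisation, and coefficients (with their
  covariance) are mapped back to the raw scale by the exact affine
  transform. This is a pure reparametrization — the ML optimum is
  unchanged — but it conditions the optimiser when predictors live on
  very different scales (MAP in mm versus elevation in km), and it makes
  a product interaction the product of centred mains, decorrelating it
  from the main effects.
* **Elevation is expressed per km** (`elev_km`) inside models, so slopes
  are read directly in ‰ km⁻¹ or Δlog(%N) km⁻¹.
* **Selection** fits every candidate subset obeying marginality, ranks
  by AIC, and returns the most parsimonious model within ΔAIC ≤ 2 of
  the best (ties broken by lower AIC).
* **Hierarchical partitioning** (LMG) averages each predictor's
  incremental R² over all orderings of entry, computed by OLS on the
  fixed-effect design — i.e. marginalizing over random effects, which is
  how the partitioning packages used in this literature operate. Shares
  are reported as fractions of the full model's explained variance.
* **Monte-Carlo bands** simulate Gaussian error with the fitted residual
  SD around the population-level mean response, 1000 times by default,
  and take the inner 95 % per grid point. This is the literal reading of
  the published procedure: fixed-coefficient uncertainty is *not*
  resampled, so the band is a prediction-style band around the mean
  curve, and its nominal coverage of the true mean curve in simulations
  is accordingly high.

## Temperature sensitivity

The exponential model is implemented as `a·exp(k·MAT)` with `k` free in
sign. The published curve constants are typeset as a power law
(`(3.158)^{0.066·MAT}`), which as printed would give Q₁₀ = 3.158^0.66 ≈
2.14 rather than the reported ~1.9; the operative reading
`a·exp(−0.066·MAT)` gives exp(0.66) ≈ 1.935, which matches. The package
implements the exponential reading and `q10()` returns the
larger-over-smaller ratio of curve values raised to `10/(MAT₂ − MAT₁)`
— i.e. `exp(|k|·10)`, invariant to the reference pair, ≥ 1 with
equality iff `k = 0`. Defaults are MAT₁ = 10 °C, MAT₂ = 20 °C. No Q₁₀
is computed for δ¹⁵N (it is not proportional, so a multiplicative
sensitivity is not meaningful).

The optimiser starts from the log-linear regression solution; on
failure it restarts from a perturbed grid and finally falls back to
Levenberg–Marquardt. Two numerical guards matter in the degenerate
limits: the convergence test uses a `scaleOffset` so zero-residual
(noise-free) data converge, and a vanishing log-linear slope is snapped
to exactly zero because `nls`'s relative-step numeric derivative
degenerates at ~1e-18.

## Mapping and uncertainty

Grid prediction multiplies fixed coefficients with predictor layers
(random effects at zero — population-level maps). Log-scale fits are
back-transformed by plain exponentiation; a lognormal smearing
correction (`× exp(σ²/2)`) is available but off by default, matching
the direct coefficient-times-grid description of the source procedure.
Pools are `%N/100 × bulk density (kg m⁻³) × 0.2 m` in kg N m⁻²; zonal
totals multiply by cell area (constant per grid on these planar
synthetic landscapes; latitude-dependent areas are out of scope) and
convert to Pg. Stratum totals are exactly additive by construction.
Where per-cell prediction SEs are supplied, stratum SEs aggregate under
independence (`sqrt(Σ(se·area)²)`) — the source's exact aggregation rule
is unstated, so this documented choice brackets the uncorrelated case —
and 95 % bounds are `pool ± t*·SE` with `t*` the 97.5th t percentile at
the model degrees of freedom.

## Problem sizes

The shipped tests and the acceptance script run entirely on synthetic
data at desk scale, chosen as the smallest sizes at which the
statistical checks are sharp: 100 random 50 × 50 DEMs for the
brute-force terrain equivalence; 200 replicates of 16 transects × 50
samples (n = 800) for slope recovery and band coverage; 30 replicates
for the Q₁₀ refit (a single raw-scale exponential fit under lognormal
noise has a sampling SD of ~0.7, so the replicate mean is reported);
and a 30 × 45 cell landscape for the end-to-end pipeline. The published
map-scale quantities (montane share of tropical land area, the 10.1 Pg
global pool, the t(53.5) = 4.73 contrast) depend on external global
rasters and the compiled field dataset, and are deliberately not
reproduced; the package instead verifies the machinery that produced
them — rule equivalence, conservation, additivity, parameter recovery,
coverage, and the printed worked examples (Q₁₀ from the published
constants; the regional pool table summing to its printed global
totals).

## A worked run

```{r, eval = FALSE}
library(montaneN)

cfg <- synth_config(seed = 1)
land <- gen_landscape(cfg)
samples <- gen_transects(cfg, land) |> filter_samples()

fit <- fit_gradient_model(samples, "d15n_permil")
tidy(fit)      # elevational slope near -2 permil/km
glance(fit)    # AIC, marginal/conditional R2

q10(fit_exponential(samples$mat_c, samples$n_pct))

run_pipeline(cfg, out_dir = "run")   # writes rasters, fits, pools, manifest
```

## Known limitations

* The raster container is planar and in-memory; there is no
  reprojection, geodesic windowing, or latitude-dependent cell area.
* Only Gaussian linear mixed models with random intercepts are fitted —
  no random slopes, non-Gaussian families, or spatial error structures.
* The Monte-Carlo band deliberately omits fixed-coefficient uncertainty
  (see above); it is not a confidence band for the mean curve.
* The SOC > 18 % exclusion is a sensitivity mode, not a default, and
  the organic-horizon flag can only be as good as its source labels.
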