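# geotriad

Three-perspective spatiotemporal evaluation of areal healthcare-resource
panels: **inequality** (spatial Gini decomposition), **hotspots**
(emerging hot/cold spot classification from Getis-Ord Gi\* statistics),
and **determinants** (a Bayesian spatiotemporally varying coefficients
model with spatiotemporal variance partitioning).

## Who this is for

Health-services and spatial-epidemiology researchers working with
balanced small-area panels — e.g. a resource count (hospital beds)
observed for N counties over T years, with a province partition, a
contiguity structure, population, land area, and candidate socioeconomic
and environmental covariates. Real panels of this kind are often not
redistributable, so the package includes a seedable synthetic generator
with the exact statistical structure the analysis assumes, making every
stage reproducible and testable without external data.

## The methods in brief

**Response.** Analyses run on raw counts or on the health resource
density index, `HRDI = sqrt((y/(P/1000)) * (y/A))` — the geometric mean
of the resource per 1000 population and per km².

**Spatial Gini.** Within each region, with binary contiguity weights
`w_ij`,

    G = Σ_i Σ_j w_ij |y_i − y_j| / (2 n² ȳ)  +  Σ_i Σ_j (1 − w_ij) |y_i − y_j| / (2 n² ȳ)

splits the classical Gini exactly into neighbor and non-neighbor
components, per region-year; per-region temporal trends are tested with
Mann-Kendall + Theil-Sen.

**Emerging hotspots.** Per-year self-inclusive Gi\* z-scores under
binary contiguity; each area's significance series is classified by
trend-aware rules into new / consecutive / intensifying / persistent /
diminishing / sporadic / oscillating / historical hot or cold spots, or
no pattern.

**STVC + STVPI.** The determinants model, fit by blocked Gibbs sampling
with compiled conditional draws,

    log y_it = Σ_k (β_k + μ_ik + γ_tk) X_itk + ε_it

places an intrinsic CAR prior on each space-coefficient field `μ_·k`, an
RW2 prior on each time-coefficient path `γ_·k` (both sum-to-zero), flat
priors on the global levels `β_k`, and inverse-gamma priors on the
variances. The spatiotemporal variance partitioning index attributes
explainable variation per posterior draw on the SD scale:

    ρ_k = 100 · (σ_μk + σ_γk) / (Σ_k (σ_μk + σ_γk) + σ_ε)

with per-factor space/time splits, socioeconomic/environmental group
shares, space-vs-time scale shares, and model-vs-residual shares, each
with 95% credible intervals.

## Worked example

```r
library(geotriad)

# a 15x15 county lattice, 9 provinces, 10 years, 3 covariates
cfg <- sim_config(grid_rows = 15, grid_cols = 15, T = 10, K = 3,
                  sd_mu = 0.5, sd_gamma = 0.3, sd_eps = 0.2,
                  region_blocks = 3, seed = 42)
sim <- simulate_panel(cfg)

# inequality: per-province-year decomposition + trends
g <- gini_by_region_year(sim$panel, sim$weights)
head(g, 3)
#>   region year  neighbor nonneighbor     total neighbor_share_pct n_areas
#> 1    R11    1 0.1599775   0.7999870 0.9599645           16.66494      25
#> 2    R11    2 0.1582451   0.7989412 0.9571863           16.53232      25
#> 3    R11    3 0.1094909   0.7587476 0.8682385           12.61070      25

# hotspots: Gi* cube -> per-area emerging pattern
cube <- gi_star_cube(sim$panel, sim$weights)
cls <- classify_emerging_pattern(cube)
table(cls$category)
#>      new hot   no pattern sporadic hot
#>            2          222            1

# determinants: STVC fit (4 chains x 5000 iterations) + variance partition
fit <- stvc(sim$panel, sim$weights, seed = 42)
print(fit)
#> Bayesian STVC model fit (blocked Gibbs)
#>   225 areas x 10 years, 3 covariate(s): X1, X2, X3
#>   4 chains x 5000 iterations (burn-in 2000, thin 3): 4000 draws
#>   converged: TRUE (max variance R-hat 1.001)
#>   global coefficients (posterior mean):
#>     X1     X2     X3
#> 0.9932 1.0034 1.0084

vp <- stvpi(fit)
print(vp)
#> Spatiotemporal variance partitioning (posterior mean %, 95% CI):
#>   model 91.78% [90.96, 92.69] | residual 8.22% [7.31, 9.04]
#>   space 58.73% | time 33.05%
#>   per-factor shares:
#>   name share lower upper
#> 1   X1 34.15 29.63 39.55
#> 2   X2 28.81 24.41 34.42
#> 3   X3 28.81 24.76 33.29

rank_determinants(vp, cumulative_threshold = 84)
#>   name    share    lower    upper space_share time_share cumulative
#> 1   X1 34.15290 29.62552 39.55198    21.28056  12.872339   34.15290
#> 2   X3 28.81280 24.76096 33.29312    20.50034   8.312457   62.96569
#> 3   X2 28.81177 24.40691 34.41592    16.94846  11.863306   91.77746
```

The Gini rows say province R11's inequality is ~0.96 on this draw and
about a sixth of it sits between adjacent county pairs. The fit recovers the generative global
coefficients (all 1 by construction); `stvpi()` reports how the
explainable variation splits across the three covariates and the space
and time scales (the generative split here is 57.7% space / 34.6% time /
7.7% residual). The whole pipeline — simulate, screen, Gini, hotspots,
STVC, STVPI, with artifacts and a manifest — runs as one call via
`run_pipeline()`.

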