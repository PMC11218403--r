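---
title: "Methods: spatiotemporal inequality, hotspots, and determinants for areal resource panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatiotemporal inequality, hotspots, and determinants for areal resource panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope

`geotriad` evaluates a balanced areal panel of a healthcare resource (the
motivating case is county-level hospital beds observed yearly) from three
complementary perspectives:

1. **Inequality** — how unevenly the resource is distributed within each
   region (province), split into the part attributable to neighboring
   area pairs and to non-neighboring pairs, and how that inequality trends
   over time.
2. **Hotspots** — which areas form statistically significant high- or
   low-value clusters, and how each area's cluster membership evolves
   (new, consecutive, intensifying, persistent, diminishing, sporadic,
   oscillating, historical; hot and cold variants).
3. **Determinants** — which covariates drive the resource, allowing the
   strength of each association to vary over both space and time, and how
   the explainable variation partitions across factors, factor groups,
   and the space versus time scales.

Because real county panels of this kind are typically not redistributable,
the package ships a seedable synthetic generator whose structure is the
exact generative twin of the inference model, so every stage is testable
end to end.

## The response variable

Analyses can run on raw resource counts or on the health resource density
index (HRDI), the geometric mean of the resource per 1000 population and
per km²:

$$\mathrm{HRDI}_{it} = \sqrt{\frac{y_{it}}{P_{it}/1000}\cdot\frac{y_{it}}{A_i}}.$$

The index is scale-consistent (doubling beds doubles the index) and avoids
privileging either the demographic or the geographic denominator.
`compute_hrdi()` applies it cell-wise; `panel_with_hrdi()` converts a
count panel in place. The default pipeline operates on the HRDI response;
raw counts are accepted by simply not converting.

## Spatial Gini decomposition

For areas within one region with values $y_1,\dots,y_n$ and binary
contiguity weights $w_{ij}$ (1 when two areas share a border),

$$G = \underbrace{\frac{\sum_i\sum_j w_{ij}\lvert y_i-y_j\rvert}{2n^2\bar y}}_{\text{neighbor}}
  + \underbrace{\frac{\sum_i\sum_j (1-w_{ij})\lvert y_i-y_j\rvert}{2n^2\bar y}}_{\text{non-neighbor}}.$$

The two components add exactly to the classical Gini coefficient — this
identity is enforced to $10^{-12}$ in the test suite. The sums run over
ordered pairs including $i=j$, whose terms are identically zero, so this
is bit-equivalent to excluding them. Decompositions are computed within
each region using only within-region adjacency (cross-region borders are
ignored), one per region-year; singleton regions cannot carry a Gini and
are skipped with a warning.

A large neighbor share signals that much of the inequality sits between
adjacent areas, i.e. spatial autocorrelation in the disparity itself. The
share is reported without a significance test; we know of no standard
reference distribution for it and do not invent one.

**Temporal trend.** Per-region yearly Gini series are tested with the
Mann-Kendall statistic plus a Theil-Sen slope at $\alpha = 0.05$. The
sources describing this style of analysis typically report "significant
decrease" without naming a test; we chose Mann-Kendall/Theil-Sen because
it is nonparametric, robust for short annual series, and consistent with
the trend machinery the hotspot stage already needs. A verdict is
`decreasing`/`increasing` only when the Mann-Kendall p-value is below
$\alpha$ and the slope sign agrees; otherwise `none`.

## Emerging hot/cold spots

Each year is scored with the self-inclusive Getis-Ord statistic under
binary contiguity. With star set $J(i)$ = area $i$ plus its neighbors,
global mean $\bar y$ and population SD $s$ over all $n$ areas,

$$z_i = \frac{\sum_{j\in J(i)} y_j - \bar y\,\lvert J\rvert}
             {s\sqrt{\left(n\lvert J\rvert - \lvert J\rvert^2\right)/(n-1)}}.$$

Two conventions are worth making explicit. First, the neighborhood is the
contiguity star rather than a fixed-distance band: the surrounding
analyses all use contiguity, and the statistic is written for generic
binary weights. Second, a constant field has $s = 0$ and no meaningful
z-score; we define $z \equiv 0$ there and warn, rather than failing.

`gi_star_cube()` scores every year independently by default
(`temporal_window = 0`). With `temporal_window = 1` the bin neighborhood
additionally includes the same spatial star in the adjacent years and the
mean/SD are taken over all $N \times T$ bins, mirroring space-time-cube
tools; both variants are checked against brute-force transcriptions of
the defining sums.

**Classification.** Each area's yearly significance series (hot:
$z \ge 1.96$; cold: $z \le -1.96$ at the default $\alpha = 0.05$) is
classified by the first matching rule, with `persistence_frac = 0.9`
encoding "at least 9 of 10 years" generically and `recency = 1` defining
"the last year":

1. *new* — significant only in the final step(s);
2. *consecutive* — one unbroken run ending at the final step, covering
   under 90% of steps, nothing before;
3. *intensifying* — present in ≥ 90% of steps, final step included, with
   a significantly strengthening Mann-Kendall trend in the z-series;
4. *persistent* — present in ≥ 90% of steps, no significant trend;
5. *diminishing* — present in ≥ 90% of steps, significantly weakening;
6. *sporadic* — final step significant, earlier gapped occurrences, never
   the opposite sign;
7. *oscillating* — final step significant with at least one earlier
   opposite-sign step;
8. *historical* — not significant in the final step despite ≥ 90%
   earlier presence.

Cold categories use the same rules with roles swapped; a *strengthening*
cold trend is a significantly decreasing z. The precedence resolves every
overlap deterministically — e.g. a 10/10-hot area with a rising trend is
*intensifying*, not *consecutive*; and a 9-of-9-earlier-years area that
just turned off is *persistent* (rule 4 precedes rule 8) unless a
significant trend pushes it past rules 3–5 to *historical*. No
multiple-testing correction is applied across areas by default (a
Benjamini-Hochberg flag would be a natural extension); the per-year
z-cutoffs follow the conventional 90/95/99% bins for reporting, with only
the 95% level driving classification.

## The STVC model

The determinants stage fits, by blocked Gibbs sampling,

$$\log y_{it} = \sum_{k=1}^{K} (\beta_k + \mu_{ik} + \gamma_{tk})\,X_{itk} + \varepsilon_{it},
\qquad \varepsilon_{it} \sim N(0, \sigma_\varepsilon^2),$$

with an intrinsic CAR (ICAR) prior on each space-coefficient field
$\mu_{\cdot k}$ (each value conditionally normal around its neighbors'
mean with variance $\sigma^2_{\mu k}/n_{w_i}$), a second-order random
walk (RW2) prior on each time-coefficient path $\gamma_{\cdot k}$ (iid
normal second differences with variance $\sigma^2_{\gamma k}$), and
inverse-gamma(1, 0.01) priors on all variance components (a
sensitivity-style alternative such as (0.5, 0.005) can be passed through
`hyper_a`/`hyper_b`).

**Identifiability.** Both intrinsic priors are improper on a level: the
ICAR null space is the constant field, and the RW2 null space contains
constants and linear trends. We impose sum-to-zero constraints on each
$\mu_{\cdot k}$ and $\gamma_{\cdot k}$ (the RW2 slope is left free —
time-coefficient paths may trend). A formulation with varying
coefficients alone would then force every covariate's *average* effect to
zero, which is not a meaningful model, so a flat-prior global coefficient
$\beta_k$ carries the level: the standard varying-coefficient convention.
Reported space/time coefficients default to the total local effects
$\beta_k + \mu_{ik}$ and $\beta_k + \gamma_{tk}$; the centered components
alone are available with `total = FALSE`.

**Sampling.** Each coefficient block is drawn jointly from its Gaussian
full conditional. Because the likelihood contribution to each block's
precision is a fixed diagonal divided by $\sigma_\varepsilon^2$, we
diagonalize $A^{-1/2} Q A^{-1/2}$ once per fit and every draw thereafter
costs a few dense matrix-vector products; the sum-to-zero constraint is
imposed exactly by conditioning-by-kriging. The inner loop is compiled
(RcppArmadillo) and uses R's RNG, so fits are exactly reproducible from a
seed. Variance components use conjugate inverse-gamma updates with shape
increments $(N-1)/2$ (ICAR rank) and $(T-2)/2$ (RW2 rank). Four chains
from overdispersed starts, 5000 iterations, 2000 burn-in and thinning 3
are the defaults; split-R-hat and effective sample sizes are reported for
every scalar parameter, and a fit is flagged non-converged (returned, not
discarded) when any variance component's R-hat exceeds 1.1.

**Covariate handling.** Covariates are standardized to mean 0, SD 1 by
default so coefficient scales — and hence variance-partitioning shares —
are comparable across factors; constant columns (an explicit intercept)
are left untouched, and the centering/scale is recorded in the fit.
Screening for multicollinearity uses the variance inflation factor with
the conventional threshold of 5, dropping the worst column one at a time
and recomputing (single-pass screening can over-drop once a collinear
partner is removed); ties go to the later-listed column. Whether to
screen on raw or standardized covariates is a genuine free choice — VIFs
are invariant to affine rescaling, so the flag exists only for workflow
symmetry. The response must be strictly positive for the log link; zero
cells are a hard error with advice to floor or exclude upstream, never a
silent jitter.

A machine-learning variable-importance pre-ranking (e.g. random-forest
node purity) is deliberately not implemented; the covariate shortlist is
an input.

## Variance partitioning (STVPI)

On the standard-deviation scale, per posterior draw, with
$D = \sum_k(\sigma_{\mu k} + \sigma_{\gamma k}) + \sigma_\varepsilon$:

$$\rho_k = 100\,\frac{\sigma_{\mu k} + \sigma_{\gamma k}}{D},\qquad
\text{space}_k = 100\,\frac{\sigma_{\mu k}}{D},\qquad
\text{time}_k = 100\,\frac{\sigma_{\gamma k}}{D}.$$

Group shares (socioeconomic vs environmental) sum $\rho_k$ over the
group; scale shares sum the per-factor space and time shares; the model
share is $100$ minus the residual share. Shares are computed **per draw**
and then summarized (posterior means, 2.5/97.5% bounds), so the credible
intervals inherit the joint posterior dependence of the components —
plugging posterior-mean SDs into the formula would understate that
uncertainty. Per draw the identities
$\sum_k \rho_k + \text{residual} = 100$ and
$\text{space} + \text{time} + \text{residual} = 100$ hold exactly.
When global coefficients are enabled they contribute to neither numerator
nor denominator — the partition is over the stochastic components only —
which is a documented limitation of the index. `rank_determinants()`
returns the shortest prefix of factors (by posterior-mean share) whose
cumulative share reaches a threshold (default 84%).

## The synthetic generator

`simulate_panel()` draws, in order: a rook/queen lattice with a
contiguous block partition into regions (mimicking provinces containing
many counties); covariates (iid normal, or spatially smoothed over the
contiguity star with an AR(1) blend across years), standardized after
generation; ICAR fields $\mu_{\cdot k}$ sampled on the positive
eigenspace of $D - W$ (so the constraint holds by construction and the
covariance is exactly $\sigma_\mu^2 (D-W)^+$ — the generative model is
the exact twin of the prior, with no diagonal jitter); RW2 paths by
accumulating iid second differences, centered; and iid residuals. The
response is $\exp$ of the linear predictor, population and land area are
log-normal, and a raw beds column is back-solved so `compute_hrdi()`
reproduces the response exactly.

Default generative SDs ($\sigma_\mu = 0.5$, $\sigma_\gamma = 0.3$,
$\sigma_\varepsilon = 0.2$) put roughly comparable energy in the spatial,
temporal and noise channels of a log-scale response — spatial
heterogeneity somewhat dominant, as areal resource data usually show.
What the generator does **not** emulate: irregular county geometries and
their very uneven neighbor counts, covariate collinearity structured like
real socioeconomic indicators, measurement error in denominators, or
zero-count cells. Passing recovery tests therefore demonstrates the
correctness of the machinery under the model's own assumptions, not
robustness to real-data pathologies.

`simulate_hotspot_panel()` is a separate deterministic preset (14×14
lattice, 10 years): a 3×3 block whose intensity rises linearly
(*intensifying hot*), a block high only in the final year (*new hot*), a
block low from year 4 onward (*consecutive cold*), and a unit-SD
background that stays non-significant. Block values were designed against
the classifier's published rule definitions so that every block cell
lands in its intended category and every background cell is "no pattern";
the test suite asserts exactly that.

## Problem sizes and numerical choices

The validation suite uses a 15×15 lattice over 10 years with K = 3
covariates for parameter-recovery and variance-partitioning checks (50
replications; posterior-median field correlations ≥ 0.8 spatial / ≥ 0.9
temporal, 95%-interval coverage of the variance components ≥ 80%), a
3×3 × 5-year instance for validating the sampler against the exact dense
Gaussian posterior with variances held fixed, and thousands of small
random instances for the exact Gini, Gi*, and Mann-Kendall identities.
These sizes were chosen to make the checks sharp while keeping a full run
of the suite comfortable on a laptop.

Degenerate-input conventions collected in one place: constant Gi* field →
all z = 0 with a warning; all-tied Mann-Kendall series → S = 0, z = 0,
p = 1 (tie-corrected variance otherwise, with the ±1 continuity
correction); constant Gini values → all components 0; all-zero values →
error (the mean normalization is undefined); singleton Gini region →
skipped with a warning; disconnected weights graph → error naming the
component count (both the ICAR simulator and the STVC model require
connectivity); simulated response overflowing `exp()` → error advising
smaller SDs.

One reparameterization caveat: with covariates standardized versus raw,
fitted values agree only up to Monte-Carlo error (the two chains traverse
different parameterizations), and exact agreement additionally requires
mean-zero covariates, since without an intercept term centering a
covariate genuinely changes the model space. The test suite checks this
identity at Monte-Carlo tolerance on a mean-zero noiseless fixture.

## Known limitations

- Gaussian likelihood on the log scale only; no Poisson/negative-binomial
  option and no zero-inflation handling.
- No space-time interaction random effects; the STVPI partition has no
  coupling term to attribute.
- The spatial Gini inference is descriptive; no permutation inference for
  the neighbor share.
- The hotspot taxonomy implements the eight trend-aware categories above,
  not the full 17-category space-time-cube taxonomy of GIS tools.
- Convergence flagging relies on split-R-hat of scalar parameters; field
  values are not individually monitored.
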