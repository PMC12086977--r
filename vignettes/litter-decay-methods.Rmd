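---
title: "Models and methods for litterbag decay analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for litterbag decay analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litterdecay)
```

## The decay model

Litter mass loss is modelled as a single exponential pool (Olson's model),
linearized for estimation:

$$\ln M_t = \ln M_0 - k\,t,$$

where $M_t$ is the percent of initial dry mass remaining at time $t$ (years),
$M_0 = 100\%$, and $k$ (year$^{-1}$) is the decay constant. Percentages are
carried on the 0–100 scale so the regression intercept sits near
$\ln 100 \approx 4.605$. Two estimators are provided:

* `instantaneous_k()` — the per-bag rate
  $(\ln \text{remaining\%} - \ln 100)/\text{year-fraction}$, exact for one bag
  at one removal. For mixed bags, `per_species_mixed_k()` applies the same
  formula to each 1.5 g component.
* `fit_multigroup()` — one regression over all bags, with a *single shared
  intercept* and one slope per treatment cell. The shared intercept encodes
  the design fact that every bag starts at 100%: cell-specific intercepts are
  deliberately not offered. Slopes are stored with the negative mass-loss
  sign; `slope_magnitudes()` serves ratio arithmetic.

The 12 treatment cells cross beech-sapling proliferation (Yes/No), rainfall
exclusion (Yes/No) and litter species (maple, beech, 50:50 mixed), in a fixed
canonical order (`treatment_cells()`): proliferation varies slowest, species
fastest, Yes before No. All modules use this ordering.

Estimation is ordinary least squares. Inference with flat priors on the
coefficients coincides numerically with OLS t-intervals, so a separate
Bayesian fit is not provided. Single-pool exponential decay is a deliberate
simplification: multi-pool and Weibull formulations are out of scope.

### Interval estimation

Intervals default to heteroscedasticity-robust (HC3) t-intervals rather than
pooled OLS intervals (`se_type = "classical"` restores the latter). The
reason is structural: on the ln scale, between-bag variance grows with
elapsed time and differs strongly between moisture regimes — litter that has
barely decayed *cannot* vary much, because percent remaining is bounded above
by 100. A pooled residual variance therefore overstates the precision of
fast-decaying (rainfall-accessible) cells and understates that of
slow-decaying (excluder) cells. With HC3 intervals, simulation (see the test
suite) puts per-slope 95% interval coverage at roughly its nominal level
across all 12 cells; with pooled intervals the rainfall cells undercover.

### Physiological time

`accumulate_gdd()` converts a sub-daily soil-temperature log into growing
degree-days: the daily contribution is $\max(0, \bar{T}_\text{day} - 5)$
(base 5 °C on the *daily mean*, the standard base-threshold formulation;
sub-daily excursions above the base on cold days do not count). Days with
logging gaps are excluded with a warning. Passing `time_basis = "gdd"` to the
fit replaces year-fractions with cumulative degree-days at each removal; at
constant temperature this is an exact rescaling of the slopes by
1/(degree-days per year).

## Mixture additivity

Additivity means the mixed-litter rate equals the mean of the monospecific
rates, $k_\text{exp} = (k_\text{maple} + k_\text{beech})/2$. Departures are
summarized two ways:

* the standardized difference $(k_\text{obs} - k_\text{exp})/k_\text{exp}$,
  a signed fraction (positive = faster-than-expected loss for negative
  rates), and
* a z-score $z = (k_\text{obs} - k_\text{exp}) / \sqrt{v_\text{obs} +
  v_\text{exp}}$ with $v_\text{exp} = (v_\text{maple} + v_\text{beech})/4$.

The field literature sometimes phrases this test as "squared mean differences
divided by pooled variances", which is ambiguous about both the squaring and
the variance source. We implement the standard two-quantity z with
independent variances — which reproduces the magnitudes such tests report —
and expose the squared variant as `z_squared`. Whether the variances come
from cell means or slope estimates is equally unstated in that phrasing;
`test_additivity()` uses the squared standard errors of the fitted slopes,
the natural choice when the rates themselves come from the multigroup
regression. The critical value defaults to 1.96 (two-sided 5%) and is
configurable. Verdicts: `additive` if $|z|$ is below the critical value,
otherwise `synergistic` when the observed magnitude exceeds the expected one
and `antagonistic` otherwise. Interval-containment checks
(`interval_containment()`) treat intervals as closed.

## Rank concordance

`kendalls_w()` ranks items within blocks with mid-ranks for ties and applies

$$W = \frac{12 S}{m^2(n^3 - n) - m\sum T},$$

with the tie term $T = \sum (t^3 - t)$ on by default (tie handling in the
field literature is usually unstated; mid-ranks plus correction is the
textbook treatment). The chi-square approximation $m(n-1)W$ on $n-1$ df is
reported; exact permutation p-values for W are out of scope. If every block
is completely tied the statistic carries no ordering information and W is
defined as 0. Ranking direction defaults to ascending (fastest decay — most
negative $k$, lowest mass remaining — ranks first) and is recorded in the
output; W itself is direction-invariant. `spearman_rho()` is the Pearson
correlation of mid-ranks and refuses constant vectors.

## Environmental summaries

* `grid_summary()`: mean, sample SD ($n-1$) and CV% $= 100\,s/\bar{x}$ of a
  moisture grid; CV% is scale-invariant.
* `weighted_shade_tolerance()`: basal-area-weighted mean of ordinal shade
  ratings (1 = most tolerant), bounded by the ratings present.
* `clr_transform()`: centered log-ratio for compositional data (texture
  fractions); outputs sum to zero; zero parts are rejected rather than
  replaced.
* `permutation_group_test()`: one-way PERMANOVA on Euclidean distances with
  the add-one p-value convention $(\#\{F^* \ge F\} + 1)/(B + 1)$. In the
  univariate case the pseudo-F *equals* the classical one-way ANOVA F.
  Two-way designs are handled by testing each factor with the other pooled;
  this ignores interactions and is documented as a limitation (the
  experimental questions here are one-way).
* `moisture_delta()`: SWC change scaled to a 30-day month.

## The synthetic generator

`generate_bags()` inverts the fitted model: for each bag,
$\text{percent} = \exp(\ln 100 - |k|\,m\,t + \varepsilon)$ with $m$ an
optional mesh modifier. Its defaults *are* the study conditions the package
is built around: 3 species × 3 meshes × 2 exclusion plots × 2 replicates ×
2 proliferation levels × 3 sites × 3 removals (30/60/90 d) = 648 bags;
ln-noise SD 0.1 (consistent with the ~0.015–0.019 standard errors of 90-day
remaining-mass proportions at n ≈ 18 in such experiments); mesh modifiers of
1 (no consistent mesh effect was observed in the field); and
`site_dropout = "site3"` available to emulate the loss of one
beech-proliferated site (540 bags). The default slope table uses the six
published rainfall-accessible slopes; for the excluder cells only the
monospecific instantaneous rates (−0.248 maple, −0.307 beech) are published,
so the mixed-cell value (−0.333) was chosen once so that the six excluder
cells average exactly the published excluder-cell mean of −0.296 year$^{-1}$.

### Noise and the no-loss boundary

Noise is additive on the ln scale (multiplicative on mass), matching the
linearized model — the generator is the exact inverse of the estimator, and
a noiseless run reproduces the configured slopes and the $\ln 100$ intercept
to numerical precision. Percent remaining must stay in $(0, 100]$, and *how*
the boundary is enforced matters: censoring draws at 100% (or one-sided
rejection sampling) shifts the ln-scale mean near the boundary, and through
the shared intercept that bias propagates into the fast-cell slopes. We
therefore draw $\varepsilon$ from a Normal(0, sd) *symmetrically truncated*
to $|\varepsilon| \le |k|\,m\,t$, the distance to the boundary. This is
mean-preserving (slope estimates stay unbiased), respects the support, and
has a natural reading: bags that have barely decayed show little between-bag
spread. Its cost is that the effective noise SD shrinks below the nominal
`ln_noise_sd` near the boundary — one reason the robust intervals above are
the default.

Mixed bags are built from two 1.5 g components drawn independently with half
the noise variance each and summed, so component masses add to the bag total
exactly (the validator's tolerance for real data is 0.005 g, reflecting
per-component weighing on an analytical balance). By default both components
decay at the mixed-cell slope, so the bag total follows the configured slope;
`mixture_components = "species"` switches to the additive null (each
component at its monospecific rate) with `mixture_synergy` available to
inflate component rates for power studies. Replicate bags are independent
draws: no replicate-level variance component is modelled, since duplicate
bags are absorbed into the residual in the target analysis.

Moisture grids (`generate_moisture_grid()`) draw node values as means of 3
lognormal readings parameterized so the node-level mean and CV match the
configured exclusion level (defaults: mean 15.57%/CV 24.40% with rainfall,
8.82%/54.10% under excluders — the published plot summaries). The lognormal
is a pragmatic positive-support choice; only mean and CV are specified by
the design. Temperature logs are deterministic (profile plus an optional
sinusoidal diurnal cycle that integrates to zero over each day), since the
GDD computation only consumes daily means.

### What the generator does not emulate

Real litterbag data have spatially correlated micro-site effects, month-to-
month weather in the decay rates, handling and sieving losses, occasional
apparent mass *gain* from contamination, and site-level random effects. The
generator models none of these: bags are conditionally independent given
their cell, and rates are constant in time. Passing tests therefore
demonstrate the estimators' correctness under the stated model, not
robustness to field messiness; the mixed-effects analyses such messiness
calls for are out of scope here.

## Reproducibility and problem sizes

Every stochastic function takes a seed and restores the caller's RNG state;
the pipeline derives deterministic per-stage substreams from one master seed,
so a re-run of a manifest reproduces numeric outputs byte-for-byte. Numeric
outputs are written at full precision; rounding (3 decimals for rates, 1 for
percentages) is applied only in the human-readable summary.

The simulation-based checks use sizes chosen to estimate rates with adequate
Monte-Carlo precision while staying quick on a laptop: 200 replications of
the 540-bag design for interval coverage (binomial SE ≈ 1.5% per cell),
500–1000 replications of a 216-bag design for the additivity type-I rate,
500 random tables for the rank-statistic oracles, and a few hundred
permutation-test null runs at 99 permutations each.

## Known limitations

* Single-pool exponential only; no Weibull or double-exponential fitting.
* One-way PERMANOVA (Euclidean) only; two-way designs are approximated by
  pooling.
* The additivity z construction assumes independent monospecific and mixed
  slope estimates; in the joint regression they share the intercept, so the
  independence is approximate.
* The GDD series uses daily means; sub-daily threshold crossings are ignored.
* No mechanistic soil-moisture or litter-chemistry simulation, and no
  mixed-effects (REML) estimation.
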