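---
title: "Models and methods: genetic correlation across countries and zones"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: genetic correlation across countries and zones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its statistical machinery:
the model family, the covariance structures and their parameterisation, the
REML engine's numerical choices, what the synthetic generator does and does
not emulate, and the open design decisions we had to settle.

## 1. The data and the model family

The unit of analysis is a *trial mean*: the yield (dt/ha) of one variety in
one official trial, i.e. one (genotype, location, year, country) cell.
Replicate-level design information (blocks, incomplete-block recovery) is
assumed to have been absorbed upstream; `metcor` has no plot-level data
model. Official series are balanced *within* years — every variety active
in a year is grown at all of that year's locations — but strongly
unbalanced *across* years, because varieties are tested for only 2–3
consecutive years before withdrawal or registration.

The full trend model for two countries (`catalogue_model("RGC", ...)`) is

$$yield_{ijlk} = \mu + c_l + \beta_1 x_{1jl} + \eta_l x_{1jl}
  + \beta_2 x_{2i} + \beta_3 x_{3i}
  + g(c)_{il} + y(c)_{kl} + gy(c)_{ikl} + s_{jl} + sy_{jlk} + gs_{ijl}
  + e_{ijlk}$$

with Gaussian random terms. The covariates matter for the interpretation
of the genetic correlation:

* `x1` — nitrogen application (kg/ha), mean-centred over the analysis
  records and divided by a `scale` (default 500). The division is pure
  numerics: it keeps random nitrogen-slope variances on the same order as
  the other components, which stabilises the optimizer. We allow `x1` to
  vary by (location, year) by default, with a per-location-mean option
  (`nitrogen_key = "location"`), since the location-specific interpretation
  admits both readings and real networks adjust fertilisation year to year.
* `x2` — the variety's *first trial year*, centred over varieties. Its
  coefficient $\beta_2$ is the **genetic trend**: the yield gain carried by
  newer breeding material. For a variety tested in both countries the first
  trial year is the minimum calendar year over *all* its records — the
  dataset-wide reading of "first trial year of a variety"; a per-country
  first year would make `x2` country-dependent and is not what a
  genetic-gain covariate means.
* `x3` — the calendar year of the record, centred; $\beta_3$ is the
  **non-genetic trend** (agronomy, environment). With random year effects
  in the model, $\beta_3$ is identified only through the prior on those
  effects, so its standard error is intrinsically large in short series.

Centering constants are stored with every covariate set and every fit, so
transformations are invertible and predictions reproducible.

The catalogue mirrors the standard analysis ladder: fixed-genotype models
(`FG`, `FGC`) for per-country BLUEs; random-genotype models (`RG`, `RGC`)
that merge $g_i + (gc)_{il}$ into a composite genotype-within-group effect
`g(c)` and exploit its between-group covariance; and random-coefficient
models (`RC1`–`RC4`) that let genotypes respond to nitrogen with their own
random slopes. The residual is heterogeneous by country/zone and absorbs
the three-way genotype-location-year interaction (at trial-mean level the
two are not separable).

## 2. Covariance structures and the genetic correlation

The genotype-group block can be `CS`, `UN`, `FA1`, `FA0` (reduced-rank
factor analytic), or — in the random-coefficient models — a 2x2
intercept/slope `RC` block per unit, or the Kronecker structure
`Sigma_reg (x) G_c` (`RC4`). `implied_genetic_correlation()` maps each
fitted structure to a between-group correlation matrix; for `CS` this is
$\sigma^2_g/(\sigma^2_g + \sigma^2_{gc})$, for rank-1 `FA0` it is exactly
±1 by construction.

Two identifiability conventions are fixed once:

* **Kronecker scale.** The factorisation `Sigma_reg (x) G_c` is scale
  non-unique; we pin the first diagonal element of `G_c` to 1, leaving
  `Sigma_reg` fully free (3 parameters) and `G_c` with $L-1$ variances and
  the correlations. This is the usual convention for Kronecker covariance
  models and keeps `Sigma_reg` interpretable as the first group's
  intercept/slope covariance.
* **FA sign.** Loadings are reported with the first non-zero loading
  non-negative; the likelihood is invariant to a global sign flip, so this
  is applied only when estimates are extracted.

Random-coefficient blocks are always the *full* 2x2 unstructured
intercept/slope covariance. This is not a modelling taste: only the full
block makes the fit invariant under translation and rescaling of the
covariate, a property the test suite checks by shifting nitrogen by
±100 kg/ha and changing the divisor from 500 to 1000.

The two-term representation `g:ID + gc:ID` and the composite `g(c):CS` are
the same model under the parameter map
$(\sigma^2_g, \sigma^2_{gc}) \mapsto$ CS; the engine keeps both forms
available (the zone variance-component analysis uses the separate form, as
its two variances are the reported quantities) and the test suite verifies
likelihood identity at mapped parameters to 1e-8.

## 3. The REML/ML engine

Estimation maximises the restricted likelihood through Henderson's
mixed-model equations. With $V = \sum_t Z_t G_t Z_t' + R$ and
$C = W'R^{-1}W + \mathrm{blockdiag}(0, G^{-1})$, $W = [X\,Z]$:

$$-2\ell_R = (n-p)\log 2\pi + \log|R| + \log|G| + \log|C| + y'Py,$$

with $y'Py = y'R^{-1}y - r'C^{-1}r$. The constant convention matches
lme4's REML criterion, which the tests verify directly. For full ML with
profiled fixed effects the same quantities are reused with the
random-effect block $C_{uu}$ in place of $C$. Implementation notes:

* All cross-products $W'W$ (one per residual group) are computed once per
  design. Each likelihood evaluation only refills the numeric values of
  $C$ — whose sparsity pattern is fixed — and updates a cached CHOLMOD
  Cholesky factorisation. This is what makes the replicate studies
  affordable on one CPU.
* $G^{-1}$ is assembled block-diagonally per unit; units sharing a
  slot-pattern (e.g. all genotypes observed in both countries) share one
  small matrix inversion per evaluation.
* The optimizer is `nlminb` on a transformed scale: log variances, atanh
  correlations (capped at |0.999|), log-Cholesky for unstructured blocks of
  3+ groups, free loadings with log specific variances for FA. Box bounds
  put every variance at least at the floor `1e-8 * var(y)`.
* Starting values split the response variance equally across the random
  terms plus residual; correlations start at 0.3. Fits with FA or RC
  structures additionally use 3 random restarts (seeded, so deterministic);
  for plain CS/UN/DIAG fits a single start is used — in our testing the
  transformed-scale objective for those fits was unimodal, and restarts
  only added cost. `fit_options(restarts =)` overrides either default.
* `FA0` blocks are singular, which the $G^{-1}$ formulation cannot invert;
  fitting reduced-rank FA therefore pins the FA1 specific variances at the
  variance floor. The materialised `FA0` structure and its ±1 implied
  correlation remain exact; only the fitted likelihood carries the
  numerical floor.
* Convergence is declared on relative change of $-2\ell_R$ (default 1e-8).
  Hitting the iteration cap — including in the full-ML stage — is a
  reported status (`converged`, `ml_converged`), never an exception:
  fixed-genotype models on real series are known to resist full-ML
  convergence, and a comparison pipeline must survive that.
* Parameters within 10x of the variance floor (and correlations at the
  cap) are flagged `bounded`; the non-bounded covariance count reported
  next to the structural count reflects the convention of counting only
  parameters estimated away from the boundary. AICs use the structural
  count: `aic_reml = -2 lR + 2 p_cov`,
  `aic_ml = -2 lML + 2 (p_cov + p_fixed)`.
* Covariance-parameter standard errors come from the observed information
  (numerical Hessian of $\ell_R$) computed on the transformed scale —
  where finite-difference steps cannot leave the parameter space — and
  mapped back by the delta method. SEs are suppressed (NA) for bounded or
  boundary-collapsed components, whose Wald theory breaks down.
* Fixed effects are GLS at the optimum; their covariance is the leading
  $p \times p$ block of $C^{-1}$. Aliased fixed-effect columns are removed
  deterministically by pivoted QR, preferring earlier columns (intercept,
  group, covariates, then genotype dummies with lexicographically first
  reference levels) — so in `FGC`, where `x2` is exactly collinear with
  the fixed genotype effects, the covariate is retained and a genotype
  dummy is dropped, leaving the likelihood untouched.

## 4. The synthetic trial-system generator

The generator is first-class, tested code: it is the only way to validate
the pipeline, since real official series are confidential. It emulates:

* yearly cohorts of new varieties with 1–3-year testing windows; default
  duration probabilities (0.50, 0.225, 0.275) encode the typical attrition
  of official testing — about half withdrawn after year one, a quarter to
   a third reaching year three;
* a shared-variety fraction between two countries, with the second
  country's entry lagged by 0–4 years by default (`shared_entry_lag`), so
  shared varieties have different testing windows per country, as observed
  for common varieties in official lists. Without the lag, identical
  windows confound the genotype-group correlation with the
  genotype-year-group correlation at small scale;
* within-year balance: every active variety appears at every location of
  its country that year; zone systems are single-country networks whose
  locations are stratified into zones, so every variety appears in every
  zone;
* nitrogen per (location, year): location means around 150 kg/ha
  (sd 20) plus yearly noise (sd 10), stationary by default, with an
  optional linear drift — the analysis does not depend on the trajectory;
* all random effects drawn from the configured group-level covariance
  matrices in a fixed order, so a single seed reproduces the dataset
  byte-for-byte. Genotype-group effects are drawn for all groups (latently
  for groups where the genotype is never tested).

The default parameter values are the package's published operating point
(genotype variances 11.292/15.021 with correlation 0.890, year-group
59.706/191.284 with 0.812, genotype-year 5.144/6.269 with 0.126, location
99.976/89.923, location-year 155.660/172.154, genotype-location
4.356/8.462, residuals 27.775/27.359, nitrogen slope 14.7611 per 500 kg/ha,
genetic trend 1.4695, non-genetic trend −0.2882). The overall intercept and
the country offsets are not identified by published analyses and default to
100 dt/ha and zero.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: no selective withdrawal (attrition is random
with respect to the genetic effects, whereas real breeders withdraw the
worst candidates), no spatial field-trial error, no weather or soil
process, no location turnover (the location set is fixed over years), and
Gaussian effects throughout. Yields are floored at 0.1 dt/ha to maintain
the positive-yield invariant; at the default means this touches of the
order of one record in 10^5^ and is irrelevant to the analyses.

## 5. Zone analysis and merging

`run_zone_analysis()` fits the zone-level trend model twice: once with
separate identity-structured genotype and genotype-by-zone terms (the
variance-component parameterisation whose two numbers answer "is zonation
needed?") and once with a genotype-zone covariance (UN up to 4 zones, FA1
beyond, with an automatic UN→FA1 fallback on non-convergence) for the
between-zone correlation matrix. Zone-level year and genotype-year terms
use heterogeneous diagonal structures: short per-zone series rarely support
unstructured blocks there.

A genotype-by-zone variance within 1e-3 dt²/ha² of the floor triggers the
single-zone recommendation: genotype rankings do not change across zones.
Note the sampling behaviour at the null: when the true interaction is
zero, REML estimates have a point mass of roughly one half *at* the
boundary, and otherwise take small positive values — `zone_boundary_study()`
makes this distribution visible, and its median is the robust
single-number summary.

`merge_zones()` implements the merging rule as an explicit, logged
procedure: a zone with fewer than `min_locations` locations (default 4 —
networks rarely support zone-level estimates below that; the threshold is
configurable and recorded) merges into its *adjacent* zone with the
highest estimated genetic correlation, ties resolved towards the neighbour
with more locations, then lexicographically; the smallest zone is
processed first. Adjacency must be supplied explicitly — it is map
knowledge, not something the data contain. Merged correlations are
location-weighted means of the constituents'; for final numbers the
zone-level model should be refitted on the merged zoning (`apply_zoning()`),
with `merge_zones()` applied iteratively if needed. The procedure is
idempotent and independent of zone enumeration order.

## 6. Validation studies and problem sizes

Two packaged studies are the package's standard evidence, shared by the
test suite and `scripts/acceptance.R`:

* `recovery_study()` — 50 replicate two-country systems (10 years, 6
  locations per country, 23 new varieties per year of which 30% enter both
  countries, i.e. 15 new per country per year, all tested 2 years) at the
  default parameters; each replicate is refitted with `RGC-UN` and the
  estimated genetic correlation and genetic trend are recorded. These sizes
  keep a replicate around 2,200 records and the full study inside a few
  minutes on one CPU while leaving roughly 70 shared varieties per
  replicate — enough for the correlation to be informative. At this reduced
  scale the per-replicate spread of the trend estimate is ~0.17 dt/ha/year
  (the GLS estimator at the *true* covariance parameters already has this
  spread, so it is design information, not estimator noise), which is worth
  remembering when comparing study means against the operating point.
* `zone_boundary_study()` — 20 replicate four-zone systems (4 locations
  per zone, 10 years, 12 new varieties per year) with genotype variance 19,
  no genotype-by-zone interaction and zone-heterogeneous residuals near
  27 dt²/ha², refitted with the separate-term zone model.

## 7. Known limitations

* Unstructured blocks for many groups (L > 5) are supported through the
  log-Cholesky parameterisation but the catalogue deliberately switches to
  FA1 beyond 4 zones; full UN fits at L = 6+ are slow and fragile on
  realistic series.
* The engine assumes trial means with a diagonal (group-heterogeneous)
  residual; no spatial or AR residual structures.
* Standard errors are Wald/observed-information; no profile or bootstrap
  intervals.
* `FA0` fitting carries the variance-floor approximation described above.
* Fixed-genotype models with many varieties produce wide fixed-design
  matrices; they fit, but the random-genotype models are the intended
  path for series of realistic size.
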