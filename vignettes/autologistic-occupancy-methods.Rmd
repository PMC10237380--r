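---
title: "Auto-logistic multi-season occupancy: models, simulation design and checks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auto-logistic multi-season occupancy: models, simulation design and checks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`autocc` implements a complete Bayesian workflow for studying habitat use by
mobile avian predators — common ravens and red-tailed hawks are the motivating
species — along a gradient of conifer (juniper) expansion in shrubland, with a
synthetic-data generator standing in for field data.  This vignette is the
package's own account of the models it fits, the choices made where the design
was genuinely open, and what its tests do and do not establish.

## The model

Sites (800-m survey transects) are indexed `i`, seasons (years) `t`, and
repeated visits within a season `j`.  The latent indicator `z[i,t]` says
whether the species used site `i` in year `t`.  The model is the
auto-logistic formulation of the dynamic occupancy model:

* first year: `logit(psi[i,1]) = beta0 + beta' x[i,1]`
* later years: `logit(psi[i,t]) = beta0 + beta' x[i,t] + theta * z[i,t-1]`
* detection: `y[i,t,j] ~ Bernoulli(z[i,t] * p[i,t,j])` with
  `logit(p[i,t,j]) = alpha[t] + gamma' w[i,t,j]`.

The carry-over coefficient `theta` replaces an explicit
colonization/extinction decomposition: last year's use enters this year's
use logit as one extra covariate.  That keeps the inferential focus on
year-specific use probability, which suits a small panel of unique sites.
Because ravens and hawks range far beyond a transect within a season, the
within-season closure assumption is read as *availability*, and `psi` is
reported as a probability of habitat use rather than of physical occupancy.

Detection intercepts are year-specific (always), and detection covariates —
terrain roughness, day of year — enter through `gamma`.  All parameters,
including intercepts and `theta`, get independent Normal(0, sd = 10) priors
(precision 0.01).  The prior is specified for "covariate parameters" in the
tradition this model comes from; extending the same prior to the intercepts
and `theta` is our choice, configurable through `occu_spec(prior_sd = )`.

### Marginalized likelihood

Rather than Gibbs-sampling `z` as BUGS-style implementations do, the package
integrates the latent sequence out analytically.  Each site is a two-state
hidden Markov chain over years; `site_log_likelihood()` runs a scaled
forward recursion in which a missing visit contributes a factor of one and a
fully unsurveyed year contributes only its state transition.  The two
formulations have identical posteriors; the package carries a small
data-augmented Gibbs sampler (`fit_gibbs_reference()`) purely so that the
test suite can verify that equivalence numerically, and the suite also
checks the recursion against brute-force enumeration of all `2^T` latent
sequences at tolerance 1e-12.

Smoothed latent marginals `Pr(z[i,t] = 1 | all data)` come from the matching
forward-backward pass and feed the derived parameters: for each posterior
draw, `n.occ[t]` sums the smoothed marginals over sites surveyed in year
`t`, mean use is `n.occ[t] / S[t]`, and mean detection averages `p[i,t,j]`
over realised surveys only.  Posterior means and SDs of these quantities
give the familiar Est./SE tables.

### Sampling

`fit_occu()` runs an adaptive random-walk Metropolis sampler on the
marginalized posterior: the proposal covariance is the inverse Hessian at
the posterior mode (found by BFGS from the zero vector), and a global scale
factor adapts by Robbins-Monro during warmup towards ~0.3 acceptance,
inside the 0.2–0.4 band that is near-optimal for random-walk proposals in
this dimension range.  Adaptation freezes at the end of warmup.  Chains
(3 by default) start from jittered mode points, and split R-hat is computed
per parameter; any value above 1.1 flags the fit as non-converged in its
metadata without discarding it.  Default run lengths (3 × 2,000 draws after
1,000 warmup) are deliberately short — posteriors here are low-dimensional
and unimodal — and a field-study-scale run (hundreds of thousands of iterations,
as JAGS-era analyses of this design used) is a parameter change, not a
code change.  Fits are bit-reproducible given
`seed`.

## Model comparison and checking

**PSIS-LOO.**  The exchangeable unit is the site: one transect's entire
multi-year history.  Per-draw, per-site likelihoods give importance ratios
`1/L_i(theta_d)`; the largest 20% of each site's ratios are smoothed by a
generalized-Pareto fit (Zhang–Stephens empirical-Bayes estimator, tail
quantiles replacing raw weights, truncation at the maximum raw weight), and
the smoothed weights give `elpd_loo` with a standard error from the
pointwise spread.  Tail shapes `k > 0.7` are flagged.  With 12–37 sites each
point is a nontrivial fraction of the data, so `k` is often high and PSIS
mildly optimistic; the suite therefore validates PSIS against exact
refit-LOO (drop a site, refit, predict it) on small instances.  Ranking ties
break by fewer parameters, then model list order.  All models in a
comparison set are fitted with common random numbers (the same MCMC seed),
so duplicated models tie exactly rather than differing by Monte-Carlo noise.

**Freeman–Tukey check.**  Detections are aggregated to site-year counts
`y[i,t,.]` and compared with `e[i,t] = pi[i,t] * sum_j p[i,t,j]` over
realised visits, where `pi` is the *model-marginal* use probability (the
forward-propagated mixture, not conditioned on `y`).  Using the marginal
rather than the smoothed `z` keeps the observed and replicated
discrepancies exchangeable under the model, so the Bayesian p-value
`Pr(T_rep >= T_obs)` is calibrated; the suite confirms this on
self-simulated data.  A documented blind spot: an omitted *occupancy*
covariate barely moves this statistic, because the latent Bernoulli mixture
absorbs site-level heterogeneity in use — we verified this empirically at
effect sizes up to 3 logits.  The statistic responds to genuine count
over/under-dispersion, e.g. unmodelled detection structure; the
misspecification stress test therefore simulates a steep within-season
decline in detection (logit slope −5 across visits) omitted from the fitted
model, which drives p above 0.95 reliably.

**Staged selection** mirrors the field workflow: detection screening (null,
day of year, TRI, on an intercept-only use model); spatial-scale screening
of juniper metrics (percent cover at 100–3,000 m, category proportions,
clustering index) as univariate use models; the habitat-structure candidate
set; then prey models built around the best structure model.
`scale_screening()` selects the top-ranked metric but exposes an `override`
hook, because an interpretable metric (continuous percent cover) may be
carried forward over a marginally better-ranked transform of the same
information.

## The synthetic-data generator

The generator is first-class, tested code; its defaults *are* the study
conditions.

* **Landscape** (`generate_landscape()`): tree cells are the upper quantile
  of a Matérn-style intensity surface (Gaussian kernels around Poisson
  parents), which yields the patchy stands-on-ridges character of juniper
  woodland; the realised fill fraction is exact to one cell, and areal cover
  can be pushed to the ~60% the densest stands reach.  The DEM is a smooth
  sinusoidal ridge/drainage field (default relief ~120 m around 1,400 m).
  Correlating tree placement with ridges is possible in principle but off
  by default; nothing downstream depends on it.
* **Transects** (`place_transects()`): 37 straight 800-m transects accepted
  by rejection sampling into the three cover strata used for the real
  design (1–10%, 10–20%, >20% cover within 100 m; default 17/12/8 per
  stratum), 18 flagged for removal.  An unreachable stratum errors by name
  rather than looping forever.
* **Visit design**: the published first-season counts are internally
  inconsistent (21/10/2 transects at 3/2/1 visits is 33 transects and 85
  surveys, against a stated 30 transects and 76 surveys); the generator
  defaults to the unique allocation consistent with both totals —
  18 × 3 + 10 × 2 + 2 × 1 visits with 7 transects unsurveyed — and the
  pattern is fully configurable.
* **Removal**: cover cells within 100 m of treated transects are set to
  zero from the removal year on (the hand-cutting reduced cover on treated
  transects by ~99%), and cover-derived covariates are recomputed per year,
  so treated sites' covariates are time-varying.
* **Prey layers**: deer-mouse density is quadratic in juniper cover within
  100 m with its peak at 10% cover, declining into woodland; pocket-mouse
  density is quadratic in mean sagebrush cover; songbird relative abundance
  is a non-negative noisy quadratic; ground-squirrel presence is drawn once
  per site and held constant across years.  The quadratic coefficients are
  synthetic stand-ins chosen to reproduce those published *shapes* — the
  source capture-recapture coefficients are not public — and negative
  predictions floor at zero with a warning.
* **Default effect sizes** follow the published raven fit where available:
  `beta_juniper = 1.74` per SD, detection intercepts giving p ≈ 0.43–0.58
  across years, a TRI detection effect of 0.22, and `theta = 1` (a
  moderate, plausible carry-over; no published estimate exists for the
  emulated system, so this is the generator's own choice).

What the generator does **not** emulate: spatial autocorrelation in
detection beyond the shared landscape, observer effects, unmodelled
availability cycles, or any geodesy (coordinates are planar metres).
Passing tests therefore demonstrate that the *estimators* behave correctly
under the model's own assumptions plus realistic covariate correlation
structure — not that the model is adequate for any particular field
dataset.

## Covariate extraction

All buffer summaries use the cell-centre-in-buffer rule, so every value can
be re-derived by direct enumeration (that is how the tests check them).
Percent cover within a radius of the transect *polyline* (not its midpoint)
is computed at the nine radii from 100 m to 3,000 m; category proportions
aggregate cover to 30 m × 30 m blocks (0%, under 10%, 10–20%, over 20%;
proportions sum to one); cliffs are cells whose Horn-stencil slope exceeds
60°, with `Inf` as the documented no-cliff sentinel; TRI is the
mean absolute elevation difference to the eight neighbours (Riley variant),
averaged over the buffer; clustering is the average nearest-neighbour ratio
against the CSR expectation `0.5/sqrt(density)` (the ArcGIS tool family's
statistic — exact ArcGIS semantics are not reproducible, so the formula is
fixed here and stated).  Distances to water, streams, roads and dwellings
are minimum planar distances from the transect polyline to the feature
geometry.  Standardization uses the sample (n−1) SD, pooled over site-years
for time-varying columns; constant columns are rejected by
`standardize_covariates()` (the pipeline passes landscape-degenerate
columns through untouched instead), and the stored means/SDs make the
transform exactly invertible.

## Numerical and design notes

* Forward recursion rescales at every year, so likelihoods of impossible
  histories degrade to `-Inf` cleanly rather than underflowing.
* `log_posterior()` returns `-Inf` for non-finite parameter vectors
  (rejection), never an exception mid-chain.
* Posterior direction is the share of draws matching the sign of the
  posterior mean, in [50, 100]; draws exactly at zero count half, an
  exactly-zero mean is reported as a 50% tie with a warning.  The point
  estimate is the mean (the source convention does not say mean or median).
* 90% credible intervals are equal-tailed (5%/95% quantiles).
* Grid I/O uses ESRI ASCII rasters — a plain-text, universally parseable
  raster format — with cell size and origin in the header.
* Problem sizes in the test suite (e.g. recovery at 200 sites x 4 years x 3
  visits over 20 replicates; exact-LOO at 12 sites; screening over 4 radii
  at 150 sites x 20 replicates) were chosen as the smallest designs at
  which the checked properties are comfortably identifiable.

## Known limitations

* The sampler is a full-vector random-walk; for models far larger than this
  package's (tens of parameters) HMC would mix better.
* PSIS-LOO at 12–37 sites routinely flags high Pareto-k; exact refit LOO is
  provided and cheap at these sizes, and is the default check in that
  regime.  WAIC/DIC are deliberately not offered.
* The Freeman–Tukey check's insensitivity to omitted occupancy covariates
  (above) is inherent to count-dispersion discrepancies in occupancy
  models; a fit that "passes" can still mis-specify the use model.
* Species are simulated and analysed independently; there is no shared-site
  dependence between the raven-like and hawk-like processes.
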