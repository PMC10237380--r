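# autocc

Bayesian auto-logistic multi-season occupancy modelling of habitat use by
generalist avian predators (common ravens, red-tailed hawks) in shrubland
experiencing juniper expansion and removal — implemented end to end as an R
package with a synthetic-data generator standing in for the field data.

Shrubland managers remove encroaching conifer partly on the premise that
trees subsidise avian predators.  Evaluating that premise requires modelling
predator *habitat use* from repeated-visit detection/non-detection surveys
while accounting for imperfect detection, multi-year dynamics, and habitat
covariates measured at many spatial scales.  This package provides that
workflow for researchers and for anyone studying the statistical behaviour
of the design: landscape simulation, covariate extraction, model fitting,
model selection, and goodness-of-fit checking, all reproducible from a
single seed.

## The model

For site *i*, year *t*, visit *j*, with latent use `z[i,t] ∈ {0,1}`:

```
logit ψ[i,1] = β₀ + β′x[i,1]                      (first year)
logit ψ[i,t] = β₀ + β′x[i,t] + θ·z[i,t−1]          (auto-logistic carry-over)
z[i,t]  ~ Bernoulli(ψ[i,t])
y[i,t,j] ~ Bernoulli(z[i,t] · p[i,t,j]),  logit p[i,t,j] = α_t + γ′w[i,t,j]
```

with independent Normal(0, sd 10) priors throughout.  The latent sequence is
marginalised by a two-state forward recursion (each site is a small hidden
Markov chain), and the posterior is sampled by adaptive random-walk
Metropolis with split-R̂ convergence diagnostics.  Model comparison uses
PSIS-LOO (site = exchangeable unit) with exact refit-LOO as the small-sample
oracle; goodness of fit uses a Freeman–Tukey posterior predictive check,
`T = Σ(√y − √e)²` on site-year detection counts.

## Worked example

```r
library(autocc)

# a full synthetic study: clustered landscape, 37 stratified 800-m
# transects (18 treated), 4 years x <=3 visits, removal before year 4
b <- simulate_study(seed = 1)
dim(b$y)
#> [1] 37  4  3

fit <- fit_occu(occu_spec(~juniper_100, ~tri), b$y,
                b$covariates, b$survey_covariates, seed = 1)
round(summary(fit)[1:3, c("mean", "sd", "5%", "95%")], 2)
#>                  mean   sd    5%  95%
#> beta0            0.94 0.74 -0.02 2.38
#> beta_juniper_100 1.31 0.53  0.56 2.27
#> theta            0.99 0.81 -0.44 2.30

round(derived_parameters(fit, draw_ids = seq(1, 6000, by = 6))[, 1:5], 3)
#>   year   psi psi_se     p  p_se
#> 1    1 0.683  0.096 0.417 0.091
#> 2    2 0.766  0.045 0.392 0.061
#> 3    3 0.858  0.020 0.571 0.055
#> 4    4 0.580  0.053 0.519 0.082
```

(Output above is from this exact code at seed 1; the year-4 drop in mean
use probability is the removal treatment acting through the time-varying
juniper covariate.)  `beta_juniper_100` is the use-juniper effect per SD of
standardized cover at 37 sites; its 90% CrI comfortably covers the
generator's default effect (1.74), and detection probabilities land in the
0.4-0.6 band the generator encodes.

The staged analysis over a generated bundle lives in `analysis/`:

```sh
Rscript analysis/01_simulate.R          # bundle -> results/bundle/
Rscript analysis/02_scale_screening.R   # juniper metric x radius screening
Rscript analysis/03_candidate_sets.R    # detection / structure / prey stages
Rscript analysis/04_derived_and_checks.R
```

Each script prints what it found and writes plain-text tables under
`results/`.

## Package layout

- `R/` — landscape/transect/prey simulation, covariate extraction,
  marginalized likelihood + MCMC, derived parameters, PSIS-LOO,
  Freeman–Tukey PPC, staged selection, pipeline glue.
- `analysis/` — numbered narrative drivers over the package.
- `tests/testthat/` — unit, property and acceptance suites (oracles are
  brute-force/closed-form and live in `helper-oracles.R`).
- `vignettes/autologistic-occupancy-methods.Rmd` — the methods vignette:
  model, priors, sampler, generator design, numerical choices, known
  limitations.
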