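# selsurv

Habitat that animals select is not always habitat in which they
succeed. `selsurv` is an R workflow for wildlife ecologists who need to
tell the difference at landscape scale: it links resource selection to
demographic performance across reproductive life stages and maps where
strong selection coincides with high survival (productive, source-like
habitat) versus poor survival (potentially maladaptive, sink-like
habitat). The motivating system is a sagebrush-obligate grouse whose
nesting (38 days), early brood-rearing (21 days) and late brood-rearing
(28 days) stages were monitored by telemetry across a network of
breeding subpopulations; all components are species-agnostic.

## The models

**Selection** is a resource selection function fit to used versus
available points (5 available per used point, drawn within the 90th
percentile of movement distances from the lek or nest):

    logit P(Y = 1) = b0 + X*beta + kappa_site + eta_year + nu_animal

with distance-to-anchor as a movement confounder. Predictions drop the
intercepts, random effects and confounder: w(x) = exp(X*beta), mapped
as the bounded habitat selection index HSI = w/(1+w).

**Survival** is an exposure-time binomial model on interval-censored
encounter histories: a unit survives an interval of length t with
probability DS^t, where

    logit DS = g0 + X*beta + kappa_site + eta_year

and cumulative stage survival is DS raised to the stage duration.

Both families are fit by MCMC (JAGS) with Laplace (Lasso) shrinkage
priors on habitat coefficients, lambda ~ Uniform(0.001, 10), and a
latent indicator per covariate group that selects the supported spatial
scale (radii 75-1451.7 m, the species' movement statistics) at every
iteration. Convergence is judged by Gelman-Rubin statistics < 1.1.
Because real telemetry of this kind is restricted, the package includes
a first-class synthetic generator (autocorrelated landscapes, point
features, used points and fates from known coefficients) so that every
estimator is exercised by simulation-recovery against known truth.

## Worked example

Fit an intercept-only exposure model to synthetic nest histories
generated at constant daily survival 0.9749 (whose 38-day product is
0.38), with nests checked every 10 days:

```r
library(selsurv)

cfg <- sim_config(nx = 40, ny = 40, seed = 42,
                  covariates = list(covariate_spec("elevation",
                                                   "elevation",
                                                   "topographic")),
                  gamma0 = c(nest = qlogis(0.9749), early_brood = 0,
                             late_brood = 0),
                  sd_site = 0, sd_year = 0,
                  beta_sel = list(nest = c(), early_brood = c(),
                                  late_brood = c()),
                  beta_surv = list(nest = c(), early_brood = c(),
                                   late_brood = c()))
truth <- sim_truth(cfg)
eh <- simulate_fates(data.frame(unit = 1:600), truth, "nest",
                     check_interval = 10)
fit <- fit_model(eh, "survival",
                 control = mcmc_control(6000, 2000, 2, 3), seed = 7)
ds <- median_daily_survival(fit)
c(daily = ds, cumulative_38day = cumulative_survival(ds, 38))
#>            daily cumulative_38day 
#>        0.9735488        0.3610724 
max(gelman_rubin(fit))
#> [1] 1.000161
```

The posterior-median daily survival (0.9735) and its 38-day product
(0.361) recover the generating rate and its stage survival of 0.38
within Monte-Carlo error, and the three chains agree (all Gelman-Rubin
statistics at 1.00).

## The analysis workflow

The numbered drivers under `analysis/` run the whole study on a
synthetic system and write tables and plain-text rasters under
`results/`:

1. `01_simulate.R` — landscape, used locations, encounter histories
   with known truth
2. `02_design.R` — used/available design tables (5:1, multi-scale
   candidate columns, decayed distances, centred/scaled)
3. `03_fit_selection.R` — scale selection (BLISS) then the final RSF
   per stage
4. `04_fit_survival.R` — exposure-time survival models per stage
5. `05_validate.R` — individual-level holdout: rank cross-validation,
   used-habitat calibration, survival posterior predictive check
6. `06_map_rank.R` — HSI surfaces, isopleth categories (top 5% of used
   locations = high), cumulative-survival surfaces and categories,
   composite indices, the 12-cell source-to-sink rank overlay and
   example management categories

Run them in order from the repository root, e.g.
`Rscript analysis/01_simulate.R`.

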