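---
title: "Linking habitat selection to reproductive survival: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking habitat selection to reproductive survival: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

Habitat that animals prefer is not always habitat in which they do well.
When selection cues are decoupled from demographic consequences — after
fire, conifer encroachment or other rapid change — strongly selected
places can become population sinks. `selsurv` implements a workflow for
separating productive habitat (high selection *and* high survival) from
potentially maladaptive habitat (high selection, poor survival) across
the reproductive life stages of a territorial bird: nesting (38 days),
early brood-rearing (21 days) and late brood-rearing (28 days, to
independence at about 50 days post-hatch). The motivating system is a
sagebrush-obligate grouse monitored by radio-telemetry across a network
of breeding subpopulations, but every component is species-agnostic.

This vignette describes the models, the synthetic study system used to
exercise them, the numerical conventions, and the choices we made where
the methodology is genuinely open.

## The two model families

**Habitat selection.** Selection is estimated with a resource selection
function (RSF) contrasting used telemetry locations with availability:

$$\mathrm{logit}\, P(Y_i = 1) = \beta_0 + X_i\beta + \kappa_{site(i)} +
\eta_{year(i)} + \nu_{animal(i)},$$

where the used/available indicator is modelled by logistic regression
only to estimate $\beta$; predictions discard the intercepts and random
effects and apply the exponential link, $w(x) = \exp(x\beta)$, which is
proportional to the relative probability of use. Availability is
defined behaviourally: available points are drawn uniformly within the
90th percentile of observed movement distances from the anchor (the lek
for nesting, the individual's nest for broods) at a 5:1
available:used ratio, and every row carries its distance to the anchor
as a movement confounder so that environmental coefficients are not
contaminated by central-place behaviour. The confounder is part of the
fitted model but never of the prediction surface.

**Survival.** Nest and brood fates are observed only at periodic
revisits, so survival is modelled on interval-censored encounter
histories with an exposure-time binomial likelihood: the probability
that unit $h$ survives interval $i$ of length $t$ is $DS_{h,i}^{t}$,
with

$$\mathrm{logit}\, DS_{h,i} = \gamma_0 + X_{h,i}\beta + \kappa_{site} +
\eta_{year},$$

covariates measured at the start of each interval. Daily survival
raised to the stage duration (38/21/28 days) gives cumulative stage
survival; in the intercept-only case the posterior reproduces the
classical Mayfield-type daily-rate estimate, which we use as an oracle
in the tests.

## Priors, sampling and scale selection

Models are fitted by MCMC in JAGS. Habitat coefficients carry Laplace
(Lasso) shrinkage priors with a single shared tuning parameter,
$\beta_j \sim \mathrm{Laplace}(0, 1/\lambda)$,
$\lambda \sim \mathrm{Uniform}(0.001, 10)$, which regularises the many
candidate covariates without hard pre-selection. Random intercepts are
normal with mean zero and a Uniform(0, 100) prior on their variance
(the printed prior is on $\sigma^2$; a uniform-on-SD variant would be a
one-line change and we note the ambiguity). The baseline intercept has
a vague normal prior. The default protocol is 3 chains of 30,000
iterations, 20,000 discarded, thinned by 5; convergence is judged by
per-parameter Gelman-Rubin statistics below 1.1. The drivers and tests
use shorter, explicitly stated runs.

Because selection is scale-dependent, each covariate group (twelve
groups of correlated variables) carries a latent categorical indicator
that chooses, at every MCMC iteration, which candidate variable-scale
column enters the linear predictor. Candidate radii are the movement
statistics of the species: 167.9, 439.5 and 1451.7 m (minimum, mean and
maximum daily movements), plus 75 and 260 m for nesting (recess area
and recess distance) and 260/370 m for early/late broods. Within a
group exactly one candidate is active, so collinear scales never
co-occur; the posterior frequency of each candidate measures scale
support and the modal candidate enters the final model. Ties break
toward the smallest radius. Because the group keeps one coefficient
regardless of which candidate is active, the indicator swap is a
fixed-dimension Gibbs update — no trans-dimensional machinery is
needed for an identical posterior. Variables and scales compete
jointly within a group; confounders are exempt. One caveat found while
testing: for a genuinely null group the indicator does *not* sit at
uniform frequencies within any one dataset — it favours whichever
candidate is chance-correlated with the response, an O(1) effect.
Uniformity holds in expectation over datasets, and the test suite
checks exactly that.

## Covariate engineering

Land-cover covariates are summarised as proportions (or feature
densities) within circular moving windows at each candidate radius.
Window membership is metric — a pixel belongs if its centre lies within
the radius of the focal pixel's centre — so fractional radii behave
correctly on the 30 m grid; edge windows are renormalised by the number
of valid in-grid pixels. The implementation is an FFT convolution of
the band and its validity mask, verified against a brute-force window
loop in the tests. Distance predictors are transformed as
$\exp(-d/\alpha)$ so their influence decays smoothly, with $\alpha$ set
to the mean raw distance over the rows of the analysis at hand —
estimated per life stage, never from the map. All covariates are
centred and scaled (population SD, a documented convention) over the
fitting rows, and those same parameters are reapplied verbatim at
prediction time so coefficients keep their per-SD meaning.

## The synthetic study system

Restricted telemetry cannot ship with the package, so a generator
produces a study system with known ground truth; it is first-class,
tested code, and every downstream claim is a recovery statement about
it. Continuous covariates are Gaussian random fields (white noise
convolved with a Gaussian kernel, edge-corrected and standardised) with
configurable autocorrelation range; point and line features (leks,
streams, springs, saline lakes) yield Euclidean distance bands;
temporal covariates get one band per year. Used points are drawn with
probability proportional to $\exp(X\beta_{true})$ within the stage's
availability disc; fates are daily Bernoulli trials at
$\mathrm{logit}^{-1}(\gamma_0 + X\beta_{true} + \text{intercepts})$,
recorded against whole inter-visit intervals because the failure day is
unobservable in the field. Default conditions mirror the motivating
study: ten subpopulations, years 2003-2019, 419 marked females, 579
nests, 10-day revisit schedules, 38/21/28-day stage durations, and
baseline daily survival whose stage products are 0.38 (nesting, 38
days) and 0.74 (brood rearing, 50 days). Where the study system gives
no number (random-intercept spreads, field autocorrelation range,
availability radii on a desk-scale grid) we fixed plausible values once
— intercept SDs of 0.2-0.3 on the logit scale, availability radii of
one to a few kilometres — and did not revisit them. What the generator
deliberately omits: movement trajectories (points are exchangeable
within the availability disc), telemetry error, observer effects, and
any feedback between fate and subsequent selection. Passing recovery
tests therefore demonstrates correctness of the estimators under the
stated generative model, not robustness to those field realities.

## Validation

Individuals, never rows, are withheld (50 by default) so testing data
are independent of every training individual. Three diagnostics:

* **Rank cross-validation.** Availability predictions are cut into ten
  (near) equal-area quantile bins; each bin's expected share of use is
  its share of total selection weight; observed withheld-point counts
  are regressed on expected counts. We report the Spearman rank
  correlation of observed counts with bin rank, the regression
  $R^2$ and its slope. The diagnostic is invariant to monotone
  transforms of the surface.
* **Used-habitat calibration.** For each covariate, availability rows
  are resampled per posterior draw with weight $\exp(X\beta_s)$, the
  covariate density of each simulated used set is evaluated on a fixed
  grid, and the pointwise 95% envelope is compared with the observed
  test-point density; we report the fraction of the grid covered.
* **Survival posterior predictive check.** Per draw, fates are
  re-simulated over the withheld exposure structure; the discrepancy is
  the maximum absolute distance between a product-limit survival curve
  (on the check-day grid) and the draw's model-implied curve; the
  p-value is the share of draws whose replicate discrepancy exceeds the
  observed one. The maximum-distance metric is our choice; the
  literature specifies only "survival curves".

## Spatial products

Selection maps use posterior-median coefficients pixelwise, dropping
intercepts, random effects and the movement confounder, then the
bounded habitat selection index $HSI = w/(1+w) \in (0,1)$. The
continuous surface is categorized by percent isopleths at used
locations: the high class holds the top 5% of used-location HSI values,
moderate to the 25% isopleth, low to the 50% isopleth, nonhabitat
below. Thresholds live in used-value space, so any monotone transform
of the surface yields identical classes; class intervals are half-open
and lower-inclusive, ties falling to the lower class. Survival maps are
$\mathrm{logit}^{-1}$ surfaces exponentiated over the stage duration.
Their categorization derives from the empirical distributions of
predicted survival at failed and successful units: very-low/low
boundary at the failed median, moderate/high at the successful median,
low/moderate at their midpoint. The source defers this rule to an
external reference, so ours is an explicit, overridable default.

Composite indices multiply the three stage surfaces: selection surfaces
are first relativised by their stage maximum (equal stage weighting;
the composite's maximum is exactly 1), survival surfaces are not
(they are true probabilities, so the product is reproductive-period
survival), and survival is evaluated only where the composite selection
categories call habitat. The composite selection categorization reuses
the isopleth procedure on composite values at used points pooled across
stages (a per-stage option exists). The selection and survival
categories then overlay into a 12-cell ordinal rank. Survival tier
dominates; within the low-to-high survival tiers more selection ranks
higher, but within the very-low tier more selection ranks *lower*,
because strong selection for lethal habitat is the sink signature. Rank
12 is high selection with high survival; rank 1 is high selection with
very low survival. Area tables report pixels, km² (at 900 m² per pixel)
and percentages against both the whole region and the classified area,
because the two denominators answer different questions and reported
shares in the literature do not reconcile under a single one. Finally,
four example management categories combine the composite classes with a
binary abundance-and-space-use (ASUI) layer supplied by the caller
(priority+, priority, general, other, as a rule list; "source" means
the top two overlay ranks). Building the ASUI itself is out of scope;
any continuous use layer must be pre-thresholded.

## Numerical and engineering choices

* Rasters are an in-package grid type (matrix, origin, pixel size) with
  plain-text ESRI ASCII grid I/O; no GDAL-backed raster stack is
  required anywhere in the workflow.
* The 90th availability percentile uses linear interpolation between
  order statistics (R type 7), documented because conventions differ.
* Available points falling off the raster are rejected and resampled so
  the 5:1 ratio is exact.
* Failure is attributed to its whole interval, and exposure counts the
  full interval length; the binomial-exposure likelihood needs only the
  pair (t, fate).
* All randomness flows from one master seed through named substreams
  (landscape, truth, per-stage points and fates), so every artefact is
  bit-reproducible; chain RNGs derive from the fit seed.
* Non-finite likelihood at initialisation triggers up to three
  re-initialisations with perturbed RNG states before failing loudly.
* Degenerate inputs error early and by name: zero-variance covariates,
  all-tied isopleth thresholds, non-monotone survival thresholds,
  single-chain convergence requests, both-class outcome checks.

## Problem sizes

The bundled drivers and tests run at desk scale, chosen as the smallest
sizes at which the estimators are comfortably identified: landscapes of
120-150 pixels square at 30 m, 300-500 used locations per stage,
150-250 monitored units, chains of 1,500-6,000 iterations with 2-3
chains. Recovery statements at these sizes are about correctness, not
about the power of any particular field design; the full 30,000 x 3
protocol remains the package default for real analyses.

## Known limitations

Brood survival is presence/absence of the brood, not chick survival.
The generator shares one landscape across years apart from designated
temporal covariates. Prediction surfaces use posterior medians rather
than full posterior propagation (interval surfaces would be a direct
extension over the stored draws). The individual-level holdout is a
single split, not k-fold. None of these affect the estimators'
contracts; they bound what the maps claim.
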