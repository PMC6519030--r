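---
title: "Selection on and predicted evolution of a laying-date reaction norm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection on and predicted evolution of a laying-date reaction norm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Seasonal timing traits such as avian egg-laying date are phenotypically
plastic: each female adjusts her laying date to the spring temperature she
experiences, so her phenotype is a *reaction norm* — a linear function of a
temperature cue with an **elevation** (the phenotype at the average
environment) and a **slope** (plasticity). When a warming climate shifts
the phenology of the food supply (in tit populations, the spring caterpillar
biomass peak), the *optimal* laying date moves, and selection can act on the
elevation of the reaction norm, on its slope, or both. Whether the
population can respond depends on whether elevation and slope harbour
additive genetic variance.

`rnevo` implements the full analysis chain for this question on pedigreed
wild-population breeding records:

1. **Optimal reaction norm** — the yearly optimal laying date is the
   caterpillar peak date minus a 33-day rearing lag (the time from laying
   through incubation to peak chick food demand). It is regressed on the
   cue temperature over consecutive study periods, with BCa bootstrap
   intervals for elevation and slope changes between periods.
2. **Cue window** — a simplified sliding-window grid search for the
   temperature window whose mean best predicts an annual response series.
3. **Random-regression animal models** — Bayesian mixed models partitioning
   individual variation in reaction-norm elevation and slope into
   permanent-environment and additive-genetic parts, using the pedigree.
4. **Annual selection gradients** — spline fitness surfaces of recruit
   counts over laying date, and average-derivative Lande–Arnold gradients.
5. **A reaction-norm breeder's equation** — mapping annual gradients and
   the G matrix into predicted yearly and cumulative changes in elevation
   and slope, with propagated uncertainty.
6. **A residual-structure simulation** — showing that misspecifying the
   heterogeneous-residual grouping inflates slope-variance estimates.

Because the motivating field data are not publicly deposited, the package
ships a synthetic-data generator that reproduces the *statistical
structure* of such a study, so that every stage is testable end to end
against known truth.

## The models

### Laying-date random regression (selection model)

For female $i$ in year $j$, nest box $k$ and temperature-group $l$:

$$z_{ijkl} = \alpha_z + a_i + b_i\,(T_{ij} - \bar T_i) + b\,\bar T_i +
\mathrm{age}_{ij} + nb_k + yr_j + e_{z,ijl}$$

Temperature is split into a within-individual component
$T_{ij}-\bar T_i$ and a between-individual component $\bar T_i$, so that
individuals observed only in warm (or only in cold) years do not fake a
plasticity signal. Lifetime reproductive success $W_i$ (summed recruits) is
an overdispersed Poisson trait,
$\log E[W_i] = \alpha_W + c_i + e_{W,i}$, and $(a_i, b_i, c_i)$ are drawn
from an unstructured $3\times3$ covariance matrix. The covariance between
$a_i$ (elevation) or $b_i$ (slope) and $c_i$ (fitness) measures selection
on the respective reaction-norm component. The residual variance of the
Poisson trait is held at a small fixed value (0.01 by default): it cannot
be constrained to exactly zero without the chain seizing up, because the
latent log-means then have no room to move relative to the individual
effects.

### The animal model (G matrix)

On the full data set, elevation and slope are modelled on grand-mean-centred
temperature and split into permanent-environment and additive-genetic
parts:

$$z_{ijkl} = \alpha_z + a_i + A_i + (b + b_i + B_i)(T_{ij}-\bar T) +
\mathrm{age}_{ij} + nb_k + yr_j + e_{z,ijl}$$

with $(a_i,b_i)$ and $(A_i,B_i)$ each governed by an unstructured
$2\times2$ covariance matrix, the additive one tied to the pedigree through
the numerator relationship matrix $A$. The residual variance is
heterogeneous across equal-count temperature groups of years (the number
of groups defaulting to the number of years divided by ten, rounded).

A slope variance in (days/°C)² is not directly comparable to an intercept
variance in days²; `slope_variance_contribution()` multiplies it by the
variance of the centred temperatures to put both on the days² scale.

### The reaction-norm breeder's equation

Selection gradients on elevation and slope follow from environment-specific
gradients as $\beta_g = \Phi^\top \beta_z$ with rows $(1, x_j)$, so a
single year's genetic response is

$$\Delta\bar g = G\,(1, x_j)^\top \beta_{z_j} \times p_{recr,j+1} \times 0.5,$$

where $p_{recr,j+1}$ (the fraction of the next breeding population that are
locally born first-year birds) converts a per-generation response to a
per-year one, and the halving reflects that laying date is expressed only
by females. First-order error propagation combines the gradient SE with
HPDI-derived SEs of the G components:
$SE^2 = (G(1,x)^\top)^2 V(\beta) + \beta^2 V(G(1,x)^\top)$. The cumulative
change across years carries a $\pm1.96\sqrt{\sum SE^2}$ interval. The
HPDI-to-SE normal approximation is deliberately conservative for
zero-bounded, skewed variance posteriors; we keep the simple recipe and
flag the caveat here.

## Estimation machinery

The mixed models are fitted by a purpose-built Gibbs sampler (compiled
core, driven entirely by R's RNG so `set.seed()` gives bit-identical
output):

* Fixed effects, year and nest-box intercepts, and each female's
  random-regression block get exact Gaussian conditional updates. The
  permanent-environment and additive effects of a phenotyped female are
  sampled *jointly* (a 4-dimensional block) — the two terms are strongly
  anti-correlated given the data, and separate updates mix an order of
  magnitude slower. Unphenotyped pedigree members (sires, non-breeding
  ancestors) get single-site draws from their pedigree-conditional prior.
* Covariance matrices get conjugate inverse-Wishart updates; scalar and
  group residual variances inverse-gamma updates.
* The LRS trait uses random-walk Metropolis updates of the latent
  log-means, plus a joint shift move of (individual effect, latent) pairs
  that defeats the tight coupling induced by the small fixed residual;
  step sizes adapt during burn-in only.
* **Parameter expansion** (default on): each random-regression term is
  written as $\mathrm{diag}(\alpha)\,\eta$ with working scales
  $\alpha \sim N(0, 25^2)$ and a working covariance
  $\Psi \sim IW(\nu = d, V = I_d)$; reported covariances are
  $D_\alpha \Psi D_\alpha$. Without expansion, variance chains near zero
  stall; with it the same fits mix freely (the fit object reports
  per-parameter effective sample sizes, so this is easy to inspect). This
  mirrors the parameter-expanded prior convention for animal models; exact
  equivalence to any particular software's prior is not claimed.
* Non-positive-definite conditional precisions are repaired by an
  escalating diagonal jitter (counted and reported in the fit object); a
  non-finite state aborts with the iteration number.

Pedigree machinery is classical quantitative genetics: inbreeding
coefficients by the Meuwissen–Luo traversal of the tabular relationship
matrix, and the sparse inverse of $A$ assembled directly by Henderson's
rules (verified in the tests against dense tabular inversion to $10^{-8}$
on random pedigrees).

Posterior point summaries are medians — variance posteriors bounded at zero
are right-skewed, where the mean is misleading — with shortest-interval
(HPD) 95% intervals and autocorrelation-based effective sample sizes.

### Fitness surfaces and gradients

Annual fitness surfaces are penalized splines (mgcv, REML smoothness, small
basis `k = 5` — annual samples are modest and fitness surfaces smooth) with
a negative-binomial family and a Poisson fallback when the dispersion is
unidentifiable. The directional gradient is the *average derivative* of
relative fitness on the unstandardized day scale,
$\beta_z = \overline{W'(z_i)} / \bar W$, which is what the breeder's
equation consumes with G in day units; for Gaussian surfaces and normal
phenotypes it coincides with the Lande–Arnold regression gradient. The
acceptance suite replays a 200-replicate calibration (n = 300 broods,
Gaussian surface, negative-binomial counts) and checks that the bias is
statistically indistinguishable from zero and that the mean
parametric-bootstrap SE sits within 25% of the replicate SD. Gradients are
deliberately *not* variance-standardized:
standardization would break the dimensional consistency of
$\Delta\bar g$ in days.

### BCa bootstrap

The optimum module's intervals are bias-corrected and accelerated: the
bias correction comes from the fraction of bootstrap replicates below the
point estimate, the acceleration from jackknife skewness. The resampling
unit is the *year* (stratified within period), because the optimum is a
yearly quantity; resampling residuals would instead condition on the
fitted model. Degenerate bootstrap distributions yield a zero-width
interval with a warning rather than an error, so noise-free pipelines stay
usable. The acceptance suite verifies, over 200 replicate series with a
planted −5-day elevation step (15 years per period, 4-day optimum noise),
that BCa coverage of the elevation difference stays within 5 points of
nominal.

## The synthetic-data generator

The generator emulates a 44-year nest-box study with roughly 110 breeding
females per year (about 3,000 females and 4,900 broods in total):

* **Demography** — breeders survive with probability 0.375 per year (so a
  female averages ~1.6 breeding attempts, matching the brood/female ratio
  of such studies); vacancies are filled by locally born yearlings with
  probability 0.55, otherwise by immigrants, giving a recruit fraction of
  the breeding population around 0.35 and a realistically shallow, open
  pedigree. Both parents of a recruit come from a pair that bred the
  previous year, so full- and half-sib structure arises naturally.
* **Environment** — cue-window temperatures are Normal(8 + 0.035·year, 1) °C
  (a 1.5 °C warming over the study), and the caterpillar peak date is
  linear in the cue with slope −3.15 days/°C plus 4-day noise; the optimal
  laying date is the peak minus 33 days.
* **Laying dates** — assembled exactly from the animal-model equation, with
  variance components defaulting to posterior medians of a published
  analysis of such a population (additive intercept variance 4.38 day²,
  additive slope variance 0.02, permanent environment 3.24/0.02, year
  9.65, nest box 1.22, and four temperature-ordered residual variances
  11.09–19.27 day²; overall mean 21.8 April-days, population slope −3.28).
  Breeding values flow through the pedigree as midparent plus a Mendelian
  deviation of covariance G/2 — the non-inbred approximation, appropriate
  for a shallow open pedigree; inbreeding is still handled on the
  estimation side via the A-matrix.
* **Fitness** — expected recruits follow Gaussian stabilizing selection
  around the year's optimum (width 10 days, 0.9 recruits at the optimum),
  with the default bird phenotype a few days later than the optimum so
  annual gradients are predominantly negative; realized counts are
  negative binomial (size 1.5). A configurable fraction of broods is
  flagged as experimentally manipulated (default 25%, with a mild fitness
  penalty), and a fraction of records (default 7%) has the female identity
  blanked, biased towards extreme laying dates — exercising the
  include/exclude rules of the downstream analyses.

What the generator does **not** emulate: spatial structure and habitat
heterogeneity, extra-pair paternity (the social pedigree is the true
pedigree here), density dependence, observation error in temperatures, and
any nonlinear optimum–temperature relationship. Passing tests therefore
show that the estimators recover the assumed generating structure — not
that real data satisfy that structure.

## Numerical and design choices

* **Laying-date scale**: days since March 31 (April 1 = day 1), so an
  intercept of ~22 is late April.
* **Residual grouping**: equal-count (rank-based) temperature groups with
  ties broken by year. Equal-width temperature bins can end up empty,
  making group variances inestimable.
* **Decade grouping** (for the misspecification experiment): contiguous
  calendar blocks; "decade" means n_years/n_groups-year blocks when the
  series is not a multiple of ten.
* **Age classes**: first-year / older / unknown with "older" as the
  reference level; unknown-identity records are excluded from
  individual-level models (they cannot inform individual effects) but kept
  for annual selection gradients; only females with ≥ 2 breeding attempts
  enter the bivariate selection model.
* **Elevation reporting**: at the grand-mean temperature, so elevation
  changes between periods are not contaminated by slope differences; the
  centring constant is stored with each fit and reused by the predictor.
* **Year exclusion** (e.g. a frost year with an aberrant food peak) is a
  data flag honoured by the optimum module, not a hard-coded year.
* **p_recr** counts breeding *females* that are locally born first-year
  birds, consistent with the female-expression halving.
* **Detection criterion** for slope variance (the experiment's "power"):
  the posterior probability that the slope-variance contribution exceeds
  5% of the total individual variance must exceed 0.90; an HPDI-based rule
  is selectable. The original power criterion behind such figures is
  typically unstated, so this is a package definition, not an inference.
* **MCMC defaults** are desk-scale (6,000 iterations, 1,000 burn-in,
  thinning 5, targeting effective sizes of a few hundred); analyses that
  need more (the full animal model) pass their own settings.

## Problem sizes used by the test suite

The tests run reduced but honest designs, chosen as the smallest sizes at
which each property is identifiable: parameter recovery uses 20 data sets
of ~1,000 females over 30 years (12,000 MCMC iterations each, with a
pedigree-permutation negative control); the residual-structure experiment
uses 100 replicates of ~500 females over 30 years; gradient calibration
uses 200 replicates of 300 broods; BCa coverage uses 200 replicate
30-year series; the breeder's-equation oracle uses 200 one-generation
forward simulations of 500 parents.

## Known limitations

* With ~1.6 records per female and a shallow open pedigree, the split of
  individual intercept variance into permanent-environment and additive
  parts is weakly identified at reduced population sizes; posteriors are
  honest but prior-influenced, and component-wise HPDI coverage for the
  permanent-environment variance can dip below nominal there. At the full
  simulated population size the posteriors centre on the truth.
* The slope-variance inflation under misspecified residual grouping is
  modest at 500 females (the artefact scales with how much
  temperature-linked residual variance the grouping fails to absorb);
  the experiment demonstrates direction, not the magnitude seen in
  larger data sets.
* The Poisson-trait sampler targets annual/lifetime recruit counts of
  order one; very large counts would want a different latent proposal.
* First-order error propagation ignores covariances among G components
  (component SEs enter independently) and the HPDI-to-SE conversion
  assumes near-normal posteriors; both choices are conservative for the
  zero-bounded components.
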