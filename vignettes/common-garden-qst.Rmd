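---
title: "Hierarchical Bayesian analysis of common-garden provenance trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical Bayesian analysis of common-garden provenance trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Widespread temperate forest trees such as cottonwoods (*Populus*) span
strong latitudinal climate gradients, and populations sampled along such
gradients often differ genetically in phenology (the timing of spring bud
flush and fall bud set) and growth.  A replicated common-garden
(provenance) trial separates genetic from environmental causes of this
variation: cuttings from many source populations ("rivers", for riparian
species) are cloned and planted together at several garden sites, so that
population and genotype effects can be estimated free of the confounding
between source environment and phenotype that plagues in-situ
measurements.

Two classic questions drive the analysis this package implements:

1. **Is trait divergence among populations larger than neutral
   expectation?**  Quantitative differentiation is summarized by
   $$Q_{ST} = \frac{\sigma^2_P}{\sigma^2_P + 2\sigma^2_G},$$
   where $\sigma^2_P$ is the among-population and $\sigma^2_G$ the
   within-population (among-genotype) genetic variance.  Comparing the
   $Q_{ST}$ posterior distribution with a neutral-marker $F_{ST}$
   confidence interval (supplied externally, as a number) tests for
   divergent selection: disjoint intervals with $Q_{ST}$ above $F_{ST}$
   indicate that among-population divergence exceeds what drift alone
   would produce.
2. **Is the divergence climate-driven?**  Clinal correlations of
   population-level trait values with climate variables (and their
   principal components), and a quadratic *transfer function* of growth
   against climate transfer distance (garden climate minus source
   climate, in PC1 units), test whether populations perform best near
   their home climate — the signature of local adaptation.

A third strand asks whether this adaptive genetic variation propagates to
the dependent arthropod community, by modeling per-tree richness (S),
abundance (A) and Shannon diversity (H') with the same hierarchical
machinery and correlating them with tree traits at the individual,
genotype and population levels.

## The hierarchical model

For a (spatially detrended) trait value $y_{igp}$ of tree $i$ of genotype
$g$ from population $p$:

$$y_{igp} = \alpha_0 + \beta_{g(p)} + \gamma_p + \varepsilon_{igp},
\qquad \varepsilon_{igp} \sim N(0, \sigma^2_W),$$

with exchangeable Gaussian random effects
$\beta_{g(p)} \sim N(0, \sigma^2_G)$ and $\gamma_p \sim N(0, \sigma^2_P)$.
The G×E variant adds garden and population×garden blocks, each with its
own variance; the transfer function further adds fixed effects of
`pc_trd` and `pc_trd`$^2$ with $N(0, 100)$ priors.  The intercept carries
a $N(0, 100)$ prior and every variance an inverse-gamma IG(1, 8) prior.

Counts (S, A) are modeled as conditionally Poisson,
$y_{igp} \sim \text{Poisson}(\theta_{igp})$, with the identical Gaussian
hierarchy on $\ln \theta_{igp}$; the residual log-scale variance
$\sigma^2_W$ is then the extra-Poisson (overdispersion) layer.  H' is
approximately normal and uses the Gaussian model directly.

### Sampling

`fitGaussianHB()` is a pure Gibbs sampler: normal full conditionals for
the intercept, fixed coefficients and each random-effect level, and
conjugate inverse-gamma updates for each variance.  `fitPoissonHB()` adds
an embedded Metropolis step: each latent log-mean $\ln\theta_{igp}$ is
updated by a per-tree Gaussian random walk whose acceptance combines the
Poisson likelihood with the $N(\mu_{igp}, \sigma^2_W)$ prior.  Proposal
scales start at 0.5 and adapt by Robbins–Monro during burnin only,
targeting ~30% acceptance (reported acceptance rates should sit in the
20–50% band).

Two implementation details matter for mixing and invariance:

* **Centering.**  Gaussian responses are centered internally and the mean
  restored in the intercept draws, so the $N(0, 100)$ intercept prior is
  location-free (day-of-year responses near 250 would otherwise sit many
  prior standard deviations from zero).
* **Location sweep.**  The intercept and each random-effect block share a
  likelihood ridge (only $\alpha_0 + \bar\gamma$ is well identified).
  After each block update the sampler resamples the split $\delta$
  between the intercept and that block from its exact conditional (a
  Gibbs move along the translation group), which raises the effective
  sample size of $\alpha_0$ and of the small-$K$ variances by one to two
  orders of magnitude.  Random effects are *not* constrained to sum to
  zero, matching the exchangeable-prior formulation.

The default schedule is 10,000 burnin + 20,000 retained draws, thinning 1;
the simulation studies in the test suite use 300–5,000 draw schedules,
which the mixing diagnostics support at the problem sizes involved
(split-chain $\widehat R$ and a crude effective sample size are computed
for every scalar parameter, with a warning above $\widehat R = 1.05$;
chains were additionally spot-checked against an independent MCMC
implementation of the identical model during development).  Credible
intervals are equal-tailed 2.5%/97.5%.

### The variance prior and its parameterization

"IG(1, 8)" is read as shape/scale: density $\propto x^{-2} e^{-8/x}$,
with conditional $\mathrm{IG}(1 + k/2,\; 8 + \mathrm{SS}/2)$.  On the
scales of field traits (dates in days, heights in cm; variances of tens
to hundreds) this prior is weak.  At unit variance it is not: the scale
parameter 8 is then several times the total variance, and with few
populations it inflates $\sigma^2_P$ (conditional mean
$(8 + \mathrm{SS}/2)/(K/2)$) and hence $Q_{ST}$.  Because the reading of
the second hyperparameter is ambiguous in the literature this package
serves, `hbPrior(parameterization = "rate")` exposes the alternative,
near-scale-free reading (density $\propto x^{-2} e^{-1/(8x)}$), whose
conditional mean is essentially $\mathrm{SS}/k$.

The package default follows the field convention (shape/scale).  The
validation suite, however, runs its parameter-recovery simulations at
unit variance scale with the weak `"rate"` prior: a recovery study must
use a prior that is weak relative to the simulated scale, or it measures
the prior rather than the sampler.  Under that prior the suite verifies
(all computed by `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R`) that the 95% $Q_{ST}$ credible interval covers
the generative value in at least 18 of 20 replicates, that posterior
means agree with REML on a large balanced design, and that the Poisson
sampler matches a lognormal fit at large means.

## Q_ST, heritability and the nine-population plug-in

$Q_{ST}$ and broad-sense heritability
$H^2 = \sigma^2_G / (\sigma^2_G + \sigma^2_W)$ are computed per draw and
summarized from the draw distribution (not as ratios of posterior means),
because the divergence test needs the full posterior of the ratio.  Draws
in which both variances fall below $10^{-12}$ are excluded and counted.
$H^2$ comes in two flavors: *hierarchical* (genotype variance within
populations, from the full model) and *collection-wide* (population
grouping omitted, genotypes pooled), reflecting two defensible poolings
of clonal replication.

Designs in which only a subset of populations carries clonal replication
cannot separate $\sigma^2_G$ from $\sigma^2_W$ for the full collection.
The plug-in estimator refits without the genotype layer (so $\sigma^2_W$
absorbs genotype plus error) and replaces $2\sigma^2_G$ with
$2 H^2 \sigma^2_W$, using the $H^2$ posterior mean from the replicated
subset; no $H^2$ uncertainty is propagated (a deliberate, simple plug-in).
The self-consistency of the two routes on identical data is part of the
acceptance suite (agreement within 0.05 in posterior mean).

A trait is called **divergent** when the $Q_{ST}$ 95% credible interval
and the $F_{ST}$ 95% confidence interval are disjoint, with the direction
(above/below) reported.

## Trait preparation

* **Bud flush interpolation.**  Flush is scored on a 5-point stage scale
  (0–4, initiation = stage 1, completion = stage 4) on several buds per
  tree every few days.  Buds are averaged to one stage value per survey
  date, stage is regressed on date by OLS per tree, and the line is
  inverted for the date at each requested stage.  Trees with fewer than
  two distinct stages or a non-positive slope are flagged and yield
  missing dates.  Flush duration is the stage-4 date minus the stage-1
  date.
* **Spatial detrending.**  Within-garden microsite heterogeneity is
  removed per trait × garden × year by a thin-plate regression spline
  over planting coordinates (`mgcv::gam`, `s(x, y, bs = "tp")`), with the
  smoothing parameter chosen by generalized cross-validation unless
  overridden.  The spline's affine null space absorbs planes exactly, so
  planar or constant fields give zero residuals; degenerate layouts (all
  trees at one coordinate) fall back to centering with a warning.  All
  downstream models consume these residuals.

## Climate analyses

The climate table (one row per population: 21 climate normals plus
latitude, longitude, elevation) is decomposed by PCA on the *correlation*
matrix; constant columns are dropped with a warning and loading signs are
fixed so each component's largest-magnitude loading is positive.  The
transfer function standardizes the response to unit variance by default
(set `standardize = FALSE` to keep trait units); "apex near zero" is
operationalized as $|{-b/2a}| < 0.5$ PC1 units, and the local-adaptation
flag additionally requires the quadratic coefficient to be negative in at
least 97.5% of draws.  The projected curve is evaluated only within the
observed transfer-distance range, with random effects set to zero (an
idealized population).  Population- and genotype-level trait values used
in climate and community correlations are posterior mean effects from the
hierarchical fits.

## Community diversity

S, A and H' are computed with vegan (H' in natural-log units).  Species
accumulation curves use seeded random orderings (default 100) or, for
seven or fewer trees, the analytic expectation over all orderings, which
the tests verify against an exhaustive enumeration.  Community–trait
correlations use Spearman rank correlation for the counts S and A and
Pearson for H', at the individual (raw values), genotype and population
(posterior mean effects) levels.  Individual-level correlations use
spatially detrended trait values.

## The synthetic garden

`simulateGardenDesign()`, `simulateTraits()` and `simulateCounts()`
generate the study conditions end to end: nine populations on a
latitudinal gradient contributing 30–60 genotypes each, planted once per
garden in three gardens, with three "local" populations contributing 20
genotypes × 6 clonal copies per garden; smooth within-garden microsite
surfaces (2–3 seeded Gaussian bumps plus a planar tilt, amplitude
configurable); Gaussian traits built from population / genotype / garden /
interaction variance layers, an optional climate slope on PC1 and an
optional quadratic transfer term; and Poisson-lognormal community counts
allocated to 53 taxa by a fixed geometric abundance profile (decay 0.85),
so S, A and H' have known expectations.  Climate PC1 is an evenly spaced,
unit-variance gradient by default, mirroring the strong
latitude–temperature axis of western North American climate extracts.

Ground truth (every drawn effect and the parameters) is returned as a
sidecar object and written as a sidecar CSV by the pipeline, never merged
into analysis inputs.  What the generator does *not* emulate — and what
passing recovery tests therefore do not certify for field data —
includes: mortality and replanting (the tables are perfectly balanced),
year-to-year measurement structure, non-Gaussian trait errors, spatial
autocorrelation beyond a smooth surface, and climate tables with real
covariance structure.  The field-scale pipeline defaults
(`runConfig()$simulate$truth`) put trait variances at 30/15/30 with mean
40, i.e. realistic day²/cm² magnitudes rather than unit scale.

## Numerical choices and degenerate inputs

* Variance draws: `1/rgamma(shape, rate = scale)`; one shared IG prior
  for all components, switchable parameterization as above.
* Q_ST/H² ratio draws with total variance below $10^{-12}$ are excluded
  (count reported); ratios are clamped to [0, 1] against floating-point
  spill.
* The Metropolis proposal adapts only during burnin (so the retained
  chain is a fixed-kernel Markov chain), clamped to [$10^{-3}$, 10].
* Pipeline outputs are rounded to 10 significant digits before writing so
  manifest MD5 hashes are platform-stable; all stage seeds derive from
  one root seed via `stageSeed()` substreams.
* Unidentifiable fits (a grouping with one level, missing responses,
  negative counts) are refused with diagnostics rather than patched.

## Validation problem sizes

The test suite and acceptance script size their simulations to the study
design where that is what is being tested (9 × 20 × 6 = 1080 trees for
Q_ST recovery; 3 local populations for the plug-in; 9 populations × 3
gardens for the transfer function) and to larger balanced designs where
asymptotic agreement is the claim (150 populations × 4 genotypes × 4
replicates for the REML comparison), with 1,000–1,500 burnin and
2,000–5,000 retained draws.  These schedules were chosen from the mixing
diagnostics at those sizes; final analyses of real data should use the
package defaults (10,000 + 20,000).

## Known limitations

* Single-chain sampling with split-chain diagnostics; no multi-chain
  $\widehat R$ out of the box (run the fit at several seeds for that).
* The plug-in $Q_{ST}$ treats $H^2$ as known; its uncertainty is not
  propagated.
* The Poisson model's taxon-level structure is reduced to per-tree totals
  (richness/abundance); no joint species-level model.
* F_ST is consumed as a published point estimate with its CI; no marker
  data are handled.
* Multiple-testing correction across traits is deliberately not applied
  in the divergence calls.
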