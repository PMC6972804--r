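---
title: "Quantitative genetics and climate projection of functional traits in a common-garden trial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative genetics and climate projection of functional traits in a common-garden trial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gardenclim)
```

## The problem this package addresses

A common-garden (provenance) trial grows trees from many source
populations, each represented by open-pollinated half-sib families, in one
plantation. Because every tree experiences the same environment,
systematic phenotypic differences among families and populations reflect
genetics rather than plasticity. `gardenclim` implements the full analysis
chain for such a trial:

1. trait construction — leaf spectral indices (PRI and the modified
   red-edge NDVI), leaf size and specific leaf area from flatbed scans,
   wood density from mass and displacement volume;
2. REML variance components and narrow-sense heritability for each trait,
   with likelihood-ratio tests for the family component;
3. population differentiation (mixed model + Tukey all-pairs comparisons
   with compact letter displays);
4. family-mean PCA and trait-pair regressions;
5. bounded-smoothness generalized additive models (GAMs) of population
   trait means on climate-of-origin, with exhaustive subset selection;
6. projection of the fitted trait-climate response over current and
   future climate rasters, proportional-change maps, and tests for
   *decoupling* of trait correlations between climate scenarios.

Every stage can be exercised end-to-end on data from the built-in
synthetic plantation generator, which has known ground truth.

## The genetic model

For a single trait, the fully random plantation model is

$$y_{ijk} = \mu + b_i + p_j + f_{j(k)} + (b f)_{ik} + e_{ijk},$$

with independent Gaussian random effects for block $b_i$, population
$p_j$, family-within-population $f_{j(k)}$, the block-by-family
interaction, and residual error. Components are estimated by REML
(`fit_random_model()`); the fit is deterministic given the data (fixed
optimizer, tight stopping rule), and components estimated at numerically
zero are reported as boundary cases.

Narrow-sense heritability uses the mixed-mating multiplier:

$$\hat h^2 = 2.5 \cdot \frac{\sigma^2_{fam}}
  {\sigma^2_{fam} + \sigma^2_{fam \times block} + \sigma^2_{error}}.$$

Under pure half-sib outcrossing the family variance is a quarter of the
additive variance and the multiplier would be 4; eucalypts self at
roughly 30%, which inflates within-family relatedness to a coefficient of
relationship of $1/2.5$, hence the default `multiplier = 2.5`
(overridable). The denominator deliberately excludes block and population
variance: it is the within-population, within-block phenotypic variance.

Three numerical choices deserve note:

* **Engine.** The REML optimum is found with `lme4`, which is the
  established mixed-model engine in R; the package additionally carries
  its own closed-form restricted log-likelihood (`reml_loglik()`), which
  is checked against the `lme4` maximum in the tests and supplies what
  `lme4` does not expose: the observed-information covariance of the five
  variance components, computed by a central-difference Hessian at the
  estimates. Boundary components are excluded from the information matrix
  and carry `NA` covariance rows.
* **Standard errors.** `heritability()` propagates the component
  covariance through the heritability ratio by the first-order delta
  method. In simulations at the trial's scale (480 trees) the mean delta
  SE tracks the empirical SD of $\hat h^2$ within a few percent, both
  about 0.09–0.10 — the magnitude typical for half-sib trials of this
  size.
* **Boundary LRT.** The family-component test refits without
  $f_{j(k)}$ and refers $2\Delta\ell$ to the mixture
  $0.5\chi^2_0 + 0.5\chi^2_1$, the standard reference when a single
  variance sits on the boundary under the null; `mixture = FALSE`
  switches to a plain $\chi^2_1$ for comparability with software that
  does not apply the correction. At a boundary estimate the statistic is
  0 and the p-value is reported as 0.5 (never `NA`), with the boundary
  flagged.

Population differentiation uses the complementary parameterization —
population fixed, family random — with single-step max-|t| (Tukey-type)
adjustment over all pairwise contrasts on a multivariate-t reference with
containment degrees of freedom `n_populations * (mean families per
population - 1)`. The compact letter display is assigned by the greedy
insert-and-absorb algorithm with populations ordered by mean; letters are
a display convention only and the tests assert their consistency with the
adjusted-significance matrix rather than a particular labelling.

## Trait construction

Spectral indices are computed **per tree from the band-wise mean spectrum
over the sampled leaves** (averaging first, then the index), matching
field practice; the alternative order (mean of per-leaf indices) differs
in general and a test documents that. Required bands (445, 531, 570, 705,
750 nm) are taken at the exact 1-nm grid value; a missing band falls back
to the nearest neighbour within ±2 nm with a logged message, and beyond
that is an error. Both indices are ratios and therefore invariant to
uniform rescaling of the spectrum, so percent versus fractional
reflectance is immaterial.

SLA pools the scanned leaves — areas and masses are summed before
division — rather than averaging per-leaf ratios; the pooled estimator is
the standard choice and is less noisy when leaves differ in size. Leaf
area is foreground pixels times the physical pixel area
$(25.4/\mathrm{dpi})^2$; scans are accepted pre-thresholded, with a
fixed-threshold binarization helper (Otsu via EBImage optionally).

## Trait–climate models

Population-level trait means (n = 12 populations) are regressed on
climate-of-origin with Gaussian identity-link GAMs. Smoothness is bounded
hard: each covariate enters as a cubic regression spline with basis
dimension $k = 3$, i.e. at most two effective df per term after the
sum-to-zero constraint, and at most three covariates per model — the
bound is read as mgcv's `k = 3` convention, which is our interpretation
of "degree of smoothness three" (recorded as such, not as fact). With an
intercept this caps the total effective df at 7, structurally below the
12 observations; the cap is asserted in the tests, and exceeding n is a
hard error, not a warning. Smoothing parameters are chosen by GCV
($\gamma = 1$); deviance explained equals variance explained for the
Gaussian family; per-term F statistics are mgcv's Wald-type tests on the
penalized coefficients — conventions for reference df differ among
implementations, and this package documents its own rather than claiming
equivalence to any other.

Model selection enumerates all subsets of one to three candidates (63
models for seven candidates) and ranks by deviance explained, ties broken
by fewer variables and then lexicographically.

**A known limitation, measured honestly.** At n = 12 with flexible
smooths, candidate models are near-saturated (deviance explained
typically above 99%) and the regional climate variables are strongly
collinear (e.g. maximum summer temperature against driest-month
precipitation at r ≈ −0.76 across the twelve populations). The argmax
over subsets is therefore partly noise-driven: in simulations where one
variable truly generates the population means at a 5:1 signal-to-noise
ratio, the selected model contains the generating variable in roughly
70–90% of repeats depending on the candidate set — not essentially
always. Selected variable *sets* should be read as families of correlated
predictors with comparable support, not as causal attributions; the
deviance explained of the winner is far more stable than its identity.

## Landscape projection and decoupling

`predict_surface()` evaluates a fitted GAM over co-registered climate
raster stacks (ESRI ASCII grids; row 1 is the northernmost row,
cell-centre registration). Cells where any covariate leaves the fit's
training range are still predicted but flagged in an extrapolation mask
and excluded from summaries by default. Proportional change is
$(\mathrm{future} - \mathrm{current})/\mathrm{current}$ per cell; because
indices such as PRI cross zero, cells with $|\mathrm{current}|$ below
$10^{-6}$ times the 95th percentile of $|\mathrm{current}|$ are marked
undefined rather than producing unbounded ratios. Change summaries report
mean, range and the shares of cells increasing and decreasing, over
defined, non-extrapolated cells only.

The decoupling test regresses the y-trait surface on the x-trait surface
within each scenario and tests slope equality via the scenario-by-x
interaction in the stacked regression (`car::linearHypothesis`), which is
algebraically the pooled-variance two-sample slope test — an identity the
tests verify to 1e-9. Pixels are treated as independent observations, as
is conventional for this analysis; no spatial-autocorrelation correction
is applied, and the output records that assumption. With tens of
thousands of pixels the test will flag minute slope differences as
significant; effect sizes (the slopes themselves) matter more than the
p-value at that n. Extrapolation-flagged pixels are excluded unless
explicitly included.

## The synthetic plantation generator

The generator is first-class, tested code, and its defaults are the study
conditions, not tuning knobs:

* design: 6 blocks; either 4 populations × 10 families × 12 replicates
  (the heritability layout) or 12 populations × 10 families × 4
  replicates (the modelling layout); both 480 trees;
* seven traits at field-realistic means and spreads with target
  heritabilities 0.08–0.22 (the published range), family variance derived
  as $h^2 \sigma^2_P / 2.5$, a 10% family-by-block share and a 5% block
  share of phenotypic variance;
* genetic correlations of ±0.5 on the four canonical trait pairs
  (negative for wood density against nitrogen concentration, positive for
  the other three), applied to family effects; residuals uncorrelated by
  default; block and block-by-family effects independent across traits so
  that recovery by the fitted model is well-posed;
* population means shift deterministically along the real
  climate-of-origin of the twelve study populations
  (`population_climate()`). The three candidate climate variables not
  available from the published table (mean annual temperature,
  temperature range, precipitation range) are deterministic synthetic
  complements built from the published variables plus latitude/longitude
  terms — they are plausible for southwestern Australia and deliberately
  not near-duplicates of their parents, and are documented as synthetic
  throughout;
* climate rasters are affine gradient fields spanning the populations'
  climate ranges, with future offsets defaulting to a hotter, drier
  scenario (+2.8 °C summer maximum, −120 mm annual precipitation, etc.)
  and an optional elliptical distribution mask.

What the generator does **not** emulate: spatial autocorrelation of the
field microenvironment, non-Gaussian trait distributions, dominance and
epistasis, and real raster geometry (coastlines, topography). Passing
tests therefore demonstrate that the estimators recover the parameters of
the Gaussian half-sib world they assume — they do not validate the
biological assumptions against real plantations.

## Problem sizes used in the tests

The simulation-based checks run at the trial's own scale: heritability
recovery uses 200 datasets of 480 trees (mean $\hat h^2$ within ±0.03 of
0.20; delta SE within 25% of the empirical SD), LRT calibration 500 null
datasets (rejection rate within [0.03, 0.07] at α = 0.05), selection
recovery 100 repeats of 12 population means, and slope-equality
calibration 500 repeats of 1,000 pixels per scenario. The acceptance
script scales some replicate counts down (60/200/40) to keep a single run
short while reporting the replicate count alongside every value.

## A worked example

```{r example, eval = FALSE}
library(gardenclim)

cfg <- plantation_config()              # 4 x 10 x 12 in 6 blocks
sim <- simulate_plantation(cfg, seed = 1)

h <- estimate_heritability(sim$table, "N_CONC")
h
#> h^2(N_CONC) = 0.202 +/- 0.094 SE

cmp <- diff_populations(sim$table, "d13C")
cmp$letters

cfg2 <- plantation_config(n_populations = 12, replicates_per_family = 4)
sim2 <- simulate_plantation(cfg2, seed = 2)
pm <- population_means(sim2$table)
cli <- cfg2$climate[match(pm$population, cfg2$climate$population), ]
sel <- select_climate_gam(pm$SLA, cli)
sel$winner

rs <- simulate_climate_rasters(n_rows = 40, n_cols = 40, mask = "ellipse")
cur <- predict_surface(sel$winner, rs$current, "current", mask = rs$mask)
fut <- predict_surface(sel$winner, rs$future, "future", mask = rs$mask)
summarize_change(change_map(cur, fut))
```

## Known limitations

* Raster IO is ESRI ASCII grid only; there is no GDAL binding, so
  GeoTIFF stacks must be converted before use, and no
  reprojection/resampling is offered (inputs must be co-registered).
* The heritability model assumes half-sib families with a constant
  coefficient of relationship; pedigree structure beyond that (dominance,
  full-sib contamination varying by family) is out of scope.
* Multivariate (genetic-correlation) REML is not implemented; trait
  correlations are assessed on family means.
* Subset selection instability at n = 12 (above) is a property of the
  method, not fixable by implementation; treat selected variables as
  correlated families.
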