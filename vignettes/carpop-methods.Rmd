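---
title: "Estimating internal displacement from satellite car detections: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating internal displacement from satellite car detections: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carpop)
```

## The problem and the modelling idea

Internally displaced people are hard to count: surveys are slow and
dangerous in active conflict, and administrative data lag. Cars are a
visible proxy. In very-high-resolution satellite imagery (ground sampling
distance 0.3–0.5 m) individual cars can be detected by a CNN object
detector; a baseline year with reliable gridded population establishes how
many people correspond to how many visible cars in each square kilometer of
a city; and the change in visible cars in later months then translates into
a change in population. `carpop` implements the full chain downstream of the
detector: detection post-processing, image screening, gridded car dynamics,
and two population-prediction models whose disagreement is itself the
uncertainty statement.

All geometry is planar, in meters, in a local Cartesian frame. The analysis
grid must be metric (1 × 1 km cells), so real-data inputs have to arrive in
a metric projected CRS; the synthetic world used for validation is generated
directly in such a frame, which keeps projection noise out of the oracle
tests. Intersections are computed by convex clipping (Sutherland–Hodgman):
cells, footprints and areas of interest (AOIs) are rectangles, so every clip
in the pipeline has a convex operand.

## Detection post-processing

The upstream detector emits point detections with confidence scores and
class labels; only the "small car" class is processed (other classes are
dropped with a reported count). Two decisions the upstream literature leaves
open had to be made explicit:

* **Detection–truth matching.** For threshold tuning, detections are matched
  one-to-one to ground-truth car points greedily by increasing distance,
  with a 2.5 m acceptance radius — about half a car length, the natural
  scale for point (not box) detections at this resolution. Greedy matching
  is deterministic and order-independent given distinct distances; a
  quadratic reference implementation in the test suite confirms the
  bucket-hash implementation.
* **Tie-breaking in the threshold sweep.** Among thresholds attaining the
  maximal F-beta, the largest is chosen. With beta = 0.5 the sweep already
  favors precision; the tie rule keeps that preference.

The F-beta score itself is

$$F_\beta = (1+\beta^2)\,\frac{P \cdot R}{\beta^2 P + R},$$

defined as 0 when the denominator vanishes. It is strictly monotone in each
of precision and recall, which the tests assert on a grid.

False-positive filtering removes every detection inside (or on the boundary
of) a tagged exclusion polygon — water, cropland, forest, parks, runways.
Boundary points count as inside: removal is the conservative choice, and the
synthetic generator places injected false positives at least 5 m inside
polygon boundaries (and true cars at least 2.5 m outside them, beyond the
localization jitter), so the tests are unambiguous about which side of the
boundary a detection belongs to.

## Image screening

An image is useful only if it sees enough of the city. The
population-coverage index of image *i* in AOI *s* is

$$p_{i,s} = 100 \cdot \frac{\sum N_{i,s}}{\sum N_s},$$

the percent of the AOI's baseline population under the footprint. Fine
(100 m) population cells straddling the footprint boundary contribute in
proportion to the intersected fraction of their area, which is unbiased when
people are uniform within a fine cell. The index is used on the 0–100
percent scale with a drop threshold of 50: the defining formula multiplies
by 100, and the screening rule is "less than 50%", so the percent scale is
the consistent reading.

Cloud screening is automated here: images with cloud fraction at or above
0.95 are dropped as fully obstructed, and kept images with cloud fraction in
[0.5, 0.95) are flagged for review. The original workflow used visual
inspection for partially clouded images; a configurable numeric rule is the
reproducible stand-in, and the flag preserves the review intent. Kept images
with fewer than 10 detections are flagged as suspicious (possible false
zeros under haze) rather than silently trusted, and images covering less
than 1% of the AOI area violate the ingest contract and are rejected with a
reason (`drop_area` — a decision category added so the reason is not
mislabelled as a population-coverage failure). No image is ever silently
discarded: the screening report retains every image with its decision and
reason, and screening the kept set again is a no-op (idempotence is tested).

## Gridded car dynamics

Cells are axis-aligned 1 km squares with the grid origin snapped to
multiples of 1000 m in the world frame, so cell identities are reproducible
across runs and periods. Detections are assigned by half-open intervals
[x0, x0+1000) × [y0, y0+1000): a point on a shared edge belongs to exactly
one (the right/upper) cell, and per-image counts conserve the number of
in-grid detections exactly.

Two rules the source workflow does not state are made explicit and
configurable:

* a cell counts as *covered* by an image when at least 50% of its area lies
  inside the footprint — sliver coverage would otherwise bias monthly means
  low;
* monthly cell means average over the covering images only, and a cell-month
  with no covering image is *absent*, never imputed as zero.

Car density is cars per km² of covered area (the denominator uses covered
cells only, mirroring the standardization of counts by imaged area).
Relative change versus the baseline year is computed per city, and at oblast
level the city densities are averaged first, then the change is taken
(average-then-change); units lacking data in either period are reported as
missing with a reason. For war-period comparisons, conflict-year images
acquired before the configurable cut date (default 2022-02-24) are set
aside, and quarterly aggregation uses calendar quarters.

## The two population models

Estimation is restricted to *matching months* — calendar months observed in
both the baseline year and a comparison year — to avoid seasonality
artifacts, and within a month to *matching cells* present in both periods.
Baseline months are pooled into per-cell means of cars; baseline people come
from the gridded baseline population.

**Ratio method.** Each cell's ratio $r_{s,z} = y_{s,z} / x_{s,z}$ multiplies
the comparison month's mean cars. Cells with zero baseline cars borrow the
*global median* of the defined ratios. The median's scope is per city by
default: car-ownership rates, parking structure and transit access differ
between cities, so borrowing a ratio from another city would import its
car culture. A `scope = "global"` switch provides the pooled alternative
reading. The method predicts zero people wherever no cars are visible,
which makes it the aggressive, lower-bound-style estimator.

**Regression method.** A penalized cubic-regression-spline Poisson
regression with log link,

$$Y_i = \exp\big(\beta_0 + f(X_i) + \varepsilon_i\big),$$

fitted through `mgcv` with REML smoothing-parameter selection and basis
dimension 10 by default (capped at one basis function per two cells, never
below 4 — near-saturated bases on small cities are a numerical hazard, not a
better fit). Pooled monthly means are non-integer, so the quasi-Poisson
family is used: identical score equations, with the dispersion estimated and
reported rather than assumed 1. Degenerate predictors (constant cars) fall
back to an intercept-only fit with a warning; non-convergence is an error
carrying the problem size. The model records its training range of cars and
flags predictions outside it instead of silently extrapolating. Predictions
are strictly positive everywhere — including emptied cells — which makes the
regression the milder, upper-bound-style estimator. Goodness of fit is
reported as deviance explained and an R²-type statistic, with fits below a
documented 60% threshold labelled low-confidence (not suppressed).

City-level estimates are the exact sums of their matching-cell predictions.
The tests assert the two methods' characteristic behaviors: the ratio method
is exact to 1e-9 in a noiseless proportional world under any displacement
field; the regression method recovers a known 40% city-level drop within 15
percentage points in median over 20 simulation seeds (n = 500 cells, Poisson
noise); and on emptied-cell scenarios the regression's absolute percent
change is at most the ratio method's in the majority of seeds (the
dampening property). The strict bracket ratio ≤ truth ≤ regression is *not*
asserted — it is the typical ordering, not a guarantee.

## Imagery-feature diagnostics

A Gaussian linear model of log car density (detections / imaged km²) on
image resolution (categorical, reference 0.3 m), snow presence (reference
absent), off-nadir angle, sun elevation and cloud coverage quantifies how
acquisition conditions affect detectability. Zero-detection images have
undefined log density and are excluded with a reported count (an offset
formulation was rejected: the response is a density, not a count, once
standardized). Covariates without variation are dropped with a warning;
a design that remains collinear is an error naming the offending columns.
Coefficients for this model depend entirely on the imagery set at hand, so
the module is validated by simulation (coefficient recovery with honest
interval coverage) rather than against any published coefficient table.
Residual diagnostics cover normality (Shapiro–Wilk), homoscedasticity
(Breusch–Pagan plus a variance-trend statistic) and independence (lag-1
residual autocorrelation in acquisition-time order, Durbin–Watson). A
possible non-linearity in the off-nadir effect (detectability peaking near
25°) is documented but not modelled: only the linear term is specified.

## The synthetic world

`generate_world()` builds the validation environment: several square AOIs
(cities) with 100 m population rasters composed of Gaussian hotspots over a
uniform floor; a monotone link E[cars] = a·people^b per fine cell (default
a = 0.04, b = 1 — about one visible car per 25 residents, a plausible
city-scale rate) with Poisson count noise matching the estimation model's
observation family; per-month image counts, footprint fractions, resolution,
angles, cloud and snow drawn from configurable distributions; false
positives injected inside exclusion polygons at a configurable intensity
with Beta-distributed low scores (true cars score high), so the threshold
sweep is informative; and a per-city multiplicative displacement scenario
(default: baseline 1.0 in 2019, 0.9 everywhere in 2020, then 0.45 in the
"East" half of cities and 1.8 in the "West" half in 2022, the
East-drop/West-rise pattern of a westward displacement wave). Expected
detection counts are attenuated by the covered fraction of each cell and by
(1 − cloud fraction); a fully clouded image yields nothing.

What the generator deliberately does **not** emulate: road networks and the
spatial clustering of parked cars (points are uniform within cells),
detector miss rates that vary with context (every true car yields a
detection; recall at threshold 0 is 1), garages and parking structures that
hide cars from above, border-crossing queues, and any pixel-level imagery
effects. Passing tests therefore demonstrate that the *statistical
machinery* is correct under its own assumptions — conservation, exactness,
recovery, dampening — not that the car-to-people link holds in any real
city; on real data the link is an empirical hypothesis that the two-method
bracket is designed to hedge.

Determinism is a contract: the same configuration and seed reproduce every
exported file bit-for-bit (hash-compared in the tests), and the pipeline
manifest records file hashes, configuration and per-stage record counts so a
run's data funnel (images kept, detections removed per filter, cities
retained) is auditable.

## Numerical choices and problem sizes

* Thresholds: confidence 0.45, beta 0.5, sweep step 0.05 (21 thresholds),
  population coverage 50%, cloud drop 0.95 / review 0.5, low-count flag 10,
  cell coverage 0.5, cut date 2022-02-24 — all configurable in
  `run_config()`.
* Threshold tuning inside `run_pipeline()` uses a deterministic sample of
  images capped at roughly 19,000 ground-truth annotations, mirroring the
  scale of the tuning protocol the operating point comes from.
* The cubic regression spline's natural boundary conditions (zero second
  derivative at the range ends) limit pointwise accuracy where the true
  link is strongly curved at the boundary; the interpolation tests assert
  mean relative accuracy and the exact prediction-equals-fit identity at
  training points rather than a pointwise bound at the extremes.
* Test problem sizes are the package's own validation choices: two-city
  3 km worlds for pipeline contracts, 20–40 simulation seeds with n = 500
  cells for the model-recovery properties, 25 replicates for the
  sign-recovery property, and the default 4-city 5 km world (about 100
  images) for the count-conservation sweep.

## Known limitations

* The population-to-car link is assumed stable between the baseline and
  comparison years at the cell level; behavioral change (fuller cars when
  fleeing, hidden cars under occupation) biases both methods in ways no
  within-pipeline check can detect.
* Cells uncovered in a comparison month are excluded from both sums, never
  interpolated; months with low area coverage can therefore swing estimates
  and are reported with their coverage percent for exactly that reason.
* The regression method requires enough cells (10 by default) and variation
  in car counts; tiny AOIs fall back to the ratio method alone.
* No spatial correlation, state-space dynamics or daily forecasting: the
  estimator is month-by-month and cell-independent by design.
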