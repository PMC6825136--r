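---
title: "Pollen–climate transfer functions and h-block cross-validation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pollen–climate transfer functions and h-block cross-validation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the statistical models the package implements, the
assumptions they make, every tunable constant with its default and
rationale, and the design decisions taken where the methodology is
genuinely open. The worked numbers shown in the README are produced by the
code itself; nothing here asserts an empirical result that the test suite
or `scripts/acceptance.R` does not compute.

## 1. Data model

All assemblage data are held as site × taxon percentage matrices
(`taxon_table`, rows summing to 100). Percentages are the canonical unit;
proportions (0–1) are derived internally where a formula needs them
(squared chord distances, MAT). Counts are converted on load with
`percent_normalize()`, which errors on a zero-sum sample rather than
silently producing `NaN`. A calibration set bundles the percentage table
with per-site geography (lon/lat in decimal degrees WGS84, longitudes
normalized to [−180, 180], elevation in metres) and per-site climate
values; the three components must agree exactly in site identity and
order, which is checked at construction rather than at use.

Site-to-site distances are haversine great circles on a sphere of radius
6371.0088 km (the IUGG mean radius). At the 100-km granularity of the
*h* grid the difference from an ellipsoidal geodesic (< 0.5%) is
immaterial, and a closed-form distance keeps the n² distance matrices
cheap.

Gridded climate is read from ESRI ASCII rasters (one file per variable
plus one elevation file; the nodata sentinel comes from the header).
Extraction is bilinear from the four nearest cell centres, dropping
nodata cells with weight renormalization. The lapse-rate correction
subtracts `rate × (site_elev − grid_elev)/1000` with a default rate of
6.4 °C/km — the standard environmental lapse rate; it is applied only
when `apply_lapse = TRUE`, because the correction is physically
meaningful for air temperature but not for precipitation-derived
variables.

## 2. Calibration methods

All eight methods sit behind `fit_model(spec, X, y)` / `predict()`. The
square-root transform of the percentages is applied inside WA and WAPLS
only; MAT works on proportions and the machine-learning methods take raw
percentages (the tree ensembles are invariant to monotone predictor
transforms anyway).

**MAT.** k-nearest-neighbour prediction in assemblage space under the
squared chord distance `Σ(√p − √q)²` (range 0–2), k = 5 by default. The
analogue weights are inverse distance; an analogue at distance
< 1e-12 short-circuits to the unweighted mean of the zero-distance
analogues, avoiding a division blow-up on exact matches. Ties at the k-th
distance are broken by training-row order, making predictions
deterministic.

**WA.** Taxon optima are abundance-weighted means of the response on
sqrt-transformed percentages, tolerances the abundance-weighted standard
deviations. Tolerances are floored at
`max(1% of the response range, smallest positive tolerance)`: a taxon
occurring at a single site has raw tolerance 0, and inverse-squared
tolerance weights would otherwise give it unbounded influence. Three
deshrinking rules are available; the default is monotonic —
pool-adjacent-violators isotonic regression of observed on raw scores
with linear interpolation between knots and end-slope linear
extrapolation. Isotonic regression fulfils the monotonicity contract
without committing to a spline basis; a pooled (flat) end block
extrapolates flat, which is the conservative choice at the gradient ends.
A negative raw-score/response association (possible in principle) is
handled by fitting the antitonic map.

**WAPLS.** The iterative WA-PLS cycle on sqrt-transformed percentages:
taxon scores are abundance-weighted averages of the current working
response, site scores abundance-weighted averages of the taxon scores,
components are orthogonalized against earlier ones, and the response is
regressed on the scores by *ordinary* least squares. Using OLS (rather
than site-total-weighted regression) for both the orthogonalization and
the final regression makes the one-component model *exactly* equal to WA
with inverse deshrinking and no tolerance down-weighting — a property the
test suite asserts to 1e-8 — and is the inverse-style deshrinking choice.
Degenerate components (score variance below 1e-10 of the response scale)
truncate the model to the largest feasible component count with a
warning instead of failing.

**Tree ensembles.** RF is a 100-tree bagged forest (randomForest).
ETREES is the extremely-randomized-trees algorithm via ranger
(`splitrule = "extratrees"`, 5 random cut candidates, no bootstrap, all
predictors available at each split); its tree count is not part of the
standard parameterization, so it shares RF's 100. BRT is squared-error
gradient boosting via xgboost with depth-4 trees, shrinkage 0.025, bag
fraction 0.5 and up to 3000 trees, the count chosen by internal 5-fold
cross-validation with early stopping (50 rounds) on the training
partition; `relative_influence()` reports the per-taxon reduction-in-loss
(gain) shares normalized to 100.

**Neural networks.** NNET is a single sigmoid hidden layer with linear
output trained to squared error (nnet; quasi-Newton, 500 iterations, no
decay). The ELM trains 5 independent networks with uniform U(−1, 1)
hidden weights, a rectified ("positive") linear hidden activation, and
least-squares output weights, averaging the 5 predictions. Both scale
predictors to proportions (÷100) and both require an explicit
hidden-layer size: the standard values are calibration-set specific
(`method_defaults()` prints them), so the package refuses to guess for a
new dataset. Hidden-weight distribution, training regime and predictor
scaling are design choices of this package, not settled methodology.

Every stochastic method is seeded from its `method_spec`; inside
cross-validation each (method, h, fold) gets a deterministic seed derived
from the master seed, so a full series is reproducible and folds may be
evaluated in any order.

## 3. h-block cross-validation

For test site *i* the training set is `{j ≠ i : d(i, j) > h}` — a closed
ball is excluded, so a site at exactly *h* km is removed and `h = 0` is
literally leave-one-out. A fold whose training set falls below the
method's minimum viable size, `max(k, n_components + 1, 10)`, records a
missing prediction rather than aborting: at large *h* the folds thin
drastically and a partial series is more useful than none. Summary
metrics are RMSEP, the maximum bias (largest absolute mean residual over
the 10 equal-length segments of the observed climate gradient; empty
segments are skipped), and R², taken as the squared Pearson correlation
between observed and predicted — the common convention in this
literature; note it differs from 1 − SSE/SST when predictions are biased.
Two diagnostics accompany them: the median fraction of calibration data
lost per fold, and the median squared-chord distance to the best
remaining analogue, both provably non-decreasing in *h*.

## 4. Variogram-based selection of h

The optimal radius is estimated as the range of a circular variogram
fitted to the residuals of a standard WA model under leave-one-out. The
empirical variogram uses 15 equal-width lag bins up to half the maximum
pairwise distance (standard geostatistical practice). The circular model

γ(d) = c₀ + c·[1 − (2/π)·arccos(d/a) + (2d/(πa))·√(1 − (d/a)²)],  d ≤ a

is fitted by weighted least squares (weights = pair counts) with
multi-start over ten initial ranges spanning the lag range, keeping the
lowest weighted SSE. Whether the original methodology used weighted or
ordinary least squares is unstated; pair-count weighting is the standard
choice because bin precision is proportional to pair count.

A fitted range is only reported when the spatial structure is
statistically supported: the circular fit must beat a flat (pure-nugget)
model in a weighted-least-squares F-test of its 2 extra parameters at the
0.95 level, and carry a partial sill of at least 2.5% of the total sill.
Otherwise the fit is flagged `no_spatial_structure` and
`estimate_best_h()` returns *h* = 0 — when residuals are spatially
independent, leave-one-out is already unbiased and no exclusion is
warranted. The reported *h* is the fitted range rounded *up* to the
100-km grid granularity (an exclusion radius slightly larger than the
correlation range errs on the safe side).

## 5. Variable selection

`spearman_matrix()` computes pairwise Spearman ρ with average-rank ties;
`max_uncorrelated_subset()` finds a maximum-cardinality subset with all
pairwise |ρ| below 0.7. For ≤ 25 variables the search is exact (maximum
independent set of the conflict graph); beyond that a greedy
max-degree-removal heuristic is used. Both are deterministic, breaking
ties by variable-name order, and a `keep` argument forces named variables
into the subset. `ensemble_r2_ranking()` then ranks candidates by mean
cross-validated R² across a pluggable model set, defaulting to this
package's eight methods — the ranking logic, not any particular historical
tool roster, is the reusable method. The remaining steps of the published
workflow (an ordination-based independence check and an ecological
credibility judgement) are expert decisions; the CLI prints a checklist
instead of pretending to automate them.

## 6. Reconstruction and SiZer

`reconstruct()` restricts calibration and fossil matrices to their shared
taxa (re-normalizing rows to 100 and reporting the percentage mass each
sample lost), fits each requested method on the full calibration set, and
predicts every fossil sample, recording the squared-chord distance to the
closest modern assemblage as an analogue-quality flag.

`sizer_map()` classifies trends at every (time, bandwidth) cell. At each
cell a local-linear fit with Gaussian kernel weights estimates the slope;
its standard error uses the sandwich form (kernel weights are not inverse
variances) with the residual variance inflated by ESS/(ESS − 2), where
ESS = Σw/max(w) is the effective sample size. The confidence interval is
simultaneous in the Bonferroni sense across the m(b) = max(1,
range/(2b)) effectively independent blocks at bandwidth b. Cells with
ESS < 5 are "insufficient" — this cutoff draws the available-bandwidth
envelope. The bandwidth grid is log-spaced with 25 values from twice the
median sample spacing to half the record length; the time grid has 101
points. A numerical slope floor of 1e-9 × (value scale)/(age range) keeps
a constant series "flat" instead of classifying rounding noise; because
the floor scales with the data, SiZer categories are invariant under
positive affine rescaling of the value axis. Slopes are taken with
respect to increasing age; `time_forward = TRUE` flips the labels so
"rise" means rising toward the present.

## 7. The synthetic generator

The generator emulates exactly the structure the analyses assume: site
coordinates uniform over a 2000-km box (mapped to lon/lat around a
reference latitude; the Gaussian-process covariance is computed from the
*final* great-circle distances, so the planted range is exact in the same
metric the variogram estimator uses); two climate fields with circular
covariance (default range 400 km, 5% nugget) affinely mapped to July-like
(15 ± 2.8 °C) and January-like (−8 ± 6 °C) temperatures; cross-variable
correlation induced by mixing against the in-sample-orthogonalized second
field, so the sample correlation hits the target (default ρ = 0.05)
rather than only its expectation — under spatial autocorrelation the
number of effective replicates is far below the number of sites, and
naive mixing would scatter the realized correlation widely.

Taxon responses are bivariate Gaussian: expected abundance
`A·exp(−(x₁−o₁)²/2t₁²)·exp(−(x₂−o₂)²/2t₂²)`, with half the taxa
responding only to the primary variable, 20% only to the secondary, and
the rest to both. Optima are drawn uniformly within ±2.5 standard
deviations of each climate mean — inside the sampled gradient, which is
the regime weighted averaging assumes (an optimum outside the data cannot
be recovered by any abundance-weighted mean). Tolerances are 10–20% of
the six-sigma gradient span, i.e. the gradient is 5–10 niche breadths
long; broader niches shrink abundance-weighted means toward the gradient
centre by σ²/(σ² + t²) and heterogeneously so, which degrades optimum
recovery for every method, not just WA. Counts are multinomial with a
pollen sum of 300 per sample (a typical counting effort);
`count_depth = Inf` gives the noiseless limit used by the recovery
oracles.

What the generator does *not* emulate: realistic taxonomies or taxon
richness gradients, skewed or multimodal responses, taphonomic biases,
non-analogue fossil climates, or age-model error. Passing tests therefore
demonstrate the estimators' correctness and their behaviour under the
stated statistical structure — not performance on any real calibration
dataset.

Fossil sequences are generated from a user-supplied (age, x₁, x₂)
trajectory with the same taxon community as the calibration set
(deterministically re-derived from the configuration seed). The test
trajectories stay within ±1.5 standard deviations of the calibration
gradient: tree ensembles are piecewise-constant and cannot extrapolate,
so a trajectory spending most of its time beyond the well-sampled
gradient saturates them — a real limitation of these methods near the
calibration fringe, not an artefact.

## 8. Problem sizes and limitations

The test suite and acceptance script use 100–300-site calibration sets,
30 taxa, and 4–5-point *h* grids — sizes chosen so the full synthetic
suite runs in a few minutes on one CPU while leaving every estimator
comfortably identified (300 sites support a 15-bin variogram; 20-seed
replication bounds the stochastic checks).

Known limitations: the *h*-estimate is conservative when residual
structure is weak relative to counting noise (the F-test then returns
*h* = 0 with a flag — on such data leave-one-out is defensible, but users
expecting the published 200–600-km estimates should check the flag); R²
is correlation-based by convention; the exclusion boundary at exactly
*h* km is inclusive by definition here but unstated in the wider
literature; and sites with exactly duplicated coordinates are excluded
from each other's training sets even at *h* = 0, where leave-one-out and
h-block then differ.
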