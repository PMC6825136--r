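# paleotf

Pollen–climate transfer functions with variable-radius *h*-block spatial
cross-validation.

## The problem

Quantitative palaeoclimate reconstruction trains a statistical model on a
*calibration set* — modern surface-sediment pollen assemblages paired with
observed climate at the same sites — and applies it to fossil assemblages
to infer past climate. Two chronic difficulties motivate this package:

1. **Spatial autocorrelation inflates cross-validation skill.** Nearby
   calibration sites are pseudo-replicates: a model can "predict" a
   held-out site simply by matching its neighbours, so leave-one-out
   cross-validation overstates reconstruction ability. The *h*-block
   scheme removes, for each held-out site, every training site within a
   radius *h*; running a whole series of *h* values (0–1500 km) maps how
   performance degrades as analogues are withdrawn, and the range of a
   circular variogram fitted to the residuals of a weighted-averaging
   model gives an independent estimate of the *h* that removes
   pseudo-replication without starving the model of data.
2. **Secondary climate variables are hard to reconstruct.** Variables with
   a smaller ecological effect (winter temperature, water balance) ride on
   the coat-tails of the primary one (summer temperature). The package
   includes the screening workflow — Spearman correlation filtering at
   |ρ| < 0.7 plus cross-validated ensemble R² ranking — used to choose
   variables whose effects can be modelled independently.

## What is implemented

* **Eight calibration methods** behind one `fit_model()` / `predict()`
  contract: the modern analogue technique (MAT; weighted mean of the *k* = 5
  closest assemblages by squared chord distance
  `d(p,q) = Σ(√pᵢ − √qᵢ)²`), weighted averaging (WA; taxon optima
  `uₖ = Σᵢyᵢₖxᵢ/Σᵢyᵢₖ`, tolerance down-weighting, monotonic deshrinking),
  WA partial least squares (WAPLS, 3 components), random forests (100
  trees), extremely randomized trees (5 random cuts), boosted regression
  trees (depth 4, shrinkage 0.025, bag fraction 0.5, tree count by
  internal 5-fold CV), and two single-hidden-layer neural networks (NNET
  and an extreme learning machine averaging 5 networks).
* **The *h*-block CV engine** (`run_hblock_cv()`, `run_cv_series()`) with
  RMSEP, maximum bias (worst mean residual over 10 equal segments of the
  climate gradient), R², data-loss and best-analogue diagnostics, and
  variogram-based radius selection (`estimate_best_h()`).
* **Variable selection** (`spearman_matrix()`, `max_uncorrelated_subset()`,
  `ensemble_r2_ranking()`).
* **Reconstruction and trend significance**: `reconstruct()` applies
  fitted models to dated fossil sequences; `sizer_map()` classifies every
  (time, bandwidth) cell of the reconstruction as a significant rise,
  fall, flat, or insufficient data (SiZer: local-linear Gaussian-kernel
  fits across a log-spaced bandwidth family).
* **A synthetic-data generator** (`gen_calibration()`, `gen_fossil()`)
  producing spatially autocorrelated climate surfaces, unimodal taxon
  responses to a primary and a weakly correlated secondary variable, and
  multinomial count noise — so the whole pipeline is testable without any
  external database.

## Worked example

```r
library(paleotf)

cfg <- synthetic_config(n_sites = 200, seed = 42)
cal <- gen_calibration(cfg)
cal
#> calibration_set: 200 sites, 30 taxa, climate variables: T_jul, T_jan

series <- run_cv_series(cal, cv_spec(
  h_grid = c(0, 200, 400, 800),
  methods = list(method_spec("MAT"), method_spec("WA")),
  response = "T_jul"))
summary(series)
#>     h method response     rmsep max_bias        r2 n_predicted median_data_loss
#> 1   0    MAT    T_jul 0.4964332 2.324246 0.9754759         200       0.00000000
#> 2 200    MAT    T_jul 0.5237340 2.421001 0.9734497         200       0.03015075
#> 3 400    MAT    T_jul 0.5595185 2.739811 0.9707345         200       0.10301508
#> 4 800    MAT    T_jul 0.7268075 3.458931 0.9522356         200       0.33165829
#> 5   0     WA    T_jul 0.5512223 2.070754 0.9666277         200       0.00000000
#> 6 200     WA    T_jul 0.5642604 2.148624 0.9650138         200       0.03015075
#> 7 400     WA    T_jul 0.6042892 2.268944 0.9601840         200       0.10301508
#> 8 800     WA    T_jul 0.6981555 3.516520 0.9481098         200       0.33165829
```

Read this as the classic *h*-block picture: RMSEP grows as the exclusion
radius removes nearby pseudo-replicates (MAT, which leans hardest on close
analogues, deteriorates fastest — its RMSEP rises 46% from *h* = 0 to
800 km), while the median data-loss fraction and the median squared-chord
distance to the best remaining analogue increase monotonically with *h*.

The variogram-based radius estimate is honest about weak structure. On the
dataset above, the WA residuals are dominated by counting noise and the
circular-variogram fit finds no significant spatial structure, so
leave-one-out is already unbiased:

```r
estimate_best_h(cal, "T_jul")
#> best h for T_jul: 0 km (no spatial structure in WA residuals)
```

On a calibration set whose residuals do carry spatial structure (here, the
assemblages are driven by the secondary variable, leaving a 400-km-range
signal in the WA residuals for T_jul), the fitted range is returned,
rounded up to the 100-km grid:

```r
cfg2 <- synthetic_config(n_sites = 300, prop_primary = 0,
                         prop_secondary = 1, seed = 3)
estimate_best_h(gen_calibration(cfg2), "T_jul")
#> best h for T_jul: 400 km (variogram range 331.5 km)
```

## Command line

A thin CLI wraps the same functions (see the header of the script for all
subcommands):

```sh
Rscript inst/cli/paleotf.R simulate --seed 42 --out data/
Rscript inst/cli/paleotf.R cv --data data/ --response T_jul \
    --methods MAT,WA,WAPLS --h 0:800:200 --out results.csv
Rscript inst/cli/paleotf.R best-h --data data/ --response T_jul
```

## Vignette

`vignettes/transfer-functions.Rmd` documents the models and their
assumptions, every tunable constant with its default and rationale, what
the synthetic generator does and does not emulate, and known limitations.
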