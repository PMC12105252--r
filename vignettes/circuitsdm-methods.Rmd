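---
title: "Methods: ensemble niche models and circuit-theory connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble niche models and circuit-theory connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`circuitsdm` implements, as one tested pipeline, the analysis chain used in
habitat-suitability and landscape-connectivity studies of range-restricted,
dispersal-limited species such as stream-breeding salamanders: climatic
ensemble niche models with spatially blocked validation, multi-scenario
projection with extrapolation diagnostics, fine-scale weighted-overlay
refinement, and circuit-theory connectivity with change and
hybridization-zone indices. This vignette explains the models, the
parameters that matter, the numerical choices, and what the synthetic
landscapes do and do not establish about real data.

## The synthetic landscape and virtual species

Every stage of the pipeline is exercised against simulated landscapes with
known ground truth, so recovery can be measured rather than assumed.

**Climate fields.** Each climate layer is a deterministic latitudinal plus
longitudinal gradient overlaid with a stationary Gaussian random field. The
field is simulated by circulant embedding with exponential covariance
`C(h) = exp(-3 h / range)`, so `autocorr_range` is the *practical range*:
the distance at which correlation has decayed to `exp(-3)` (about 0.05),
the usual geostatistical reading of "range". This convention makes two
checks coherent: the empirical variogram range of a generated field matches
the configured value, and the spatial-autocorrelation range (SAR) recovered
from residual correlograms is commensurate with the generating range.
Future scenarios are additive per-variable shifts of the present layers —
deliberately simple, so scenario differences are known exactly.

**Terrain and hydrology.** The DEM is a regional tilt plus an
autocorrelated roughness field. Streams are delineated by D8
steepest-descent flow routing and a flow-accumulation threshold, and
Strahler orders follow the standard junction rule (order increases only
where two tributaries of equal maximal order meet); an independent
recursive implementation of that rule is kept in the test suite as an
oracle. Segments above order 3 are excluded by default before building the
distance-to-stream surface, reflecting the preference of small
stream-breeding amphibians for low-order tributaries.

**Virtual species.** True suitability is a logistic function of the first
two climate layers, multiplied by an exponential decay with distance to
standing water and a habitat-class factor, so the climatic, distance-based
and categorical predictor families all carry signal. The default logistic
coefficients `(-3, 2, -2)` give a moderate-prevalence species (roughly 40%
of the landscape weakly-to-strongly suitable, median truth below 0.3): a
realistic contrast for a habitat specialist, and one for which
presence-only evaluation metrics are informative. Occurrences are sampled
*without replacement at the cell level* with inclusion probability
proportional to truth, which mimics spatially thinned field data and avoids
duplicate-cell degeneracy downstream; the default draw is 128 points, a
typical dataset size for a narrowly distributed amphibian. Because
sampling is cell-exclusive, very small grids combined with large samples
saturate the best cells and flatten the presence-to-expected profile —
recovery tests therefore use grids of several thousand cells or more.

**What the simulations do not show.** The generator makes no attempt at
climate physics, real geography, observation bias, or non-stationary
autocorrelation. Passing recovery tests demonstrates that the estimators
are consistent under the stated generating model at desk scale; it does not
validate transfer to any particular real landscape.

## Ensemble niche modelling

**Pseudo-absences.** A rectilinear surface range envelope (SRE) is built
from per-variable presence quantiles `q` and `1 - q` (default
`q = 0.025`, linear-interpolation type-7 quantiles). Pseudo-absences are
drawn uniformly, without duplicate cells within a set, from cells outside
the envelope in at least one variable; by default 10 replicate sets of
1000 points. Case weights equalise the classes: presences weigh 1, each
pseudo-absence `n_presences / n`, so both classes contribute equal total
weight to every learner.

**Learners.** Three families, with fixed, conventional hyperparameters:

* quadratic-polynomial logistic GLM (binomial, logit link);
* gradient-boosted trees — 5000 trees, depth-3 (three-way) interactions,
  shrinkage 0.001, bag fraction 0.5, minimum 10 observations per terminal
  node. The fixed tree count is used as the stated parameterisation; no
  early stopping is applied. The backend is xgboost with these settings
  mapped one-to-one; it honours per-row case weights.
* random forest — 500 classification trees, 2 candidate predictors per
  split, terminal node size 5. The randomForest backend has no per-row
  weights, so the equal-class-weight scheme is expressed through class
  weights instead; with the weighting used here the two are equivalent at
  the class level.

**Spatial blocking.** To avoid optimistic validation under spatial
autocorrelation, evaluation uses two-fold checkerboard cross-validation:
square blocks anchored at the extent origin, fold = (block row + block
column) mod 2. The block size is chosen from the data: preliminary GLMs
are fitted per pseudo-absence replicate, binary-weight Moran's I of their
training residuals is computed in 20 equal distance bins up to half the
extent diagonal, and the SAR proxy is the smallest bin midpoint from which
|I| stays below 0.05 in all larger bins across all correlograms. The
default block size is 1.25 times that distance. Under independence the
per-bin expectation of Moran's I is `-1/(n-1)`, which the tests verify.

**Evaluation and ensembling.** Each family x replicate model is trained
and tested on the two checkerboard folds in both directions; the
continuous Boyce index (101 moving windows of width one tenth of the
background prediction range; Spearman correlation of the
presence-to-expected ratio against the window midpoint) and the True Skill
Statistic (maximum over thresholds of sensitivity + specificity - 1) are
averaged over the two folds. Members enter the ensemble only with Boyce
strictly above 0.7 *and* TSS strictly above 0.5 — threshold ties are
excluded, as the gates are printed as strict inequalities. Selected
members are refit on their full datasets and combined as a weighted mean
with weights proportional to the Boyce index. Permutation importance is
`1 - cor(original, permuted prediction)` per variable, normalised to
percentages.

## Scenario projection, MESS and dissimilarity weighting

Scenarios are the Cartesian product of projection years, SSP pathways and
GCMs, in deterministic (year, ssp, gcm) order. For each projection the
multivariate environmental similarity surface (MESS) is computed against
the model's calibration sample — presence plus pseudo-absence cells, the
model's actual training support. The per-variable similarity follows the
standard percentile form (100 at the calibration median, 0 at the extremes,
negative outside the calibration range), and the MESS value is the minimum
over variables; the test suite checks it against a brute-force percentile
implementation.

Per-GCM projections of each year x SSP are merged by dissimilarity-weighted
averaging: each GCM's per-cell MESS is rescaled by the global MESS range to
a similarity score (plus epsilon = 1e-6 so fully novel cells keep nonzero
weight), and weights are the normalised scores. The reference literature
for this weighting gives no closed-form equation, so the package adopts
this rescaled-similarity convex combination — monotone (more similar means
more weight), bounded by the member projections, and isolated in a single
function (`medi_combine`) so an alternative formula can be swapped in
without touching the pipeline.

## Fine-scale weighted overlay

Non-climatic predictors are reclassified to a common 0-1 suitability scale
from occurrence-versus-background relative frequencies: categorical layers
by the max-normalised frequency ratio per class; distance layers by an
exponential decay fitted to binned frequency ratios; slope by a Gaussian
bump; aspect by a Gaussian in *circular* distance to the circular mean of
occurrence aspects, since 0 and 360 degrees coincide. Curve families are
fixed per predictor kind in configuration, not auto-selected, for
reproducibility.

The final model is a per-cell weighted arithmetic mean of the score layers
and the climatic ensemble layer. Default weights — ensemble 0.40, habitat
0.20, distance-to-stream 0.15, distance-to-waterbody 0.15, slope 0.05,
aspect 0.05 — encode an ensemble-dominant, habitat-heavy prior appropriate
for a moist-forest, water-dependent species, and are fully overridable;
they are stand-ins where study-specific expert weights would be supplied.
Future runs swap only the ensemble layer, holding transforms, weights and
non-climatic layers fixed (high-resolution future projections of habitat
and hydrography are generally unavailable). Weighted models are validated
with the continuous Boyce index against held-out occurrences.

## Resistance surfaces and circuit-theory connectivity

Suitability is min-max normalised, barriers (roads, urban polygons) are
burned in as suitability 0, and resistance follows the negative-exponential
form `R(h) = 100 - 99 (1 - e^{-c h}) / (1 - e^{-c})` with `c = 4`: a
strictly decreasing map with `R(0) = 100`, `R(1) = 1`, the conventional
transform for habitat specialists whose movement cost rises sharply as
habitat quality degrades.

The raster becomes a graph with one node per valid cell and edges to the
8-neighbourhood; edge conductance is the reciprocal of the mean of the two
cell resistances, with diagonal conductances divided by sqrt(2) for the
longer centre-to-centre distance — the convention of the reference
circuit-theory software. Focal nodes are occurrences snapped to their
containing cells (coincident points collapse). For every unordered pair,
1 A is injected at the source and extracted at the destination; node
potentials solve the graph Laplacian restricted to the focal component,
grounded at one focal node, via a sparse Cholesky factorisation computed
once per graph and reused across pairs. Per-cell current is half the sum
of absolute incident edge currents (the full ampere at the two focal
cells), and the cumulative map sums over pairs; a per-pair mean is
available for comparisons across node sets of different sizes. A
configurable pair cap with deterministic even subsampling keeps large node
sets tractable (hundreds of occurrence nodes imply tens of thousands of
solves; synthetic defaults stay at or below about 30 nodes). Correctness
is anchored to a dense Laplacian-pseudoinverse oracle on small random
grids, to series/parallel/triangle closed forms, and to Rayleigh
monotonicity and resistance-scaling laws.

## Change and hybridization indices

The Standardized Connectivity Change Index is the cell-wise normalised
difference `(C_fut - C_cur) / (C_fut + C_cur)`, bounded in [-1, 1] with 0
meaning corridor maintenance; the source literature prints the anchor
values but not the equation, and this normalised difference is the simple
form matching all anchors (+1 complete gain, -1 complete loss, 0
maintenance). Cells with zero current in both maps are set to 0 —
"maintenance" semantics — rather than nodata. Percent connectivity change
is the relative change of mean cumulative current within a range mask.
Range shifts are summarised by suitability-weighted centroids, with
azimuth in degrees clockwise from grid north.

The hybridization-chance assessment intersects the two species' (convex)
range polygons, buffers the intersection centroid (50 km on a metre grid
by default), averages the two SDMs within the buffer — a cell perfect for
one species and hostile to the other averages 0.5; a cell suitable for
both stays near 1 — and reruns the barrier/resistance/pairwise chain using
all occurrences of both species inside the buffer as undifferentiated
focal nodes. Polygon operations (Sutherland-Hodgman clipping, shoelace
area and centroid, n-gon buffers) are implemented in the package and
assume convex inputs, which all package-generated ranges and buffers
satisfy.

## Numerical and design choices

* **Raster carrier and I/O.** Rasters are matrices with an affine
  georeference (cell-centre registration, row 1 north, projected map
  units) and a nodata sentinel; multi-layer stacks must share geometry.
  On-disk exchange uses the ESRI ASCII grid (text, GDAL-readable), written
  at full double precision so round trips are exact; vectors use GeoJSON;
  points use CSV.
* **Terrain.** Slope/aspect use Horn's 3x3 kernel with nearest-neighbour
  edge padding; aspect is the downslope direction clockwise from north,
  nodata on flat cells. Distance surfaces are exact cell-centre-to-cell-
  centre nearest-feature distances, computed in row chunks to bound
  memory.
* **VIF screening.** Stepwise: repeatedly drop the layer with the largest
  variance inflation factor until all are below the threshold (default
  10), computed on a fixed-seed sample of at most 10,000 valid cells; ties
  broken by layer name order for determinism. Perfectly collinear pairs
  resolve in the first iteration because one member attains infinite VIF.
* **Degenerate inputs** raise errors rather than silent results: constant
  rasters for normalisation or Boyce, single-class datasets, empty
  feature masks, flat DEMs, zero residual variance, focal nodes in
  disconnected components (named per component), empty range
  intersections.
* **Determinism.** Every stochastic step takes a seed (default 42) and
  restores the caller's RNG state; identical configuration and seed give
  bit-identical rasters and point sets.
* **Problem sizes.** The recovery analyses in the test suite run at a
  200 x 200 grid with 150 training presences and 3 pseudo-absence
  replicates for the ensemble, and 120 x 120 fields with 800 sample
  points for the SAR study — sizes chosen so the checks complete on a
  single CPU in minutes while leaving the estimators' statistical
  behaviour clearly visible.

## Known limitations

* The boosted-trees and random-forest backends reproduce the stated
  hyperparameterisation, not any other library's internal numerics
  bit-for-bit.
* Polygon clipping assumes convex inputs; arbitrary real-world range
  polygons would require a general clipping engine.
* No reprojection between coordinate systems and no geographic
  (longitude/latitude) distance computation: everything assumes one
  projected CRS in consistent map units.
* The dissimilarity-weighted GCM averaging is one defensible reading of a
  formula the literature leaves unstated; it is isolated so it can be
  replaced.
* Pairwise current maps depend on the focal node set; with capped pair
  budgets the cumulative map is an even subsample of pair contributions,
  not the full sum.
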