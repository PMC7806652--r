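---
title: "From habitat suitability to connectivity: the models behind kernelscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From habitat suitability to connectivity: the models behind kernelscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kernelscape)
```

kernelscape implements the analysis chain commonly used to plan
conservation networks for wide-ranging carnivores: estimate habitat
suitability from occurrence records, convert suitability into a movement
resistance surface, simulate connectivity across it at a range of
dispersal abilities, delineate core habitat patches, and rank those
patches by their contribution to network-wide connectivity. This
vignette explains each model, its assumptions and tunable parameters,
the numerical choices made, and what the synthetic-landscape tests do
and do not demonstrate.

## The data model

All spatial stages operate on a `raster_layer`: a numeric matrix bound
to a `grid_spec` (rows x columns, square cell size in metres, map
origin). Geometry is planar throughout — the package assumes a
projected, equal-area CRS, which is the normal setting for
regional-scale resistance modelling; there is no geodesic arithmetic.
Rasters are exchanged on disk as ESRI ASCII grids (a plain-text format
that round-trips values, geometry and the nodata mask exactly at the
written precision), points as CSV or GeoJSON, overlays as GeoJSON.

## Occurrence preparation

Opportunistic occurrence records are spatially autocorrelated, which
inflates model evaluation. `spatial_rarefy()` thins presences with a
greedy sequential rule: points are visited in ascending id order and a
point is kept iff no previously kept point lies within the exclusion
radius (default use is 5 km, roughly one home-range radius for a large
carnivore). The greedy rule is deterministic, idempotent, and guarantees
the retained set has no pair closer than the radius. A seeded randomized
visiting order is available; the default is by id, because the tool it
emulates does not document its tie-breaking and a fixed order makes runs
bit-reproducible.

`sample_pseudo_absences()` draws background points uniformly from the
cells whose centers lie at least the exclusion radius from every
presence (default 1000 points, 5 km). The eligible set is computed
exactly rather than by rejection sampling, so infeasibility (no eligible
cell) is detected analytically and reported as such.

## Multi-scale suitability modelling

Species select habitat at characteristic spatial scales, so each
covariate enters the model as a circular focal mean at each candidate
radius (default 1, 2, 4, 8, 16 and 32 km). `focal_mean()` uses the
discrete circle of cell centers within the radius, excludes nodata, and
averages over the in-bounds part of the window at edges; it is computed
by FFT convolution, so large radii cost the same as small ones
(round-off is guarded where a fraction must stay in [0, 1]).

Collinearity screening (`vif_screen()`) drops predictors iteratively:
first the worse member of any pair with |r| above 0.7, then the largest
variance inflation factor until all VIF <= 3. VIF is computed from
ordinary least squares of each column on the others.

The learner is a contract — `fit(x, y, seed)` plus
`predict(handle, x)` returning scores in [0, 1]. The default is a
probability random forest (`ranger`, single-threaded with a fixed seed
so predictions are reproducible); a plain logistic GLM ships as a fast
deterministic alternative. Model skill is summarized by AUC (computed as
the rank / Mann-Whitney statistic, so it is invariant under monotone
rescaling of the scores) and the true skill statistic (TSS), maximized
exactly by scanning the midpoints between consecutive distinct scores.
Evaluation uses stratified k-fold cross-validation (default k = 5,
seeded); training-set metrics are reported alongside for transparency.

One multivariate model is fitted per scale and the operative scale is
the one with the highest cross-validated AUC, ties broken by TSS and
then by the smaller scale (`select_scale()`). Per-variable best scales
are also recorded (`evaluate_scales(..., per_variable = TRUE)`) for the
alternative workflow in which a single model mixes each variable at its
own best scale; the per-scale workflow is the default because its
selected model is what feeds the connectivity stages.

## Suitability to resistance

`suitability_to_resistance()` maps suitability HS to a movement cost
multiplier via the negative-exponential transform `raw = 1000^(-HS)`,
linearly rescaled to [1, 10]. The rescaling anchors are the analytic
extremes `1000^0 = 1` and `1000^-1`, not the empirical range of a given
map, so HS = 1 always yields resistance 1 and HS = 0 always yields 10,
and resistance values are comparable across landscapes. The transform is
strictly decreasing and convex: resistance rises steeply only as
suitability approaches zero, encoding the assumption that animals
traverse all but the worst habitat at near-minimal cost. Base and output
range are parameters for sensitivity analysis.

## Cost distance, resistant kernels, corridors

Movement is modelled on the 8-connected raster graph. The step cost
between adjacent cells is the mean of their resistances times the
inter-cell distance (cell size, times sqrt(2) diagonally), so cost units
are resistance-weighted metres: 50,000 cost units through resistance-1
habitat correspond to 50 km of movement. Accumulated cost from a source
set is computed with Dijkstra's algorithm (`cost_distance()`).

`resistant_kernel()` builds, around each source, a dispersal kernel that
decays linearly with accumulated cost and is truncated at the dispersal
threshold D: `k_s(x) = max(0, 1 - cd_s(x)/D)`, peaking at 1 at the
source. Per-source kernels are summed over all sources; the cumulative
surface estimates the expected rate of movement through each cell. Two
conventions needed fixing where the underlying literature is loose:
kernels peak at 1 rather than integrating to 1 (the cumulative surface
is then interpretable as "expected number of sources within reach,
discounted by cost"); and a cell is counted as within reach iff its
accumulated cost is at most D, so on uniform resistance 1 the kernel's
cardinal-axis reach is exactly D metres (the kernel value at that
boundary cell is 0 — the support edge — and strictly positive inside).
A Gaussian decay (`shape = "gaussian"`) is available behind a switch.
Five thresholds spanning 50,000-400,000 cost units bracket plausible
female-to-male dispersal abilities of a large carnivore and are the
default scenario set.

`factorial_lcp()` computes the least-cost path for every unordered pair
of sources, dilates each path by a buffer (default one cell; the width
is a presentation choice, not an inference), and sums incidences into a
corridor-strength surface. Unreachable pairs are skipped with a warning
and recorded. Path ties are resolved by the shortest-path search's
deterministic visiting order, so corridor rasters are reproducible
bit-for-bit.

## Core patches, overlays, fragmentation metrics

`delineate_cores()` thresholds the cumulative kernel at a fraction
(default 25%) of its landscape maximum and labels 8-connected
components as core patches. 8-connectivity matches the movement graph.
The threshold uses a strict inequality. A percentile mode (cutting at a
quantile of the positive kernel values) is provided because both
phrasings circulate in the literature; fraction-of-maximum is the
default. Note that with the relative cutoff the threshold itself moves
with D, so metric trends across scenarios are an empirical property of
a landscape, not a mathematical consequence of kernel nesting (which
holds for a fixed absolute cutoff).

`overlay_stats()` quantifies protected-area coverage (cell-center rule:
a cell is protected iff its center falls in a polygon — exact whenever
polygons are cell-aligned, and the standard rasterization convention
otherwise) and road exposure (exact Liang-Barsky clipping of road
segments against patch cell squares, reported as length and as density
in m/km^2).

`class_metrics()` reports the four class-level fragmentation metrics:
patch count NP, percentage of landscape PLAND, largest patch index LPI,
and correlation length GYRATE_AM (the area-weighted mean over patches of
the mean distance from each cell center to its patch centroid; a
single-cell patch has gyration 0).

## Patch-graph prioritization

`build_patch_graph()` connects core patches with boundary-to-boundary
cost distances (multi-source Dijkstra from all cells of one patch to the
nearest cell of the other — centroid distances mislead when patches are
large relative to their gaps). Dispersal probability decays
exponentially, `p_ij = exp(-k d_ij)`, with k calibrated so that p equals
`p_at_D` (default 0.5; 0.05 offered as the conservative alternative,
since published guidance quotes both anchors without fixing one curve)
at the scenario threshold D. Binary links join patches with `d_ij <= D`,
keeping the binary and probabilistic models on one scale.

The integral index of connectivity and the probability of connectivity
are

    IIC = sum_ij a_i a_j / (1 + nl_ij) / A_L^2
    PC  = sum_ij a_i a_j p*_ij        / A_L^2

with `a_i` the patch areas, `nl_ij` the link count of the shortest
topological path, `p*_ij` the maximum product of probabilities over all
paths (found by Dijkstra under -log p weights), diagonal terms included,
unreachable pairs contributing 0, and `A_L` the total landscape area
(the whole study frame, not habitat area only — the more common
convention and the default here). Stepping stones matter for PC because
movement within a patch is free in the graph model: a route through a
wide intermediate patch can beat the direct cost distance, so the
two-step probability product can exceed the direct one.

`node_importance()` removes each patch in turn: `dX = 100 (X - X') / X`,
decomposed into an intra term (`100 a_k^2 / (X A_L^2)`), a flux term
(`100 * 2 sum_j a_k a_j w_kj / (X A_L^2)`, `w = p*` for PC, `1/(1+nl)`
for IIC) and a connector term defined as the remainder — the purely
topological stepping-stone contribution. `rank_cores()` averages dX
across dispersal scenarios (a patch fragmented away in some scenario
counts 0 there) and ranks descending, ties broken by patch id.

## The synthetic landscape generator

Because real occurrence and GIS layers for such studies are rarely
deposited, every stage is exercised on synthetic landscapes with known
structure:

- **Covariates** are Gaussian random fields: white noise smoothed by an
  isotropic Gaussian filter and re-standardized. The filter sigma is
  `autocorr_range / (3 * cell_size)`, which makes `autocorr_range` the
  distance at which correlation decays to about 0.1 (the Gaussian ACF is
  `exp(-d^2/(4 sigma^2))`); a range of one cell is effectively white
  noise at the cell scale. Noise is generated on a padded grid and
  cropped, so there are no edge artefacts.
- **Truth** is `logistic(sum_j beta_j * focal(cov_j, true_scale))`: the
  suitability process lives at one known scale, which is exactly what
  the scale-selection stage must recover.
- **Presences** are drawn with probability proportional to suitability
  (optionally times an effort layer, for sampling-bias experiments;
  suitability-proportional sampling is the default because the point
  process behind opportunistic records is unknown).
- **Overlays**: protected areas are cell-aligned random rectangles;
  roads are a jittered rectilinear lattice, making total length
  predictable for overlay checks.

What passing these tests shows: the estimation and connectivity
machinery is internally correct and recovers known structure under the
generator's assumptions. What it does not show: robustness to the ways
real data violate those assumptions — anisotropic or non-stationary
covariates, roads-biased detection, positional error, non-logistic
responses, or climate-layer structure (climate enters only as a generic
autocorrelated field).

## Verification at a glance

The test suite checks every stage against an independent route: raster
Dijkstra against exhaustive depth-first path search on small random
grids; IIC/PC against brute-force path enumeration on random graphs up
to 6 nodes; AUC against an independent ROC implementation; TSS against a
naive threshold scan; focal means against discrete-circle enumeration;
the resistance transform and fragmentation metrics against closed
forms; and importance fractions for exact closure (dX = intra + flux +
connector within 1e-6).

Two end-to-end properties mirror the scientific claims the pipeline is
built around. First, fragmentation direction: on a packaged 64 x 64 km
fixture landscape (seeded, ~39 rarefied sources) the five scaled
dispersal thresholds 5,000-40,000 cost units produce monotonically
falling NP and rising PLAND, LPI and correlation length. Second, scale
recovery: with truth generated at 8 km, the full
prep-features-evaluate-select chain picks 8 km from
{1, 2, 4, 8, 16, 32} km in at least 80% of 20 seeded replicates. The
recovery experiment runs on a 256 x 256 km grid (300 presences thinned
at 5 km, 1000 pseudo-absences) with the logistic learner: the extent
gives the 8 km structure enough spatial replication that coarse scales
cannot win by merely separating presence regions from the
distance-excluded background, and the logistic learner matches the
generating family, so the experiment isolates the scale-selection
machinery from learner variance. Problem sizes throughout the suite
(64-256 cell grids, tens of sources, up to 6-node brute-force graphs)
are chosen so each oracle stays exhaustive and the whole suite runs in
about a minute.

## Worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(n_rows = 64, n_cols = 64, n_presences = 40,
                       n_absences = 200, thresholds = c(10000, 30000),
                       num_trees = 200, seed = 7)
res <- run_pipeline(cfg, out_dir = "report")
res$tables$class_metrics
res$ranking$PC
```

## Known limitations

- Planar geometry only; reproject before use.
- The cell-center rule under-resolves protected-area slivers narrower
  than a cell; road lengths, by contrast, are exact.
- IIC/PC node removal is recomputed from scratch per node (quadratic in
  patches per removal), fine for the tens of patches typical of core
  delineation but not for thousands of nodes.
- The corridor buffer width and the kernel decay shape are conventions,
  not estimates; sensitivity to them should be reported when the
  package is used for planning.
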