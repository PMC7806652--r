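# kernelscape

Resistant-kernel connectivity modelling and core-habitat prioritization
on raster landscapes, in R.

Conservation planning for wide-ranging species (large carnivores above
all) needs two things the raw data never give directly: where the
population's core habitat areas are, and how well individuals can move
between them at realistic dispersal abilities. kernelscape implements
the full analysis chain that practitioners assemble from several GIS
tools, as one tested, scriptable package:

1. **Occurrence preparation** — greedy spatial rarefaction of presence
   records (default 5 km exclusion radius) and uniform pseudo-absence
   sampling outside the exclusion zones.
2. **Multi-scale suitability modelling** — each covariate enters as a
   circular focal mean at candidate radii (default 1–32 km);
   correlation + VIF screening (|r| ≤ 0.7, VIF ≤ 3); a pluggable
   learner (probability random forest by default, logistic GLM as a
   fast alternative); stratified cross-validated AUC and TSS; the
   operative scale is the one with the highest AUC.
3. **Resistance** — suitability HS maps to a movement cost multiplier
   R = 1000^(−HS), rescaled linearly so that HS = 1 ⇒ R = 1 and
   HS = 0 ⇒ R = 10, anchored at the analytic extremes.
4. **Connectivity** — Dijkstra cost distances on the 8-connected raster
   graph (step cost = mean resistance × inter-cell distance, in
   resistance-weighted metres, so 50,000 cost units ≡ 50 km through
   optimal habitat); cumulative resistant kernels
   k(x) = Σ_s max(0, 1 − cd_s(x)/D) at a ladder of dispersal thresholds
   D; factorial least-cost-path corridor surfaces summed over all
   source pairs.
5. **Core patches** — contiguous cells with kernel values above 25% of
   the landscape maximum; class-level fragmentation metrics (NP, PLAND,
   LPI, correlation length); overlay statistics against protected areas
   and roads.
6. **Prioritization** — patch graphs with boundary-to-boundary cost
   distances and p_ij = exp(−k·d_ij) calibrated to p = 0.5 at D;
   IIC = Σ a_i a_j/(1+nl_ij)/A_L² and PC = Σ a_i a_j p*_ij/A_L²;
   node-removal importance dIIC/dPC decomposed into intra, flux and
   connector fractions; cross-scenario ranking.

A seeded synthetic-landscape generator (autocorrelated covariate
fields, a known true suitability surface at a known spatial scale,
suitability-proportional presence sampling, protected-area and road
overlays) makes every stage testable end to end without any field data.

## Worked example

```r
library(kernelscape)

cfg <- pipeline_config(n_rows = 64, n_cols = 64, n_presences = 40,
                       n_absences = 200, thresholds = c(10000, 30000),
                       num_trees = 200, seed = 7)
res <- run_pipeline(cfg, out_dir = "report")
```

The run logs each stage, then `res$tables` holds the report tables the
pipeline also writes as CSV. Model evaluation by scale (the truth here
was generated at 8 km, and 8 km wins the cross-validated AUC):

```
> round(res$tables$model_eval, 3)
      1km   2km   4km   8km  16km  32km
AUC 0.504 0.470 0.525 0.698 0.606 0.608
TSS 0.157 0.126 0.110 0.331 0.214 0.321
```

Fragmentation of the core-habitat network across the two dispersal
scenarios — more dispersal ability fuses 18 patches into 3 and raises
the connected-habitat share of the 4096 km² landscape from 20% to 34%:

```
> res$tables$class_metrics
  threshold np       lpi    pland gyrate_am_m
1     10000 18  9.008789 19.94629    5617.264
2     30000  3 25.854492 33.81348   13516.786
```

Protected-area coverage and road exposure of the cores (by scenario),
and the patch ranking by mean dPC across scenarios — patch 1 dominates
the network's connectivity:

```
> res$tables$core_overlays
  threshold extent_km2 protected_km2 protected_pct road_density_m_per_km2
1     10000        817           183      22.39902               99.14321
2     30000       1385           341      24.62094              116.24549

> head(res$ranking$PC, 3)
  id  dX_10000  dX_30000   mean_dX rank
1  1 84.872067 95.681100 90.276583    1
2  2 16.285719 23.433507 19.859613    2
3  3  2.314333  6.003154  4.158743    3
```

Rerunning the same config reproduces every file byte for byte.

## Documentation

The methods vignette (`vignettes/methods.Rmd`) describes the models,
their assumptions, parameter meanings and defaults, numerical choices,
what the synthetic generator does and does not emulate, and known
limitations.
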