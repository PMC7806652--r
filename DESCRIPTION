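Package: kernelscape
Title: Resistant-Kernel Connectivity and Core-Habitat Prioritization on Raster Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for multi-scale habitat suitability
    modeling and landscape connectivity analysis of large-carnivore
    populations. Builds spatially filtered presence/pseudo-absence data,
    fits suitability models on focal-mean covariates across candidate
    spatial scales with AUC/TSS-based scale selection, transforms
    suitability to movement resistance on a 1-10 scale, computes raster
    cost distances, cumulative resistant kernels at multiple dispersal
    cost thresholds and factorial least-cost-path corridor surfaces,
    delineates core habitat patches with class-level fragmentation
    metrics (NP, PLAND, LPI, correlation length), overlays patches and
    corridors with protected areas and roads, and prioritizes patches by
    node-removal importance of the integral index of connectivity (IIC)
    and the probability of connectivity (PC), decomposed into intra,
    flux and connector fractions. Includes a seeded synthetic-landscape
    generator so the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    ranger,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
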