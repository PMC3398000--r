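Package: tigercorridor
Title: Least-Cost Corridor Delineation Between Protected Areas from
    Expert-Weighted Cost Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for delineating wildlife movement corridors between two
    protected areas with raster least-cost-path modelling. Builds six ranked
    cost surfaces (prey-ranked habitat, distance to perennial water,
    PCU-weighted road density, railway presence, settlement population
    density, and per-hexagon Total Edge) from categorical habitat rasters and
    vector layers, combines them under expert-derived weighting schemes into a
    composite movement-cost surface, traces least-cost corridors from multiple
    start cells to a destination cell, decomposes shared path segments, flags
    weak links where forest width is constricted or fragmentation severe,
    buffers the corridor, and audits along-path water availability. Includes a
    pellet-count survey analysis (belt-transect densities, standard errors,
    per-hectare conversion, habitat preference ranking, zero-count profiles)
    and seeded synthetic-landscape and synthetic-survey generators so every
    stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
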