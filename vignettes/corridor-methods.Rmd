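---
title: "Cost-surface corridor modelling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cost-surface corridor modelling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tigercorridor)
```

## The model

`tigercorridor` delineates candidate wildlife corridors between two
protected areas by least-cost-path (LCP) analysis on a composite
resistance surface. The model assumes that a dispersing tiger's route
choice can be summarised cellwise by six ranked cost layers — prey-ranked
habitat (`H`), distance to perennial water (`WS`), PCU-weighted road
density (`RD`), railway presence (`R`), settlement population density
(`S`) and per-hexagon Total Edge (`TE`) — combined linearly:

$$CM = W_H H + W_S S + W_{WS} WS + W_{TE} TE + W_{RD} RD + W_R R$$

The weights come from an expert elicitation: five tiger-behaviour
experts rated seven candidate variables 0–5 (`expert_ratings()`;
averages 4.0 cover, 3.4 prey, 2.6 water, 3.0 habitation, 1.2 roads,
0.8 railway, 0.2 slope). Three weighting schemes are predefined
(`run_option()`): RO1 treats all six themes as equally important; RO2
follows the second expert's column, mapped to model variables as cover
→ `W_TE` 5, prey base → `W_H` 4, habitation → `W_S` 3, water →
`W_WS` 2, roads → `W_RD` 1, railway → `W_R` 0; RO3 doubles habitat,
edge and water against a baseline of 1 for the rest.

Three mapping decisions deserve a note, because the elicitation
questionnaire names behavioural parameters rather than layers. *Cover*
is mapped to the Total Edge weight: `TE` is precisely the layer that
measures continuity versus fragmentation of cover. *Food
availability/prey base* maps to the habitat weight, because the `H`
ranks are themselves derived from prey pellet densities per cover type.
*Slope* is dropped: the experts scored it near zero and the model has
no terrain layer. In RO3, variables that are "not twice as important"
carry weight 1 rather than 0 — the scheme contrasts doubled importance
against baseline importance, and zeroing four of six layers would
instead remove them from the model. No weight normalisation is applied;
since the traced route is invariant under positive scaling of `CM`
(verified by property test), only weight ratios matter.

## Cost tables and binning conventions

All reclassification tables map half-open intervals $[lo, hi)$ to
integer ranks, with the top interval closed above and values beyond the
top published bound clamped to the highest rank. The published range
labels overlap at their endpoints (e.g. road density "4 to 6" and "6 to
11"); the half-open convention makes every lookup single-valued, with a
boundary value taking the higher-cost bin. "Absent" categories in the
density tables are exact-zero matches checked before the intervals, so
an infinitesimal density is Low, not Absent. Total Edge below the first
published bound (100 m) shares the lowest bin's cost 0, continuous with
"no edge costs nothing".

Water is special in two ways: cells *on* a water feature rank 10 (open
water can be a barrier even though proximity to water is attractive),
and the underlying distance grid is kept (attribute `"distance"` of
`build_water_cost()`) because the water-gap audit needs distances, not
ranks.

## Spatial primitives

Rasters are plain numeric matrices with a shared `grid_spec` (row 1 =
north, planar metres, no CRS mathematics; cells addressed 1-based).
The default synthetic resolution is 100 m — the model operates on
ranked surfaces and is scale-tolerant, so resolution mainly trades
geometric detail against run time. I/O uses plain-text formats: ESRI
ASCII grids for rasters and GeoJSON for vector layers.

* **Rasterization** of polylines is exact: each segment is split at
  every grid-line crossing and each piece's midpoint cell is marked.
  Polygons burn cells whose centre falls inside (even-odd rule).
* **Distance transform**: the exact two-pass separable lower-envelope
  algorithm on squared distances; property tests assert exact equality
  with brute-force minimisation over all sources on random masks.
* **Line/point density**: per cell centre, segment length clipped to
  the search circle (closed-form quadratic) times the feature weight,
  over the circle area. The search radius is a parameter (default
  1000 m) because the original analysis does not state its kernel
  radius — absolute densities are therefore generator-calibrated, and
  only the categorisation machinery is portable to real data.
* **Total Edge** is computed on raster rook adjacency: every pair of
  4-adjacent cells with differing class contributes one cell-edge
  length. This is the standard raster-mode equivalent of the
  polygon-based FRAGSTATS metric. Hexagon landscape units are flat-top,
  width (flat-to-flat) 2000 m by default (the original hexagon size is
  unstated); cell centres are assigned to the nearest hexagon centre by
  axial rounding, which tiles the extent without gaps or overlaps. A
  pair straddling two hexagons is counted once, for the hexagon of the
  upper/left cell, so hexagon TEs sum exactly to the whole-landscape
  TE. Landscape-boundary edges are not counted (boundary proportion
  fixed at 0).

## Cost accumulation and tracing

`accumulate_cost()` runs Dijkstra (C++ priority queue) on the implicit
8-neighbour graph with transition cost $(cm_a + cm_b)/2$ per orthogonal
step and $\sqrt2$ times that per diagonal step — the convention of
standard GIS cost-distance tools. Determinism is taken seriously:
neighbours are relaxed in the fixed order N, NE, E, SE, S, SW, W, NW
and equal keys pop in insertion order, so reruns are bit-identical and
routes are invariant under exact positive scalings of the surface
(property-tested with power-of-two factors, for which floating-point
scaling is exact). The destination park's periphery supplies the
Dijkstra sources; each start cell is traced back along backlinks
(direction codes 1–8, 0 at sources).

Traced paths are decomposed into shared and private segments by walking
them backwards from the common destination and splitting wherever the
set of paths travelling together changes; the step joining two segments
is charged to the segment farther from the destination, so each path's
length equals the sum of its segments' lengths exactly.

**Weak links.** Forest width at a path cell is operationalised as twice
the Euclidean distance to the nearest non-forest cell — the published
account reports widths without a formula, and this definition is exact
for a straight corridor of uniform width. Maximal runs of path cells
below the width threshold (default 4 km) are flagged; a run whose
surrounding hexagon edge cost reaches 8 is classed `fragmentation`,
otherwise `constriction`. Width is quantised by the cell size (the
distance is centre-to-centre), so a planted 4 km neck at 100 m cells is
recovered to within one cell.

**Buffer.** The management buffer is the union of per-cell discs:
radius `max_km` (default 6) along healthy forest, `min_km` (default 2)
inside weak-link spans, tapering linearly at one km of radius per km of
along-path distance. The buffer is produced as a raster mask plus
contour outline; its area converges to the analytic
rectangle-plus-caps value for straight paths (tested within 5%
discretisation error).

**Water gaps.** Path cells farther than `max_km` (default 5) from
water form gap spans. Waterholes are proposed greedily: place a hole at
the arc midpoint of the longest uncovered stretch, recompute coverage,
repeat until no path cell exceeds the limit. Greedy midpoint placement
is not guaranteed minimal in hole count but is simple, deterministic
and always terminates with full coverage (asserted in tests).

## The synthetic generators

The synthetic landscape emulates the *structure* of the study system —
two disjoint park rectangles in a 30 × 20 km matrix (16 × 10 km in most
tests, chosen to keep the suite fast while leaving dozens of hexagons
and thousands of cells), a spatially autocorrelated habitat mosaic
(thresholded Gaussian-smoothed noise; class fractions matched by
quantile construction), meandering streams, clustered settlements with
census-like populations 50–2000, roads carrying 3000–12000 PCU of
daily traffic, and one railway. It does not attempt the real
Kanha–Pench geography, class areas or village locations; passing tests
demonstrate that the machinery recovers engineered ground truth, not
that any particular real-world route is correct.

Two engineered modes provide that ground truth. A *planted channel*
makes the matrix non-forest and the channel plus parks prime habitat,
flanks the channel with tanks every 1.2 km (just outside it, so no
channel cell lies on water and all are within the best water bin), and
pushes all infrastructure to the landscape edges — making the channel
cells best-ranked in every layer and any off-channel route strictly
worse, for any non-negative weighting. *Necks* carve non-forest so the
forest band narrows to a stated width over a stated stretch. One master
seed is split deterministically per sub-generator, so a scenario is
reproducible bit for bit and changing one knob (say, PCU values)
perturbs only the layers downstream of it.

The synthetic survey reproduces the field design: 79 transects × 5
plots of 10 m × 2 m, allocated to forest classes by largest-remainder
proportionality to class area. Counts are negative-binomial
(size 0.6 — strongly overdispersed, as pellet-group counts typically
are; the Poisson limit is available via `dispersion = Inf`) with mean
`intensity[habitat, species]`. The default intensities are a
rank-one product of a habitat factor (Bamboo Mixed 2.5 > Mixed Bamboo
1.4 > Teak Mixed 1.1 > Miscellaneous 0.6 > Teak 0.25) and a species
rate (chital 1.2 down to barking deer 0.04 groups/plot), planting a
strict preference order shared across species and a realistic
rare-species zero profile. The acceptance analysis requires the
cumulative ranking to recover the full planted order in at least 90% of
50 survey seeds.

## Survey estimators

Per-stratum pellet density is the plain mean of per-plot counts with
standard error $sd/\sqrt{n}$ using the sample ($n-1$) standard
deviation (the estimator is unstated in the source; the sample version
is the conventional default). A single-plot stratum has an undefined SE,
reported `NA`. The per-hectare conversion is exactly ×500 (10,000 m² /
20 m²). Ranking uses fractional ranks (ties share the mean of their
positions) on descending density — zero densities automatically take
the worst rank, an all-zero species contributes equal ranks everywhere,
and any strictly monotone transform of the densities leaves the ranking
unchanged. The field rules module applies the pellet-group definition
(strictly more than five pellets) and collapses co-located latrine
observations of nilgai and chowsingha to single groups before counting.

## Known limitations

* Absolute road/settlement densities depend on the unstated kernel
  radius, so the density *categories* — not the raw values — are the
  portable quantity.
* Headline real-landscape results (corridor segment lengths of
  100+ km, specific weak-link villages) require the proprietary input
  layers and are out of scope; the package validates machinery, not
  geography.
* The buffer outline is a raster contour, adequate for area and
  overlay; users needing smooth cartographic polygons should
  post-process.
* `CM` is linear and expert-weighted; no telemetry-calibrated
  resistance, circuit-theory connectivity, or multi-species
  optimisation is attempted.
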