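#' Build the habitat cost layer
#'
#' Reclassifies the categorical habitat raster through the habitat cost
#' table (prey-ranked cover classes; bamboo-dominated forest cheapest,
#' non-forest a strong barrier).
#'
#' @param habitat Categorical `tc_grid` with classes among Teak,
#'   Miscellaneous, Teak Mixed, Bamboo Mixed, Mixed Bamboo, Non-Forest.
#' @return Cost-kind `tc_grid`.
#' @export
build_habitat_cost <- function(habitat) {
  reclassify(habitat, habitat_cost_table())
}

#' Forest / non-forest mask from a habitat raster
#'
#' Merges all forest classes into one (1) against non-forest (0).
#'
#' @param habitat Categorical `tc_grid`.
#' @param non_forest Label of the non-forest class.
#' @return Binary `tc_grid`.
#' @export
forest_mask <- function(habitat, non_forest = "Non-Forest") {
  lab <- grid_labels(habitat)
  new_grid((lab != non_forest) * 1, habitat$spec, kind = "continuous")
}

#' Build the water-source cost layer
#'
#' Combines perennial streams and standing water bodies into one source
#' mask, computes the Euclidean distance of every cell to the nearest
#' water cell, and bins the distances into 1-km cost ranks. Cells lying on
#' water are ranked 10: open water can itself act as a movement barrier.
#' The underlying distance grid is attached as attribute `"distance"` for
#' the along-corridor water-gap analysis.
#'
#' @param streams Polyline [vector_layer()] of perennial streams (may be
#'   `NULL`).
#' @param waterbodies Point or polygon [vector_layer()] of tanks/lakes
#'   (may be `NULL`).
#' @param spec A [grid_spec()].
#' @return Cost-kind `tc_grid` with a `"distance"` attribute.
#' @export
build_water_cost <- function(streams, waterbodies, spec) {
  srcs <- list()
  if (!is.null(streams) && n_features(streams))
    srcs <- c(srcs, list(rasterize(streams, spec, "presence")$values))
  if (!is.null(waterbodies) && n_features(waterbodies))
    srcs <- c(srcs, list(rasterize(waterbodies, spec, "presence")$values))
  if (!length(srcs)) stop("build_water_cost: no water features")
  mask <- Reduce(function(a, b) pmax(a, b), srcs)
  dist <- euclidean_distance(new_grid(mask, spec), spec)
  cost <- reclassify(dist, water_cost_table())
  cost$values[mask == 1] <- 10
  attr(cost, "distance") <- dist
  cost
}

#' Build the road-density cost layer
#'
#' PCU-weighted line density of the road network, binned into the
#' High/Medium/Low/Absent road cost ranks. Densities beyond the top
#' published bound clamp to the highest rank.
#'
#' @param roads Polyline [vector_layer()] with a `pcu` attribute per
#'   segment.
#' @param spec A [grid_spec()].
#' @param radius Density search radius in metres.
#' @return Cost-kind `tc_grid`.
#' @export
build_road_cost <- function(roads, spec, radius = 1000) {
  if (is.null(roads) || !n_features(roads))
    return(new_grid(matrix(0, spec$n_rows, spec$n_cols), spec, kind = "cost"))
  dens <- line_density(roads, spec, radius, weight_attr = "pcu")
  reclassify(dens, road_cost_table())
}

#' Build the railway cost layer
#'
#' Presence/absence: cells crossed by a railway line rank 10, all other
#' cells 0.
#'
#' @param rail Polyline [vector_layer()] (may be `NULL` or empty).
#' @param spec A [grid_spec()].
#' @return Cost-kind `tc_grid`.
#' @export
build_rail_cost <- function(rail, spec) {
  if (is.null(rail) || !n_features(rail))
    return(new_grid(matrix(0, spec$n_rows, spec$n_cols), spec, kind = "cost"))
  pres <- rasterize(rail, spec, "presence")
  g <- reclassify(pres, rail_cost_table())
  g
}

#' Build the settlement cost layer
#'
#' Population-weighted point density of settlements, binned into the
#' High/Moderate/Low/Absent settlement cost ranks (pop/m²).
#'
#' @param settlements Point [vector_layer()] with a `population`
#'   attribute.
#' @param spec A [grid_spec()].
#' @param radius Density search radius in metres.
#' @return Cost-kind `tc_grid`.
#' @export
build_settlement_cost <- function(settlements, spec, radius = 1000) {
  if (is.null(settlements) || !n_features(settlements))
    return(new_grid(matrix(0, spec$n_rows, spec$n_cols), spec, kind = "cost"))
  dens <- point_density(settlements, spec, radius, weight_attr = "population")
  reclassify(dens, settlement_cost_table())
}

#' Build the Total Edge cost layer
#'
#' Tessellates the extent with hexagons, computes per-hexagon Total Edge
#' on the forest/non-forest mask and spreads the binned edge cost back to
#' the cells.
#'
#' @param habitat Categorical `tc_grid` (or a binary forest grid).
#' @param hex_width Hexagon flat-to-flat width in metres.
#' @return Cost-kind `tc_grid` with attributes `"reports"` and `"tess"`.
#' @export
build_edge_cost <- function(habitat, hex_width = 2000) {
  forest <- if (habitat$kind == "categorical") forest_mask(habitat) else habitat
  tess <- tessellate(habitat$spec, hex_width)
  rep <- total_edge(forest, tess)
  g <- edge_cost_grid(rep, tess)
  attr(g, "reports") <- rep
  attr(g, "tess") <- tess
  g
}

# ---- expert weighting ---------------------------------------------------

#' Expert importance ratings of the model variables
#'
#' Ratings (0-5) given by five tiger-behaviour experts to seven candidate
#' movement variables (cover, food availability/prey base, water
#' availability, presence of roads, human habitation, presence of railway
#' track, slope), read from the ratings table shipped with the package.
#'
#' @param path Optional path to an alternative ratings CSV (first column
#'   `parameter`, one column per expert).
#' @return Numeric matrix, parameters x experts.
#' @export
expert_ratings <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "expert_ratings.csv",
                        package = "tigercorridor", mustWork = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (any(m < 0 | m > 5)) stop("ratings must lie in [0, 5]")
  m
}

#' Average the expert ratings
#'
#' Arithmetic mean rating per parameter across experts, rounded to one
#' decimal (the precision the panel summary is reported at).
#'
#' @param ratings Parameters x experts numeric matrix, as from
#'   [expert_ratings()].
#' @return Named numeric vector of mean ratings.
#' @export
average_expert_weights <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (!ncol(ratings)) stop("need at least one expert")
  round(rowMeans(ratings), 1)
}

#' Run-option weight schemes
#'
#' The three expert-derived weighting schemes for combining the six cost
#' layers:
#' * `RO1` — all six themes equally important (all weights 1);
#' * `RO2` — expert E2's ratings mapped to the model variables: cover
#'   (Total Edge) 5, prey-ranked habitat 4, habitation 3, water 2,
#'   roads 1, railway 0;
#' * `RO3` — habitat, Total Edge and water twice as important as the
#'   remaining variables (2, 2, 2 versus 1, 1, 1).
#'
#' @param name `"RO1"`, `"RO2"` or `"RO3"`; or use [weight_scheme()] for a
#'   custom scheme.
#' @return A `weight_scheme`: named non-negative weights for layers
#'   `H`, `S`, `WS`, `TE`, `RD`, `R`.
#' @export
run_option <- function(name) {
  w <- switch(name,
    RO1 = c(H = 1, S = 1, WS = 1, TE = 1, RD = 1, R = 1),
    RO2 = c(H = 4, S = 3, WS = 2, TE = 5, RD = 1, R = 0),
    RO3 = c(H = 2, S = 1, WS = 2, TE = 2, RD = 1, R = 1),
    stop("unknown run option '", name, "'"))
  weight_scheme(name, w)
}

#' @rdname run_option
#' @param weights Named numeric vector over `H`, `S`, `WS`, `TE`, `RD`,
#'   `R`; all >= 0 with at least one positive.
#' @export
weight_scheme <- function(name, weights) {
  need <- c("H", "S", "WS", "TE", "RD", "R")
  if (!all(need %in% names(weights))) stop("weights must name ", paste(need, collapse = ", "))
  weights <- weights[need]
  if (any(weights < 0) || all(weights == 0))
    stop("weights must be >= 0 with at least one > 0")
  structure(list(name = name, weights = weights), class = "weight_scheme")
}

#' Assemble the six-layer cost stack
#'
#' @param H,S,WS,TE,RD,R Cost-kind `tc_grid`s sharing one [grid_spec()]:
#'   habitat, settlement, water source, total edge, road density, railway.
#' @return A `cost_stack`.
#' @export
cost_stack <- function(H, S, WS, TE, RD, R) {
  layers <- list(H = H, S = S, WS = WS, TE = TE, RD = RD, R = R)
  do.call(check_aligned, unname(layers))
  for (nm in names(layers))
    if (layers[[nm]]$kind != "cost")
      stop("layer ", nm, " is not a cost grid")
  structure(layers, class = "cost_stack")
}

#' Composite movement cost
#'
#' The weighted linear combination of the six cost layers,
#' `CM = W_H·H + W_S·S + W_WS·WS + W_TE·TE + W_RD·RD + W_R·R`, computed
#' cellwise. Nodata in any layer propagates to the composite.
#'
#' @param stack A [cost_stack()].
#' @param scheme A [weight_scheme()] or [run_option()] result.
#' @return Continuous `tc_grid` of composite movement cost.
#' @export
composite_cost <- function(stack, scheme) {
  stopifnot(inherits(stack, "cost_stack"), inherits(scheme, "weight_scheme"))
  w <- scheme$weights
  spec <- stack$H$spec
  cm <- matrix(0, spec$n_rows, spec$n_cols)
  for (nm in names(w)) cm <- cm + w[[nm]] * stack[[nm]]$values
  new_grid(cm, spec, kind = "continuous")
}
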