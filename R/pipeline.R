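#' Assemble a pipeline run configuration
#'
#' Validated configuration for [run_pipeline()]: either a
#' [landscape_scenario()] or paths to input layers, plus every analysis
#' parameter. Can also be read from a YAML file whose keys mirror the
#' arguments (`scenario:` holds [landscape_scenario()] arguments).
#'
#' @param scenario A [landscape_scenario()] (synthetic input), or `NULL`
#'   to read layers from `inputs`.
#' @param inputs Named list of file paths (`habitat` .asc, `streams`,
#'   `waterbodies`, `roads`, `rail`, `settlements` GeoJSON) when no
#'   scenario is given.
#' @param schemes Character vector of run options (subset of
#'   `"RO1"`, `"RO2"`, `"RO3"`) and/or a list of [weight_scheme()]s.
#' @param density_radius Line/point density search radius, metres.
#' @param hex_width Total Edge hexagon width, metres.
#' @param weak_width_km Weak-link forest width threshold, km.
#' @param water_max_km Maximum acceptable distance to water, km.
#' @param buffer_km `(min, max)` corridor buffer radii, km.
#' @param start_cells,source_cell Cell matrices; default to the
#'   scenario's.
#' @param out_dir Output directory (created if needed); `NULL` disables
#'   file output.
#' @param cache Reuse cost layers cached in `out_dir` when inputs and
#'   parameters are unchanged.
#' @return A `run_config` list.
#' @export
run_config <- function(scenario = NULL, inputs = NULL,
                       schemes = c("RO1", "RO2", "RO3"),
                       density_radius = 1000, hex_width = 2000,
                       weak_width_km = 4, water_max_km = 5,
                       buffer_km = c(2, 6),
                       start_cells = NULL, source_cell = NULL,
                       out_dir = NULL, cache = TRUE) {
  if (is.null(scenario) && is.null(inputs))
    stop("either a scenario or input paths are required")
  if (!is.null(inputs)) {
    missing <- !vapply(inputs, file.exists, logical(1))
    if (any(missing))
      stop("missing input file(s): ",
           paste(unlist(inputs[missing]), collapse = ", "))
    if (is.null(start_cells) || is.null(source_cell))
      stop("file inputs need explicit start_cells and source_cell")
  }
  if (!is.null(source_cell) && nrow(rbind(source_cell)) != 1)
    stop("exactly one source cell required")
  if (!is.null(start_cells) && nrow(rbind(start_cells)) < 1)
    stop("at least one start cell required")
  structure(as.list(environment()), class = "run_config")
}

#' @rdname run_config
#' @param path YAML configuration file.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$scenario)) {
    sc <- y$scenario
    if (!is.null(sc$habitat_fractions))
      sc$habitat_fractions <- unlist(sc$habitat_fractions)
    y$scenario <- do.call(landscape_scenario, sc)
  }
  for (f in c("start_cells", "source_cell"))
    if (!is.null(y[[f]])) y[[f]] <- do.call(rbind, y[[f]])
  do.call(run_config, y)
}

stage_log <- function(log, stage, ..., echo = TRUE) {
  line <- sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                  paste(sprintf("%s=%s", names(list(...)),
                                vapply(list(...), function(x)
                                  paste(format(x), collapse = ","),
                                  character(1))),
                        collapse = " "))
  if (!is.null(log)) cat(line, "\n", file = log, append = TRUE)
  if (echo) message(line)
  invisible(line)
}

params_hash <- function(...) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(list(...), f)
  unname(tools::md5sum(f))
}

cached_grid <- function(out_dir, name, hash, builder, log) {
  if (is.null(out_dir))
    return(builder())
  asc <- file.path(out_dir, paste0(name, ".asc"))
  hfile <- file.path(out_dir, paste0(name, ".hash"))
  if (file.exists(asc) && file.exists(hfile) &&
      identical(readLines(hfile, n = 1), hash)) {
    stage_log(log, paste0("cost:", name), status = "cached, skipped")
    return(read_grid_asc(asc, kind = "cost"))
  }
  g <- builder()
  write_grid_asc(g, asc)
  writeLines(hash, hfile)
  g
}

#' Run the full corridor pipeline
#'
#' End-to-end orchestration: realise or load the input layers, build the
#' six cost layers (cached in `out_dir` by a hash of inputs and
#' parameters), and for every requested weight scheme compute the
#' composite movement cost, the accumulated-cost surface from the
#' destination cell, one traced path per start cell, the shared-segment
#' decomposition, weak links, water gaps and the corridor buffer. A
#' structured log of every stage and its parameters is written alongside
#' the outputs, so a run can be reconstructed from its log.
#'
#' @param config A [run_config()].
#' @return A `corridor_report`: per-scheme results plus a `comparison`
#'   data.frame of path lengths and costs across schemes.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  log <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    log <- file.path(out_dir, "run.log")
  }

  if (!is.null(config$scenario)) {
    stage_log(log, "inputs", source = "scenario", seed = config$scenario$seed)
    land <- generate_landscape(config$scenario)
  } else {
    stage_log(log, "inputs", source = "files")
    land <- list(
      habitat = read_grid_asc(config$inputs$habitat, kind = "categorical"),
      streams = read_geojson(config$inputs$streams),
      waterbodies = read_geojson(config$inputs$waterbodies),
      roads = read_geojson(config$inputs$roads),
      rail = read_geojson(config$inputs$rail),
      settlements = read_geojson(config$inputs$settlements))
    land$spec <- land$habitat$spec
  }
  start_cells <- rbind(config$start_cells %||% land$start_cells)
  source_cell <- rbind(config$source_cell %||% land$source_cell)
  if (is.null(start_cells) || !nrow(start_cells))
    stop("validation: no start cells")
  spec <- land$spec

  base_hash <- params_hash(land$habitat$values, config$density_radius,
                           config$hex_width)
  H <- cached_grid(out_dir, "cost_H", params_hash("H", base_hash),
                   function() build_habitat_cost(land$habitat), log)
  stage_log(log, "cost:H", table = "habitat")
  WS <- cached_grid(out_dir, "cost_WS",
                    params_hash("WS", base_hash, land$streams, land$waterbodies),
                    function() build_water_cost(land$streams, land$waterbodies,
                                                spec), log)
  if (is.null(attr(WS, "distance"))) # recompute distance when WS came from cache
    attr(WS, "distance") <- attr(build_water_cost(land$streams,
                                                  land$waterbodies, spec),
                                 "distance")
  stage_log(log, "cost:WS", table = "water_distance")
  RD <- cached_grid(out_dir, "cost_RD",
                    params_hash("RD", base_hash, land$roads),
                    function() build_road_cost(land$roads, spec,
                                               config$density_radius), log)
  stage_log(log, "cost:RD", radius_m = config$density_radius)
  R <- cached_grid(out_dir, "cost_R", params_hash("R", base_hash, land$rail),
                   function() build_rail_cost(land$rail, spec), log)
  stage_log(log, "cost:R", table = "railway")
  S <- cached_grid(out_dir, "cost_S",
                   params_hash("S", base_hash, land$settlements),
                   function() build_settlement_cost(land$settlements, spec,
                                                    config$density_radius), log)
  stage_log(log, "cost:S", radius_m = config$density_radius)
  TEg <- cached_grid(out_dir, "cost_TE", params_hash("TE", base_hash),
                     function() build_edge_cost(land$habitat,
                                                config$hex_width), log)
  stage_log(log, "cost:TE", hex_width_m = config$hex_width)

  stack <- cost_stack(H = H, S = S, WS = WS, TE = TEg, RD = RD, R = R)
  forest <- forest_mask(land$habitat)
  edge_grid <- if (!is.null(attr(TEg, "reports"))) TEg else
    build_edge_cost(land$habitat, config$hex_width)

  schemes <- lapply(config$schemes, function(s)
    if (inherits(s, "weight_scheme")) s else run_option(s))
  results <- list()
  for (sch in schemes) {
    stage_log(log, "scheme", name = sch$name,
              weights = paste(names(sch$weights), sch$weights,
                              sep = ":", collapse = " "))
    cm <- composite_cost(stack, sch)
    accres <- accumulate_cost(cm, source_cell)
    paths <- lapply(seq_len(nrow(start_cells)), function(i)
      trace_path(accres, start_cells[i, ]))
    names(paths) <- paste0("start_", seq_along(paths))
    segs <- if (length(paths) > 1) shared_segments(paths) else NULL
    wl <- lapply(paths, weak_links, forest = forest,
                 width_threshold_km = config$weak_width_km,
                 edge_cost = edge_grid)
    wg <- lapply(paths, water_gaps, water_dist = attr(WS, "distance"),
                 max_km = config$water_max_km)
    buf <- buffer_corridor(paths[[1]], config$buffer_km[1],
                           config$buffer_km[2], weak = wl[[1]])
    stage_log(log, "corridor", scheme = sch$name,
              n_paths = length(paths),
              lengths_km = paste(sprintf("%.2f",
                vapply(paths, `[[`, numeric(1), "length_km")),
                collapse = ","))
    if (!is.null(out_dir)) {
      write_paths_geojson(paths,
        file.path(out_dir, sprintf("paths_%s.geojson", sch$name)))
      utils::write.csv(do.call(rbind, lapply(names(wl), function(nm)
        if (nrow(wl[[nm]])) cbind(path = nm, wl[[nm]]))),
        file.path(out_dir, sprintf("weak_links_%s.csv", sch$name)),
        row.names = FALSE)
      if (!is.null(segs))
        utils::write.csv(segs,
          file.path(out_dir, sprintf("segments_%s.csv", sch$name)),
          row.names = FALSE)
    }
    results[[sch$name]] <- list(scheme = sch, cm = cm, accumulated = accres,
                                paths = paths, segments = segs,
                                weak_links = wl, water_gaps = wg,
                                buffer = buf)
  }

  comparison <- do.call(rbind, lapply(names(results), function(nm) {
    ps <- results[[nm]]$paths
    data.frame(scheme = nm, path = names(ps),
               length_km = vapply(ps, `[[`, numeric(1), "length_km"),
               total_cost = vapply(ps, `[[`, numeric(1), "total_cost"),
               n_weak_links = vapply(results[[nm]]$weak_links, nrow,
                                     integer(1)))
  }))
  rownames(comparison) <- NULL
  if (!is.null(out_dir))
    utils::write.csv(comparison, file.path(out_dir, "comparison.csv"),
                     row.names = FALSE)
  stage_log(log, "done", schemes = length(results))
  structure(list(landscape = land, stack = stack, results = results,
                 comparison = comparison, config = config),
            class = "corridor_report")
}

#' @export
print.corridor_report <- function(x, ...) {
  cat("<corridor_report>\n")
  print(x$comparison)
  invisible(x)
}
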