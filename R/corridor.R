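#' Accumulated cost surface from source cells
#'
#' Dijkstra-style cost-distance accumulation over the composite movement
#' cost grid: 8-connected (optionally 4-connected) moves with transition
#' cost `(cm[a] + cm[b]) / 2` per orthogonal step and `sqrt(2)` times
#' that per diagonal step, in cell units. Returns the minimal cumulative
#' cost to any source cell together with a backlink direction grid from
#' which least-cost paths are traced. In corridor use the destination
#' park's periphery cells are the Dijkstra sources and each start cell is
#' traced back to them.
#'
#' @param cm Non-negative continuous `tc_grid` (composite movement cost);
#'   `NA` cells are impassable.
#' @param sources Two-column matrix (or vector of length 2) of 1-based
#'   `(row, col)` source cells.
#' @param diagonal Allow diagonal moves (default `TRUE`).
#' @return An `accumulated_cost` object: `acc` (accumulated `tc_grid`),
#'   `backlink` (direction-code grid, 0 = source/unreached) and `sources`.
#' @export
accumulate_cost <- function(cm, sources, diagonal = TRUE) {
  stopifnot(inherits(cm, "tc_grid"))
  if (any(cm$values < 0, na.rm = TRUE)) stop("cm must be non-negative")
  sources <- rbind(sources)
  if (!nrow(sources)) stop("at least one source cell required")
  if (all(is.na(cm$values))) stop("all-nodata grid")
  res <- cpp_accumulate(cm$values, as.integer(sources[, 1]),
                        as.integer(sources[, 2]), diagonal)
  structure(list(
    acc = new_grid(res$acc, cm$spec, kind = "accumulated"),
    backlink = new_grid(res$backlink, cm$spec, kind = "continuous"),
    sources = sources, spec = cm$spec),
    class = "accumulated_cost")
}

# direction deltas for backlink codes 1..8 = N, NE, E, SE, S, SW, W, NW
dir_delta <- cbind(dr = c(-1, -1, 0, 1, 1, 1, 0, -1),
                   dc = c(0, 1, 1, 1, 0, -1, -1, -1))

#' Trace a least-cost path from a start cell
#'
#' Follows the backlink grid from the start cell down to a source cell,
#' recording the cell sequence, the geometric length (orthogonal steps =
#' one cell size, diagonal steps = `sqrt(2)` cell sizes) and the total
#' accumulated cost at the start.
#'
#' @param accres An [accumulate_cost()] result.
#' @param start `(row, col)` start cell (1-based).
#' @return A `corridor_path`: `cells` (n x 2 matrix, start first, source
#'   last), `length_km`, `total_cost`, `spec`.
#' @export
trace_path <- function(accres, start) {
  start <- as.integer(start)
  acc <- accres$acc$values
  if (is.na(acc[start[1], start[2]]))
    stop("start cell is unreachable from the sources")
  bl <- accres$backlink$values
  spec <- accres$spec
  cells <- matrix(start, 1, 2)
  r <- start[1]; c <- start[2]
  len <- 0
  repeat {
    code <- bl[r, c]
    if (code == 0) break
    r <- r + dir_delta[code, 1]
    c <- c + dir_delta[code, 2]
    len <- len + ifelse(code %% 2 == 0, sqrt(2), 1)
    cells <- rbind(cells, c(r, c))
  }
  dimnames(cells) <- list(NULL, c("row", "col"))
  structure(list(cells = cells,
                 length_km = len * spec$cell_size / 1000,
                 total_cost = acc[start[1], start[2]],
                 spec = spec),
            class = "corridor_path")
}

#' @export
print.corridor_path <- function(x, ...) {
  cat(sprintf("<corridor_path> %d cells, %.2f km, accumulated cost %.2f\n",
              nrow(x$cells), x$length_km, x$total_cost))
  invisible(x)
}

path_step_lengths <- function(path) {
  d <- abs(diff(path$cells))
  ifelse(rowSums(d) == 2, sqrt(2), 1) * path$spec$cell_size / 1000
}

#' Decompose corridor paths into shared and private segments
#'
#' Paths traced to the same destination share suffixes: routes from
#' different start cells merge and continue along one common trunk. The
#' decomposition walks the paths backwards from the source cell and emits
#' a segment wherever the set of paths travelling together changes —
#' `common` segments carried by two or more paths, `private` segments by
#' one. Each path's length equals the sum of the lengths of the segments
#' it participates in (the step joining two segments is charged to the
#' segment farther from the source).
#'
#' @param paths List of two or more [trace_path()] results ending at the
#'   same source cell.
#' @return data.frame with `segment_id`, `type`, `n_paths`, `path_ids`
#'   (slash-separated indices into `paths`), `n_cells`, `length_km`.
#' @export
shared_segments <- function(paths) {
  if (length(paths) < 2) stop("need at least two paths")
  rev_cells <- lapply(paths, function(p) p$cells[rev(seq_len(nrow(p$cells))), , drop = FALSE])
  src <- rev_cells[[1]][1, ]
  for (rc in rev_cells)
    if (!all(rc[1, ] == src)) stop("paths do not share one source cell")
  cs <- paths[[1]]$spec$cell_size
  segs <- list()
  emit <- function(type, ids, cells, join_cell) {
    n <- nrow(cells)
    len <- 0
    if (!is.null(join_cell)) {
      all_cells <- rbind(join_cell, cells)
    } else all_cells <- cells
    if (nrow(all_cells) > 1) {
      d <- abs(diff(all_cells))
      len <- sum(ifelse(rowSums(d) == 2, sqrt(2), 1)) * cs / 1000
    }
    segs[[length(segs) + 1L]] <<- data.frame(
      type = type, n_paths = length(ids),
      path_ids = paste(ids, collapse = "/"),
      n_cells = n, length_km = len)
  }
  walk <- function(ids, depth, join_cell) {
    if (length(ids) == 1L) {
      rc <- rev_cells[[ids]]
      if (depth <= nrow(rc))
        emit("private", ids, rc[depth:nrow(rc), , drop = FALSE], join_cell)
      return(invisible())
    }
    d0 <- depth
    repeat {
      ok <- all(vapply(ids, function(i) depth <= nrow(rev_cells[[i]]), logical(1)))
      if (!ok) break
      ref <- rev_cells[[ids[1]]][depth, ]
      same <- all(vapply(ids[-1], function(i)
        all(rev_cells[[i]][depth, ] == ref), logical(1)))
      if (!same) break
      depth <- depth + 1L
    }
    if (depth > d0)
      emit("common", ids, rev_cells[[ids[1]]][d0:(depth - 1L), , drop = FALSE],
           join_cell)
    live <- ids[vapply(ids, function(i) depth <= nrow(rev_cells[[i]]), logical(1))]
    if (!length(live)) return(invisible())
    jc <- if (depth > 1L) rev_cells[[ids[1]]][depth - 1L, ] else NULL
    keys <- vapply(live, function(i) paste(rev_cells[[i]][depth, ], collapse = ","),
                   character(1))
    for (k in unique(keys)) walk(live[keys == k], depth, jc)
  }
  walk(seq_along(paths), 1L, NULL)
  out <- do.call(rbind, segs)
  out$segment_id <- seq_len(nrow(out))
  out[, c("segment_id", "type", "n_paths", "path_ids", "n_cells", "length_km")]
}

#' Flag weak links along a corridor path
#'
#' Forest width at a path cell is twice its Euclidean distance to the
#' nearest non-forest cell. Maximal runs of consecutive path cells whose
#' width falls below the threshold become weak links. A run is attributed
#' to `fragmentation` when the surrounding hexagon Total Edge cost is
#' severe (>= 8) and to `constriction` otherwise.
#'
#' @param path A [trace_path()] result.
#' @param forest Binary forest `tc_grid` (see [forest_mask()]).
#' @param width_threshold_km Width below which a span is flagged
#'   (default 4).
#' @param edge_cost Optional Total Edge cost `tc_grid` (see
#'   [build_edge_cost()]) used to classify the cause.
#' @return data.frame with `link_id`, `start_index`, `end_index` (indices
#'   into the path cells), `length_km`, `min_width_km`, `cause`; zero rows
#'   when no span falls below the threshold.
#' @export
weak_links <- function(path, forest, width_threshold_km = 4,
                       edge_cost = NULL) {
  nf <- new_grid(1 - forest$values, forest$spec)
  width_km <- if (any(nf$values == 1, na.rm = TRUE)) {
    d <- euclidean_distance(nf, forest$spec)
    2 * d$values[path$cells] / 1000
  } else rep(Inf, nrow(path$cells))
  below <- width_km < width_threshold_km
  runs <- rle(below)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  if (!length(keep))
    return(data.frame(link_id = integer(), start_index = integer(),
                      end_index = integer(), length_km = numeric(),
                      min_width_km = numeric(), cause = character()))
  steps <- path_step_lengths(path)
  out <- lapply(seq_along(keep), function(k) {
    i0 <- starts[keep[k]]; i1 <- ends[keep[k]]
    cause <- "constriction"
    if (!is.null(edge_cost)) {
      ec <- edge_cost$values[path$cells[i0:i1, , drop = FALSE]]
      if (max(ec, na.rm = TRUE) >= 8) cause <- "fragmentation"
    }
    data.frame(link_id = k, start_index = i0, end_index = i1,
               length_km = if (i1 > i0) sum(steps[i0:(i1 - 1L)]) else 0,
               min_width_km = min(width_km[i0:i1]), cause = cause)
  })
  do.call(rbind, out)
}

#' Buffer a corridor path
#'
#' Demarcates a management buffer around the traced route: the union of
#' per-cell discs whose radius is `max_km` where forest is continuous and
#' narrows to `min_km` inside weak-link spans, with a linear taper (one km
#' of radius per km along the path) at span boundaries.
#'
#' @param path A [trace_path()] result.
#' @param min_km,max_km Buffer radii in km, `0 < min_km <= max_km`.
#' @param weak Optional [weak_links()] table controlling where the buffer
#'   narrows.
#' @return A list: `mask` (binary `tc_grid` of the buffer), `area_km2`,
#'   `radius_km` (per path cell) and `outline` (list of closed rings, each
#'   an n x 2 coordinate matrix).
#' @export
buffer_corridor <- function(path, min_km, max_km, weak = NULL) {
  if (!(min_km > 0 && min_km <= max_km)) stop("need 0 < min_km <= max_km")
  n <- nrow(path$cells)
  radius <- rep(max_km, n)
  if (!is.null(weak) && nrow(weak)) {
    steps <- path_step_lengths(path)
    arc <- c(0, cumsum(steps))
    dist_to_weak <- rep(Inf, n)
    for (k in seq_len(nrow(weak))) {
      i0 <- weak$start_index[k]; i1 <- weak$end_index[k]
      d <- pmax(pmax(arc[i0] - arc, arc - arc[i1]), 0)
      dist_to_weak <- pmin(dist_to_weak, d)
    }
    radius <- pmin(max_km, min_km + dist_to_weak)
  }
  spec <- path$spec
  mask <- matrix(0, spec$n_rows, spec$n_cols)
  cc <- cell_centres(spec)
  for (i in seq_len(n)) {
    r_m <- radius[i] * 1000
    p <- c(cc$x[path$cells[i, 2]], cc$y[path$cells[i, 1]])
    rows <- cand_range(spec$origin_y - c(p[2] + r_m, p[2] - r_m),
                       spec$cell_size, spec$n_rows)
    cols <- cand_range(c(p[1] - r_m, p[1] + r_m) - spec$origin_x,
                       spec$cell_size, spec$n_cols)
    if (!length(rows) || !length(cols)) next
    cx <- matrix(cc$x[cols], length(rows), length(cols), byrow = TRUE)
    cy <- matrix(cc$y[rows], length(rows), length(cols))
    hit <- (cx - p[1])^2 + (cy - p[2])^2 <= r_m^2
    mask[rows, cols] <- pmax(mask[rows, cols], hit)
  }
  outline <- grDevices::contourLines(
    x = cc$x, y = rev(cc$y), z = t(mask[spec$n_rows:1, , drop = FALSE]),
    levels = 0.5)
  rings <- lapply(outline, function(o) cbind(o$x, o$y))
  list(mask = new_grid(mask, spec),
       area_km2 = sum(mask) * (spec$cell_size / 1000)^2,
       radius_km = radius, outline = rings)
}

#' Along-path water-gap analysis
#'
#' Audits water availability along the corridor: path cells farther than
#' `max_km` from the nearest perennial water source form maximal gap
#' spans. For each gap the along-path length is reported and waterhole
#' cells are proposed by greedy midpoint placement — a hole at the
#' midpoint of the longest uncovered stretch, repeated until every path
#' cell lies within `max_km` of original or proposed water.
#'
#' @param path A [trace_path()] result.
#' @param water_dist Continuous `tc_grid` of distance-to-water in metres
#'   (the `"distance"` attribute of [build_water_cost()]), or a water-cost
#'   grid carrying that attribute.
#' @param max_km Maximum acceptable distance to water (default 5).
#' @return A list: `gaps` (data.frame `gap_id`, `start_index`,
#'   `end_index`, `length_km`, `max_dist_km`), `waterholes` (m x 2 matrix
#'   of proposed cells), `dist_km` (per path cell, before placement).
#' @export
water_gaps <- function(path, water_dist, max_km = 5) {
  if (max_km <= 0) stop("max_km must be > 0")
  if (!is.null(attr(water_dist, "distance")))
    water_dist <- attr(water_dist, "distance")
  d_km <- water_dist$values[path$cells] / 1000
  over <- d_km > max_km
  runs <- rle(as.vector(over))
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  steps <- path_step_lengths(path)
  gaps <- if (length(keep)) do.call(rbind, lapply(seq_along(keep), function(k) {
    i0 <- starts[keep[k]]; i1 <- ends[keep[k]]
    data.frame(gap_id = k, start_index = i0, end_index = i1,
               length_km = if (i1 > i0) sum(steps[i0:(i1 - 1L)]) else 0,
               max_dist_km = max(d_km[i0:i1]))
  })) else data.frame(gap_id = integer(), start_index = integer(),
                      end_index = integer(), length_km = numeric(),
                      max_dist_km = numeric())
  # greedy midpoint placement of waterholes until the whole path is covered
  holes <- matrix(integer(0), 0, 2)
  cov_km <- d_km
  cs <- path$spec$cell_size / 1000
  while (any(cov_km > max_km)) {
    r <- rle(as.vector(cov_km > max_km))
    e <- cumsum(r$lengths); s <- e - r$lengths + 1L
    unc <- which(r$values)
    longest <- unc[which.max(r$lengths[unc])]
    mid <- (s[longest] + e[longest]) %/% 2L
    hole <- path$cells[mid, , drop = FALSE]
    holes <- rbind(holes, hole)
    dd <- sqrt((path$cells[, 1] - hole[1])^2 +
               (path$cells[, 2] - hole[2])^2) * cs
    cov_km <- pmin(cov_km, dd)
  }
  dimnames(holes) <- list(NULL, c("row", "col"))
  list(gaps = gaps, waterholes = holes, dist_km = d_km)
}

#' Write corridor paths as GeoJSON LineStrings
#'
#' @param paths Named list of [trace_path()] results.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_paths_geojson <- function(paths, path) {
  feats <- lapply(seq_along(paths), function(i) {
    p <- paths[[i]]
    cc <- cell_centres(p$spec)
    coords <- lapply(seq_len(nrow(p$cells)), function(j)
      c(cc$x[p$cells[j, 2]], cc$y[p$cells[j, 1]]))
    list(type = "Feature",
         geometry = list(type = "LineString", coordinates = coords),
         properties = list(name = names(paths)[i] %||% paste0("path_", i),
                           length_km = p$length_km,
                           total_cost = p$total_cost))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
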