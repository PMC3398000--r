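#' Burn a vector layer onto a raster grid
#'
#' Presence mode marks every cell intersected by a geometry with 1 (0
#' elsewhere). Attribute mode burns a named numeric attribute into the
#' intersected cells and leaves all other cells nodata; overlapping
#' features are burned in feature order (last wins).
#'
#' Polylines are traversed exactly: each segment is split at every grid
#' line crossing and the cell of each sub-interval midpoint is marked.
#' Polygons mark cells whose centre lies inside (even-odd rule); points
#' mark their containing cell.
#'
#' @param layer A [vector_layer()].
#' @param spec A [grid_spec()].
#' @param mode `"presence"` or `"attribute"`.
#' @param attr Attribute name burned in attribute mode.
#' @return A `tc_grid` (continuous kind).
#' @export
rasterize <- function(layer, spec, mode = c("presence", "attribute"),
                      attr = NULL) {
  mode <- match.arg(mode)
  if (mode == "attribute" && is.null(attr))
    stop("attribute mode needs an attribute name")
  v <- matrix(if (mode == "presence") 0 else NA_real_,
              spec$n_rows, spec$n_cols)
  if (!n_features(layer)) {
    warning("rasterize: empty layer '", layer$geometry_type, "'")
    if (mode == "presence") return(new_grid(v, spec))
    return(new_grid(v, spec))
  }
  for (f in layer$features) {
    cells <- switch(layer$geometry_type,
      point    = xy_to_cell(f$geom[, 1], f$geom[, 2], spec),
      polyline = polyline_cells(f$geom, spec),
      polygon  = polygon_cells(f$geom, spec))
    cells <- cells[stats::complete.cases(cells), , drop = FALSE]
    if (!nrow(cells)) next
    val <- if (mode == "presence") 1 else {
      a <- f$attrs[[attr]]
      if (is.null(a)) stop("feature lacks required attribute '", attr, "'")
      as.numeric(a)
    }
    v[cells] <- val
  }
  new_grid(v, spec)
}

# cells traversed by a polyline: split each segment at every grid-line
# crossing; the midpoint of each piece identifies its cell
polyline_cells <- function(coords, spec) {
  out <- vector("list", nrow(coords) - 1L)
  for (i in seq_len(nrow(coords) - 1L)) {
    p0 <- coords[i, ]; p1 <- coords[i + 1L, ]
    d <- p1 - p0
    ts <- c(0, 1)
    if (d[1] != 0) {
      xs <- spec$origin_x + seq_len(spec$n_cols - 1L) * spec$cell_size
      t <- (xs - p0[1]) / d[1]
      ts <- c(ts, t[t > 0 & t < 1])
    }
    if (d[2] != 0) {
      ys <- spec$origin_y - seq_len(spec$n_rows - 1L) * spec$cell_size
      t <- (ys - p0[2]) / d[2]
      ts <- c(ts, t[t > 0 & t < 1])
    }
    ts <- sort(unique(ts))
    tm <- (ts[-1] + ts[-length(ts)]) / 2
    out[[i]] <- xy_to_cell(p0[1] + tm * d[1], p0[2] + tm * d[2], spec)
  }
  unique(do.call(rbind, out))
}

# cells whose centre lies inside the polygon (even-odd rule)
polygon_cells <- function(coords, spec) {
  cc <- cell_centres(spec)
  px <- coords[, 1]; py <- coords[, 2]
  n <- nrow(coords)
  xs <- rep(cc$x, each = spec$n_rows)
  ys <- rep(cc$y, times = spec$n_cols)
  inside <- rep(FALSE, length(xs))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((py[i] > ys) != (py[j] > ys)) &
      (xs < (px[j] - px[i]) * (ys - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  idx <- which(inside)
  cbind(row = (idx - 1L) %% spec$n_rows + 1L,
        col = (idx - 1L) %/% spec$n_rows + 1L)
}
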