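#' Weighted line density
#'
#' For every cell centre, the summed length of all line segments clipped
#' to a search circle of the given radius, weighted by a per-feature
#' attribute, divided by the circle area. With a PCU attribute on road
#' segments this is traffic-weighted road density in pcu/m (weight times
#' metres of line per square metre).
#'
#' @param lines A polyline [vector_layer()].
#' @param spec A [grid_spec()].
#' @param radius Search radius in metres (> 0).
#' @param weight_attr Name of the numeric per-feature weight attribute, or
#'   `NULL` for unweighted density.
#' @return Continuous `tc_grid` in weight·m/m².
#' @export
line_density <- function(lines, spec, radius, weight_attr = NULL) {
  if (radius <= 0) stop("radius must be > 0")
  stopifnot(lines$geometry_type == "polyline")
  out <- matrix(0, spec$n_rows, spec$n_cols)
  cc <- cell_centres(spec)
  for (f in lines$features) {
    w <- if (is.null(weight_attr)) 1 else {
      a <- f$attrs[[weight_attr]]
      if (is.null(a) || !is.numeric(a))
        stop("feature lacks numeric attribute '", weight_attr, "'")
      as.numeric(a)
    }
    g <- f$geom
    for (i in seq_len(nrow(g) - 1L)) {
      p0 <- g[i, ]; p1 <- g[i + 1L, ]
      d <- p1 - p0
      L2 <- sum(d * d)
      if (L2 == 0) next
      L <- sqrt(L2)
      # candidate cells: segment bounding box grown by the radius
      rows <- cand_range(spec$origin_y - c(max(p0[2], p1[2]) + radius,
                                           min(p0[2], p1[2]) - radius),
                         spec$cell_size, spec$n_rows)
      cols <- cand_range(c(min(p0[1], p1[1]) - radius,
                           max(p0[1], p1[1]) + radius) - spec$origin_x,
                         spec$cell_size, spec$n_cols)
      if (!length(rows) || !length(cols)) next
      cx <- matrix(cc$x[cols], length(rows), length(cols), byrow = TRUE)
      cy <- matrix(cc$y[rows], length(rows), length(cols))
      # clip segment parameter range to the circle |p0 + t d - c| = radius
      bx <- p0[1] - cx; by <- p0[2] - cy
      b <- 2 * (d[1] * bx + d[2] * by)
      cterm <- bx * bx + by * by - radius * radius
      disc <- b * b - 4 * L2 * cterm
      pos <- disc > 0
      if (!any(pos)) next
      sq <- sqrt(pmax(disc, 0))
      t1 <- pmax((-b - sq) / (2 * L2), 0)
      t2 <- pmin((-b + sq) / (2 * L2), 1)
      len <- pmax(t2 - t1, 0) * L
      len[!pos] <- 0
      out[rows, cols] <- out[rows, cols] + len * w
    }
  }
  new_grid(out / (pi * radius^2), spec, kind = "continuous")
}

#' Weighted point density
#'
#' For every cell centre, the sum of weights of all points lying within
#' the search radius, divided by the circle area. With settlement
#' population weights this is population density in pop/m².
#'
#' @param points A point [vector_layer()].
#' @inheritParams line_density
#' @return Continuous `tc_grid` in weight/m².
#' @export
point_density <- function(points, spec, radius, weight_attr = NULL) {
  if (radius <= 0) stop("radius must be > 0")
  stopifnot(points$geometry_type == "point")
  out <- matrix(0, spec$n_rows, spec$n_cols)
  cc <- cell_centres(spec)
  for (f in points$features) {
    w <- if (is.null(weight_attr)) 1 else {
      a <- f$attrs[[weight_attr]]
      if (is.null(a) || !is.numeric(a))
        stop("feature lacks numeric attribute '", weight_attr, "'")
      as.numeric(a)
    }
    p <- f$geom[1, ]
    rows <- cand_range(spec$origin_y - c(p[2] + radius, p[2] - radius),
                       spec$cell_size, spec$n_rows)
    cols <- cand_range(c(p[1] - radius, p[1] + radius) - spec$origin_x,
                       spec$cell_size, spec$n_cols)
    if (!length(rows) || !length(cols)) next
    cx <- matrix(cc$x[cols], length(rows), length(cols), byrow = TRUE)
    cy <- matrix(cc$y[rows], length(rows), length(cols))
    hit <- (cx - p[1])^2 + (cy - p[2])^2 <= radius^2
    out[rows, cols] <- out[rows, cols] + hit * w
  }
  new_grid(out / (pi * radius^2), spec, kind = "continuous")
}

# clamp a [min, max] coordinate offset range to valid 1-based indices
cand_range <- function(range_m, cell, n) {
  i0 <- max(1L, floor(min(range_m) / cell) + 1L)
  i1 <- min(n, ceiling(max(range_m) / cell))
  if (i0 > i1) integer(0) else i0:i1
}
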