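#' Hexagonal tessellation of a grid extent
#'
#' Tiles the grid extent with flat-top regular hexagons of a given
#' flat-to-flat width and assigns every raster cell centre to exactly one
#' hexagon (nearest hexagon centre via axial-coordinate rounding). Each
#' hexagon is later treated as one landscape unit for the Total Edge
#' metric.
#'
#' @param spec A [grid_spec()].
#' @param hex_width Flat-to-flat hexagon width in metres; must be at least
#'   3 cell sizes.
#' @return Object of class `hex_tessellation`: a data.frame `hexes`
#'   (`id`, axial `q`, `r`, centre `cx`, `cy`, `n_cells`) and an integer
#'   `assignment` matrix mapping each cell to a hexagon id.
#' @export
tessellate <- function(spec, hex_width = 2000) {
  if (hex_width < 3 * spec$cell_size)
    stop("hex_width must be at least 3 x cell_size")
  R <- hex_width / sqrt(3) # circumradius of a flat-top hexagon
  cc <- cell_centres(spec)
  x <- rep(cc$x, each = spec$n_rows) - spec$origin_x
  y <- spec$origin_y - rep(cc$y, times = spec$n_cols) # local, y down
  qf <- (2 / 3) * x / R
  rf <- (-x / 3 + sqrt(3) / 3 * y) / R
  ax <- axial_round(qf, rf)
  key <- paste(ax$q, ax$r)
  uk <- unique(key)
  id <- match(key, uk)
  assignment <- matrix(id, spec$n_rows, spec$n_cols)
  first <- match(uk, key)
  q <- ax$q[first]; r <- ax$r[first]
  hexes <- data.frame(
    id = seq_along(uk), q = q, r = r,
    cx = spec$origin_x + R * 1.5 * q,
    cy = spec$origin_y - R * sqrt(3) * (r + q / 2),
    n_cells = as.integer(tabulate(id, length(uk))))
  structure(list(hexes = hexes, assignment = assignment,
                 hex_width = hex_width, spec = spec),
            class = "hex_tessellation")
}

axial_round <- function(q, r) {
  s <- -q - r
  rq <- round(q); rr <- round(r); rs <- round(s)
  dq <- abs(rq - q); dr <- abs(rr - r); ds <- abs(rs - s)
  fixq <- dq > dr & dq > ds
  fixr <- !fixq & dr > ds
  rq[fixq] <- -rr[fixq] - rs[fixq]
  rr[fixr] <- -rq[fixr] - rs[fixr]
  list(q = as.integer(rq), r = as.integer(rr))
}

#' Hexagon outline polygon
#'
#' @param tess A [tessellate()] result.
#' @param id Hexagon id.
#' @return A 6 x 2 matrix of vertex coordinates (planar metres).
#' @export
hex_polygon <- function(tess, id) {
  h <- tess$hexes[tess$hexes$id == id, ]
  if (!nrow(h)) stop("unknown hexagon id ", id)
  R <- tess$hex_width / sqrt(3)
  ang <- (0:5) * pi / 3
  cbind(h$cx + R * cos(ang), h$cy + R * sin(ang))
}

#' Per-hexagon Total Edge
#'
#' Total Edge (TE) of a landscape unit is the summed length in metres of
#' all boundaries between classes inside it; TE = 0 when the unit is a
#' single class. On a raster the edge is the set of rook-adjacent cell
#' pairs with differing class, each contributing one cell edge length.
#' Pairs straddling two hexagons are counted once, for the hexagon of the
#' lexicographically smaller (upper/left) cell; edges along the landscape
#' boundary are not counted.
#'
#' @param forest Binary `tc_grid` (forest = 1, non-forest = 0) obtained by
#'   merging all forest classes into one.
#' @param tess A [tessellate()] result on the same spec.
#' @return data.frame with `hex_id`, `centre_x`, `centre_y`,
#'   `total_edge_m` and `cost` (the Total Edge cost table rank).
#' @export
total_edge <- function(forest, tess) {
  v <- forest$values
  if (!all(v[!is.na(v)] %in% c(0, 1)))
    stop("total_edge expects a binary forest/non-forest grid")
  A <- tess$assignment
  cs <- forest$spec$cell_size
  nhex <- nrow(tess$hexes)
  te <- numeric(nhex)
  nr <- nrow(v); nc <- ncol(v)
  if (nc > 1) {
    diffh <- v[, -nc, drop = FALSE] != v[, -1, drop = FALSE]
    diffh[is.na(diffh)] <- FALSE
    # pair owned by its left cell's hexagon
    te <- te + tabulate(A[, -nc, drop = FALSE][diffh], nhex)
  }
  if (nr > 1) {
    diffv <- v[-nr, , drop = FALSE] != v[-1, , drop = FALSE]
    diffv[is.na(diffv)] <- FALSE
    te <- te + tabulate(A[-nr, , drop = FALSE][diffv], nhex)
  }
  data.frame(hex_id = tess$hexes$id,
             centre_x = tess$hexes$cx, centre_y = tess$hexes$cy,
             total_edge_m = te * cs,
             cost = reclass_value(te_cost_table(), te * cs))
}

#' Spread per-hexagon edge costs back onto the raster
#'
#' Every raster cell receives the Total Edge cost rank of the hexagon it
#' belongs to.
#'
#' @param reports Output of [total_edge()].
#' @param tess The [tessellate()] result the reports were computed on.
#' @return A cost-kind `tc_grid`.
#' @export
edge_cost_grid <- function(reports, tess) {
  cost <- reports$cost[match(as.vector(tess$assignment), reports$hex_id)]
  if (anyNA(cost)) stop("every hexagon needs an edge report")
  new_grid(matrix(cost, nrow(tess$assignment), ncol(tess$assignment)),
           tess$spec, kind = "cost")
}
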