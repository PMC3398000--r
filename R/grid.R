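#' Define the geometry of a raster grid
#'
#' A `grid_spec` fixes the geometry every raster in one analysis shares:
#' dimensions, cell size and the planar position of the top-left corner.
#' All layers combined into a composite cost surface must carry an
#' identical spec.
#'
#' @param n_rows,n_cols Grid dimensions (row 1 is the northernmost row).
#' @param cell_size Cell edge length in metres.
#' @param origin_x,origin_y Planar metres of the top-left (north-west)
#'   corner of the grid. Defaults put the lower-left corner at (0, 0).
#' @param nodata Sentinel value used when grids are written to disk.
#' @return An object of class `grid_spec`.
#' @examples
#' grid_spec(100, 150, 100)
#' @export
grid_spec <- function(n_rows, n_cols, cell_size,
                      origin_x = 0, origin_y = n_rows * cell_size,
                      nodata = -9999) {
  stopifnot(n_rows >= 1, n_cols >= 1, cell_size > 0)
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         cell_size = as.numeric(cell_size),
         origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
         nodata = as.numeric(nodata)),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells, %g m cells, origin (%g, %g)\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_x, x$origin_y))
  invisible(x)
}

#' Construct a raster grid
#'
#' The universal carrier for every layer in the pipeline: categorical
#' habitat, continuous distances and densities, ranked cost layers and
#' accumulated cost. Values are held as a numeric matrix in row-major map
#' orientation (row 1 = north). `NA` marks nodata. Categorical grids store
#' integer class codes together with a `levels` character vector.
#'
#' @param values Numeric matrix of `spec$n_rows` x `spec$n_cols`.
#' @param spec A [grid_spec()].
#' @param kind One of `"continuous"`, `"categorical"`, `"cost"`,
#'   `"accumulated"`.
#' @param levels Optional character vector of class labels for categorical
#'   grids; `values` then holds 1-based indices into `levels`.
#' @return An object of class `tc_grid`.
#' @export
new_grid <- function(values, spec,
                     kind = c("continuous", "categorical", "cost", "accumulated"),
                     levels = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(spec, "grid_spec"))
  values <- as.matrix(values)
  if (!all(dim(values) == c(spec$n_rows, spec$n_cols)))
    stop("values must be ", spec$n_rows, " x ", spec$n_cols)
  storage.mode(values) <- "double"
  structure(list(spec = spec, values = values, kind = kind, levels = levels),
            class = "tc_grid")
}

#' @export
print.tc_grid <- function(x, ...) {
  rng <- suppressWarnings(range(x$values, na.rm = TRUE))
  cat(sprintf("<tc_grid:%s> %d x %d @ %g m, range [%g, %g], %d nodata\n",
              x$kind, x$spec$n_rows, x$spec$n_cols, x$spec$cell_size,
              rng[1], rng[2], sum(is.na(x$values))))
  invisible(x)
}

#' Cell-centre coordinates of a grid
#'
#' @param spec A [grid_spec()].
#' @return List with `x` (length `n_cols`) and `y` (length `n_rows`) centre
#'   coordinates in planar metres; y decreases with row index.
#' @export
cell_centres <- function(spec) {
  list(x = spec$origin_x + (seq_len(spec$n_cols) - 0.5) * spec$cell_size,
       y = spec$origin_y - (seq_len(spec$n_rows) - 0.5) * spec$cell_size)
}

#' Map planar coordinates to cell indices
#'
#' @param x,y Coordinates in planar metres.
#' @param spec A [grid_spec()].
#' @return Matrix with columns `row`, `col` (1-based); coordinates outside
#'   the extent give `NA`.
#' @export
xy_to_cell <- function(x, y, spec) {
  col <- floor((x - spec$origin_x) / spec$cell_size) + 1L
  row <- floor((spec$origin_y - y) / spec$cell_size) + 1L
  bad <- row < 1L | row > spec$n_rows | col < 1L | col > spec$n_cols
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  cbind(row = row, col = col)
}

same_spec <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 1e-9))
}

check_aligned <- function(...) {
  grids <- list(...)
  s <- grids[[1]]$spec
  for (g in grids[-1])
    if (!same_spec(s, g$spec)) stop("grids do not share one grid_spec")
  invisible(s)
}

#' Read and write rasters as ESRI ASCII grids
#'
#' Plain-text raster exchange format (`ncols/nrows/xllcorner/yllcorner/`
#' `cellsize/NODATA_value` header followed by rows north to south). For
#' categorical grids the class labels are stored in a JSON side-car file
#' `<path>.levels.json` and restored on read.
#'
#' @param grid A [new_grid()] object.
#' @param path File path (conventionally `.asc`).
#' @param kind Grid kind to attach on read.
#' @return `read_grid_asc` returns a `tc_grid`; `write_grid_asc` returns
#'   `path` invisibly.
#' @export
write_grid_asc <- function(grid, path) {
  s <- grid$spec
  v <- grid$values
  v[is.na(v)] <- s$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", s$n_cols), paste("nrows", s$n_rows),
    paste("xllcorner", s$origin_x),
    paste("yllcorner", s$origin_y - s$n_rows * s$cell_size),
    paste("cellsize", s$cell_size),
    paste("NODATA_value", s$nodata)), con)
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  if (!is.null(grid$levels))
    jsonlite::write_json(grid$levels, paste0(path, ".levels.json"))
  invisible(path)
}

#' @rdname write_grid_asc
#' @export
read_grid_asc <- function(path, kind = "continuous") {
  hdr <- readLines(path, n = 6)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  h <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  spec <- grid_spec(h[["nrows"]], h[["ncols"]], h[["cellsize"]],
                    origin_x = h[["xllcorner"]],
                    origin_y = h[["yllcorner"]] + h[["nrows"]] * h[["cellsize"]],
                    nodata = h[["nodata_value"]])
  v <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(v) <- NULL
  v[v == spec$nodata] <- NA
  lv <- NULL
  lp <- paste0(path, ".levels.json")
  if (file.exists(lp)) {
    lv <- unlist(jsonlite::read_json(lp))
    kind <- "categorical"
  }
  new_grid(v, spec, kind = kind, levels = lv)
}

#' Build a categorical grid from a character matrix
#'
#' @param labels Character matrix of class labels.
#' @param spec A [grid_spec()].
#' @param levels Optional explicit level ordering.
#' @return Categorical `tc_grid`.
#' @export
categorical_grid <- function(labels, spec, levels = NULL) {
  if (is.null(levels)) levels <- sort(unique(as.vector(labels)))
  codes <- matrix(match(as.vector(labels), levels), nrow(labels), ncol(labels))
  if (anyNA(codes) && !anyNA(labels)) stop("labels outside supplied levels")
  new_grid(codes, spec, kind = "categorical", levels = levels)
}

#' Class labels of a categorical grid
#' @param grid Categorical `tc_grid`.
#' @return Character matrix of labels (`NA` at nodata).
#' @export
grid_labels <- function(grid) {
  stopifnot(grid$kind == "categorical", !is.null(grid$levels))
  matrix(grid$levels[grid$values], nrow(grid$values), ncol(grid$values))
}
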