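#' Construct a vector layer
#'
#' Light-weight container for the vector inputs of the cost model: road and
#' railway polylines (with a `pcu` traffic attribute on roads), settlement
#' points (with `population`), stream polylines and water-body points or
#' polygons. Geometries are planar metre coordinate matrices; no CRS
#' mathematics is performed.
#'
#' @param geometry_type One of `"point"`, `"polyline"`, `"polygon"`.
#' @param features List of features, each a list with `geom` (an n x 2
#'   coordinate matrix; a single row for points) and `attrs` (named list).
#' @return Object of class `vector_layer`.
#' @examples
#' road <- vector_layer("polyline", list(
#'   list(geom = cbind(c(0, 5000), c(500, 500)), attrs = list(pcu = 8))))
#' @export
vector_layer <- function(geometry_type = c("point", "polyline", "polygon"),
                         features = list()) {
  geometry_type <- match.arg(geometry_type)
  features <- lapply(features, function(f) {
    g <- as.matrix(f$geom)
    if (ncol(g) != 2) stop("geometry must have two coordinate columns")
    if (geometry_type == "polyline" && nrow(g) < 2)
      stop("polylines need at least 2 vertices")
    if (geometry_type == "polygon" && nrow(g) < 3)
      stop("polygons need at least 3 vertices")
    list(geom = unname(g), attrs = as.list(f$attrs))
  })
  structure(list(geometry_type = geometry_type, features = features),
            class = "vector_layer")
}

#' @export
print.vector_layer <- function(x, ...) {
  cat(sprintf("<vector_layer:%s> %d feature(s)\n",
              x$geometry_type, length(x$features)))
  invisible(x)
}

n_features <- function(layer) length(layer$features)

feature_attr <- function(layer, name, default = NULL) {
  vapply(layer$features, function(f) {
    v <- f$attrs[[name]]
    if (is.null(v)) {
      if (is.null(default)) stop("feature lacks required attribute '", name, "'")
      default
    } else as.numeric(v)
  }, numeric(1))
}

#' Read and write vector layers as GeoJSON
#'
#' Point, LineString and Polygon features with their properties. Written
#' files are plain-text GeoJSON FeatureCollections; coordinates are the
#' package's planar metres.
#'
#' @param layer A [vector_layer()].
#' @param path Output / input file path.
#' @return `read_geojson` returns a `vector_layer`; `write_geojson` returns
#'   `path` invisibly.
#' @export
write_geojson <- function(layer, path) {
  gtype <- switch(layer$geometry_type, point = "Point",
                  polyline = "LineString", polygon = "Polygon")
  feats <- lapply(layer$features, function(f) {
    coords <- if (gtype == "Point") as.numeric(f$geom[1, ])
              else if (gtype == "Polygon") list(apply(f$geom, 1, as.numeric, simplify = FALSE))
              else apply(f$geom, 1, as.numeric, simplify = FALSE)
    list(type = "Feature",
         geometry = list(type = gtype, coordinates = coords),
         properties = if (length(f$attrs)) f$attrs else NULL)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_geojson
#' @export
read_geojson <- function(path) {
  j <- jsonlite::read_json(path)
  if (!length(j$features)) stop("empty FeatureCollection")
  gtype <- j$features[[1]]$geometry$type
  layer_type <- switch(gtype, Point = "point", LineString = "polyline",
                       Polygon = "polygon",
                       stop("unsupported geometry type ", gtype))
  feats <- lapply(j$features, function(f) {
    cc <- f$geometry$coordinates
    geom <- switch(gtype,
      Point = matrix(as.numeric(unlist(cc)), 1, 2),
      LineString = do.call(rbind, lapply(cc, function(p) as.numeric(unlist(p)))),
      Polygon = do.call(rbind, lapply(cc[[1]], function(p) as.numeric(unlist(p)))))
    list(geom = geom, attrs = f$properties)
  })
  vector_layer(layer_type, feats)
}
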