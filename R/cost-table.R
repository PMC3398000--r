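#' Cost tables: ordered category or interval lookups
#'
#' A cost table maps either categorical class labels or half-open numeric
#' intervals `[lo, hi)` to integer cost ranks. Intervals are sorted and
#' non-overlapping; the last interval is closed above (use `hi = Inf` for
#' an open-ended top bin). An interval with `lo == hi` is an exact-value
#' match checked before the intervals — used for "absent" categories where
#' exactly zero density carries its own rank. Values falling on an interior
#' boundary belong to the bin whose `lo` they equal.
#'
#' @param name Label for error messages and reports.
#' @param entries For `type = "categorical"`: a named numeric vector of
#'   costs. For `type = "interval"`: a data.frame with columns `lo`, `hi`,
#'   `cost`.
#' @param type Match type.
#' @param default Cost applied to unmatched values; if `NULL` an unmatched
#'   value is an error naming the value and cell.
#' @return Object of class `cost_table`.
#' @examples
#' habitat_cost_table()
#' reclass_value(water_cost_table(), c(500, 7500))
#' @export
cost_table <- function(name, entries, type = c("categorical", "interval"),
                       default = NULL) {
  type <- match.arg(type)
  if (type == "categorical") {
    stopifnot(is.numeric(entries), !is.null(names(entries)))
    if (any(entries < 0)) stop("costs must be >= 0")
  } else {
    entries <- as.data.frame(entries)
    stopifnot(all(c("lo", "hi", "cost") %in% names(entries)))
    if (any(entries$cost < 0)) stop("costs must be >= 0")
    iv <- entries[entries$lo < entries$hi, , drop = FALSE]
    iv <- iv[order(iv$lo), , drop = FALSE]
    if (nrow(iv) > 1 && any(iv$hi[-nrow(iv)] > iv$lo[-1] + 1e-12))
      stop("intervals overlap")
  }
  structure(list(name = name, type = type, entries = entries, default = default),
            class = "cost_table")
}

#' @export
print.cost_table <- function(x, ...) {
  cat(sprintf("<cost_table:%s> (%s)\n", x$name, x$type))
  print(x$entries)
  invisible(x)
}

#' Look up cost ranks for raw values
#'
#' Vectorised lookup through a [cost_table()]; the workhorse behind
#' [reclassify()].
#'
#' @param table A `cost_table`.
#' @param values Character vector (categorical tables) or numeric vector
#'   (interval tables). `NA` propagates.
#' @param where Optional labels used in the unmatched-value error message.
#' @return Numeric vector of cost ranks.
#' @export
reclass_value <- function(table, values, where = NULL) {
  out <- rep(NA_real_, length(values))
  ok <- !is.na(values)
  if (table$type == "categorical") {
    idx <- match(values[ok], names(table$entries))
    out[ok] <- table$entries[idx]
  } else {
    e <- table$entries
    exact <- e[e$lo == e$hi, , drop = FALSE]
    iv <- e[e$lo < e$hi, , drop = FALSE]
    iv <- iv[order(iv$lo), , drop = FALSE]
    v <- as.numeric(values[ok])
    res <- rep(NA_real_, length(v))
    for (i in seq_len(nrow(exact)))
      res[v == exact$lo[i]] <- exact$cost[i]
    if (nrow(iv)) {
      unset <- is.na(res)
      bin <- findInterval(v[unset], iv$lo)
      hit <- bin >= 1 & ifelse(bin == nrow(iv),
                               v[unset] <= iv$hi[bin] | is.infinite(iv$hi[bin]),
                               v[unset] < iv$hi[pmax(bin, 1)])
      res[unset][hit] <- iv$cost[bin[hit]]
    }
    out[ok] <- res
  }
  miss <- ok & is.na(out)
  if (any(miss)) {
    if (!is.null(table$default)) out[miss] <- table$default
    else {
      lab <- if (is.null(where)) which(miss)[1] else where[miss][1]
      stop(sprintf("cost table '%s': unmatched value '%s' at %s",
                   table$name, values[miss][1], lab))
    }
  }
  out
}

#' Reclassify a grid through a cost table
#'
#' Applies a [cost_table()] cellwise: categorical grids match class labels,
#' continuous grids match numeric intervals. Nodata propagates; an
#' unmatched value with no table default is an error naming the value and
#' the cell.
#'
#' @param grid A `tc_grid` whose kind matches the table's match type.
#' @param table A `cost_table`.
#' @return A cost-kind `tc_grid`.
#' @export
reclassify <- function(grid, table) {
  if (table$type == "categorical") {
    if (grid$kind != "categorical")
      stop("categorical cost table applied to ", grid$kind, " grid")
    vals <- as.vector(grid_labels(grid))
  } else {
    if (grid$kind == "categorical")
      stop("interval cost table applied to categorical grid")
    vals <- as.vector(grid$values)
  }
  rc <- arrayInd(seq_along(vals), dim(grid$values))
  where <- sprintf("cell (%d, %d)", rc[, 1], rc[, 2])
  out <- reclass_value(table, vals, where = where)
  new_grid(matrix(out, nrow(grid$values), ncol(grid$values)),
           grid$spec, kind = "cost")
}

# ---- the model's built-in tables ---------------------------------------

#' Built-in cost tables of the corridor movement model
#'
#' The ranked cost tables parameterising the six movement-cost layers:
#' habitat type (prey-ranked cover classes), distance to perennial water
#' (1-km bins, cells on water ranked 10 as movement barriers), PCU-weighted
#' road density, railway presence, settlement population density, and
#' per-hexagon Total Edge. Density and edge values falling beyond the
#' observed top bin clamp to the highest-cost category.
#'
#' @return A `cost_table`.
#' @export
habitat_cost_table <- function() {
  cost_table("habitat", c(
    "Teak" = 4, "Miscellaneous" = 3, "Teak Mixed" = 2,
    "Bamboo Mixed" = 1, "Mixed Bamboo" = 2, "Non-Forest" = 10),
    type = "categorical")
}

#' @rdname habitat_cost_table
#' @export
water_cost_table <- function() {
  cost_table("water_distance", data.frame(
    lo = c(0:6 * 1000, 7000), hi = c(1:7 * 1000, Inf), cost = c(0:6, 7)),
    type = "interval")
}

#' @rdname habitat_cost_table
#' @export
road_cost_table <- function() {
  # densities in pcu/m; exact 0 = absent; boundaries take the higher bin
  cost_table("road_density", data.frame(
    lo = c(0, 0, 4, 6), hi = c(0, 4, 6, Inf), cost = c(0, 2, 5, 10)),
    type = "interval")
}

#' @rdname habitat_cost_table
#' @export
settlement_cost_table <- function() {
  cost_table("settlement_density", data.frame(
    lo = c(0, 0, 0.001, 0.0015), hi = c(0, 0.001, 0.0015, Inf),
    cost = c(0, 3, 6, 10)),
    type = "interval")
}

#' @rdname habitat_cost_table
#' @export
rail_cost_table <- function() {
  cost_table("railway", data.frame(
    lo = c(0, 1), hi = c(0, 1), cost = c(0, 10)),
    type = "interval")
}

#' @rdname habitat_cost_table
#' @export
te_cost_table <- function() {
  # total edge in metres per hexagon; edge below the first published bound
  # shares the lowest bin
  cost_table("total_edge", data.frame(
    lo = c(0, 27000, 35000, 59000, 77000),
    hi = c(27000, 35000, 59000, 77000, Inf),
    cost = c(0, 4, 6, 8, 10)),
    type = "interval")
}
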