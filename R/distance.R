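#' Euclidean distance transform
#'
#' Exact centre-to-centre Euclidean distance (metres) from every cell to
#' the nearest source cell, computed with the two-pass separable
#' lower-envelope (parabola) algorithm on squared distances: a vertical
#' scan per column followed by a one-dimensional squared-distance
#' transform along each row. Exact — matches the brute-force minimum over
#' all source cells.
#'
#' @param sources A binary `tc_grid` (1 = source) or logical/numeric
#'   matrix.
#' @param spec Grid geometry; defaults to the source grid's spec.
#' @return Continuous `tc_grid` of distances in metres; 0 at source cells.
#' @export
euclidean_distance <- function(sources, spec = NULL) {
  if (inherits(sources, "tc_grid")) {
    if (is.null(spec)) spec <- sources$spec
    m <- sources$values
  } else m <- sources
  if (is.null(spec)) stop("spec required when sources is a bare matrix")
  src <- !is.na(m) & m == 1
  if (!any(src)) stop("euclidean_distance: no source cells")
  nr <- nrow(src); nc <- ncol(src)
  INF <- 1e15

  # vertical pass: per column, distance (in cells) to nearest source row
  d <- matrix(INF, nr, nc)
  d[src] <- 0
  if (nr > 1) {
    for (i in 2:nr) d[i, ] <- pmin(d[i, ], d[i - 1, ] + 1)
    for (i in (nr - 1):1) d[i, ] <- pmin(d[i, ], d[i + 1, ] + 1)
  }
  d2 <- d * d

  # horizontal pass: 1-D squared distance transform of each row
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) out[i, ] <- dt1d(d2[i, ])
  new_grid(sqrt(out) * spec$cell_size, spec, kind = "continuous")
}

# Felzenszwalb-Huttenlocher 1-D squared distance transform under a
# quadratic metric: out[q] = min_p ((q-p)^2 + f[p])
dt1d <- function(f) {
  n <- length(f)
  if (n == 1) return(f)
  v <- integer(n); z <- numeric(n + 1)
  k <- 1L
  v[1] <- 1L; z[1] <- -Inf; z[2] <- Inf
  for (q in 2:n) {
    repeat {
      s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
      if (s <= z[k]) { k <- k - 1L } else break
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- s
    z[k + 1] <- Inf
  }
  k <- 1L
  out <- numeric(n)
  for (q in seq_len(n)) {
    while (z[k + 1] < q) k <- k + 1L
    out[q] <- (q - v[k])^2 + f[v[k]]
  }
  out
}

#' Brute-force Euclidean distance (reference oracle)
#'
#' Direct minimum over all source cells; quadratic in grid size and meant
#' only for verifying [euclidean_distance()] on small grids.
#'
#' @inheritParams euclidean_distance
#' @return Continuous `tc_grid` of distances in metres.
#' @export
euclidean_distance_bruteforce <- function(sources, spec = NULL) {
  if (inherits(sources, "tc_grid")) {
    if (is.null(spec)) spec <- sources$spec
    m <- sources$values
  } else m <- sources
  src <- which(!is.na(m) & m == 1, arr.ind = TRUE)
  if (!nrow(src)) stop("no source cells")
  nr <- nrow(m); nc <- ncol(m)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  best <- matrix(Inf, nr, nc)
  for (i in seq_len(nrow(src)))
    best <- pmin(best, (rows - src[i, 1])^2 + (cols - src[i, 2])^2)
  new_grid(sqrt(best) * spec$cell_size, spec, kind = "continuous")
}
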