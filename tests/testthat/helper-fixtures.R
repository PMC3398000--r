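# shared fixtures and independent oracles

uniform_grid <- function(value, n_rows, n_cols, cell_size = 100,
                         kind = "continuous") {
  new_grid(matrix(value, n_rows, n_cols),
           grid_spec(n_rows, n_cols, cell_size), kind = kind)
}

# independent accumulated-cost oracle: explicit 8-neighbour graph + igraph
igraph_accumulate <- function(cm, source) {
  n_r <- nrow(cm$values); n_c <- ncol(cm$values)
  v <- cm$values
  idx <- function(r, c) (c - 1L) * n_r + r
  dirs <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (r in seq_len(n_r)) for (c in seq_len(n_c)) for (d in dirs) {
    r2 <- r + d[1]; c2 <- c + d[2]
    if (r2 < 1 || r2 > n_r || c2 < 1 || c2 > n_c) next
    from <- c(from, idx(r, c)); to <- c(to, idx(r2, c2))
    w <- c(w, (v[r, c] + v[r2, c2]) / 2 * if (all(d != 0)) sqrt(2) else 1)
  }
  g <- igraph::make_graph(rbind(from, to), n = n_r * n_c, directed = TRUE)
  d <- igraph::distances(g, v = idx(source[1], source[2]), weights = w,
                         mode = "out")
  matrix(as.numeric(d), n_r, n_c)
}

# independent density oracle: dense sampling of each segment
sampled_line_density <- function(lines, centre, radius, weight_attr,
                                 step = 0.25) {
  total <- 0
  for (f in lines$features) {
    w <- as.numeric(f$attrs[[weight_attr]])
    g <- f$geom
    for (i in seq_len(nrow(g) - 1)) {
      L <- sqrt(sum((g[i + 1, ] - g[i, ])^2))
      if (L == 0) next
      ts <- seq(0, 1, by = step / L)
      px <- g[i, 1] + ts * (g[i + 1, 1] - g[i, 1])
      py <- g[i, 2] + ts * (g[i + 1, 2] - g[i, 2])
      inside <- (px - centre[1])^2 + (py - centre[2])^2 <= radius^2
      total <- total + mean(inside) * L * w
    }
  }
  total / (pi * radius^2)
}

# a hand-built straight corridor path along one grid row
straight_path <- function(row, cols, spec) {
  structure(list(cells = cbind(row = rep(row, length(cols)), col = cols),
                 length_km = (length(cols) - 1) * spec$cell_size / 1000,
                 total_cost = 0, spec = spec),
            class = "corridor_path")
}
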