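test_that("accumulated cost matches closed forms", {
  cm <- uniform_grid(2, 10, 10)
  ac <- accumulate_cost(cm, c(1, 1))
  expect_equal(ac$acc$values[1, 6], 10) # five orthogonal steps of mean cost 2
  expect_equal(ac$acc$values[1, 1], 0)
  expect_equal(ac$acc$values[2, 2], 2 * sqrt(2))

  zero <- uniform_grid(0, 8, 8)
  expect_true(all(accumulate_cost(zero, c(4, 4))$acc$values == 0))

  expect_error(accumulate_cost(uniform_grid(-1, 3, 3), c(1, 1)),
               "non-negative")
  nag <- uniform_grid(1, 3, 3); nag$values[1, 1] <- NA
  expect_error(accumulate_cost(nag, c(1, 1)), "nodata")
})

test_that("accumulated cost equals explicit-graph Dijkstra on random grids", {
  set.seed(202)
  for (i in 1:15) {
    n_r <- sample(8:15, 1); n_c <- sample(8:15, 1)
    cm <- new_grid(matrix(runif(n_r * n_c, 0, 10), n_r, n_c),
                   grid_spec(n_r, n_c, 100))
    src <- c(sample(n_r, 1), sample(n_c, 1))
    mine <- accumulate_cost(cm, src)$acc$values
    oracle <- igraph_accumulate(cm, src)
    expect_equal(mine, oracle, tolerance = 1e-10)
  }
})

test_that("increasing a single cell cost never decreases accumulated cost", {
  set.seed(17)
  cm <- new_grid(matrix(runif(225, 0, 5), 15, 15), grid_spec(15, 15, 100))
  base <- accumulate_cost(cm, c(8, 8))$acc$values
  for (i in 1:10) {
    cm2 <- cm
    r <- sample(15, 1); c <- sample(15, 1)
    cm2$values[r, c] <- cm2$values[r, c] + runif(1, 1, 10)
    up <- accumulate_cost(cm2, c(8, 8))$acc$values
    expect_true(all(up >= base - 1e-12))
    cm3 <- cm
    cm3$values[r, c] <- cm3$values[r, c] * 0.2
    down <- accumulate_cost(cm3, c(8, 8))$acc$values
    expect_true(all(down <= base + 1e-12))
  }
})

test_that("traced paths follow backlinks and re-sum to the accumulated cost", {
  ac <- accumulate_cost(uniform_grid(2, 10, 10), c(5, 5))
  single <- trace_path(ac, c(5, 5))
  expect_equal(nrow(single$cells), 1)
  expect_equal(single$length_km, 0)
  expect_equal(single$total_cost, 0)

  straight <- trace_path(ac, c(5, 10))
  expect_equal(straight$length_km, 0.5)

  # path-cost re-summation on random instances
  set.seed(33)
  for (i in 1:10) {
    cm <- new_grid(matrix(runif(144, 0.1, 8), 12, 12), grid_spec(12, 12, 100))
    ac <- accumulate_cost(cm, c(12, 12))
    start <- c(sample(12, 1), sample(12, 1))
    p <- trace_path(ac, start)
    resum <- 0
    if (nrow(p$cells) > 1) {
      for (j in seq_len(nrow(p$cells) - 1)) {
        a <- p$cells[j, ]; b <- p$cells[j + 1, ]
        fac <- if (all(abs(a - b) == 1)) sqrt(2) else 1
        resum <- resum + (cm$values[a[1], a[2]] + cm$values[b[1], b[2]]) / 2 * fac
      }
    }
    expect_equal(resum, p$total_cost, tolerance = 1e-10)
    expect_true(all(abs(diff(p$cells)) <= 1)) # 8-neighbour steps only
  }
})

test_that("routes are invariant under positive scaling of the cost surface", {
  set.seed(55)
  for (i in 1:8) {
    cm <- new_grid(matrix(sample(0:10, 400, TRUE), 20, 20),
                   grid_spec(20, 20, 100))
    src <- c(20, 20); start <- c(1, 1)
    p1 <- trace_path(accumulate_cost(cm, src), start)
    for (k in c(2, 0.25)) {
      cmk <- new_grid(k * cm$values, cm$spec)
      pk <- trace_path(accumulate_cost(cmk, src), start)
      expect_identical(pk$cells, p1$cells)
      expect_equal(pk$total_cost, k * p1$total_cost, tolerance = 1e-12)
    }
  }
})

test_that("shared segment decomposition preserves path lengths", {
  spec <- grid_spec(20, 20, 100)
  cm <- uniform_grid(1, 20, 20)
  ac <- accumulate_cost(cm, c(10, 20))
  p1 <- trace_path(ac, c(10, 1))
  segs_same <- shared_segments(list(p1, p1))
  expect_equal(nrow(segs_same), 1)
  expect_equal(segs_same$type, "common")
  expect_equal(segs_same$length_km, p1$length_km)

  # three starts that merge towards one destination
  p2 <- trace_path(ac, c(1, 1))
  p3 <- trace_path(ac, c(20, 1))
  segs <- shared_segments(list(p1, p2, p3))
  expect_true(any(segs$type == "common"))
  for (i in 1:3) {
    mine <- segs[grepl(paste0("(^|/)", i, "(/|$)"), segs$path_ids), ]
    expect_equal(sum(mine$length_km), list(p1, p2, p3)[[i]]$length_km,
                 tolerance = 1e-9)
  }
})

test_that("disjoint paths share only the source cell", {
  spec <- grid_spec(5, 5, 100)
  pa <- structure(list(cells = cbind(row = c(1, 2, 3), col = c(1, 2, 3)),
                       length_km = 2 * sqrt(2) * 0.1, total_cost = 0,
                       spec = spec), class = "corridor_path")
  pb <- structure(list(cells = cbind(row = c(5, 4, 3), col = c(1, 2, 3)),
                       length_km = 2 * sqrt(2) * 0.1, total_cost = 0,
                       spec = spec), class = "corridor_path")
  segs <- shared_segments(list(pa, pb))
  common <- segs[segs$type == "common", ]
  expect_equal(nrow(common), 1)
  expect_equal(common$n_cells, 1)
  expect_equal(common$length_km, 0)
})

test_that("weak links flag narrow forest necks and honour the threshold", {
  spec <- grid_spec(60, 100, 100)
  path <- straight_path(30, 1:100, spec)

  forest_all <- uniform_grid(1, 60, 100)
  expect_equal(nrow(weak_links(path, forest_all, 4)), 0)

  # a 4 km neck: forest rows 11..50 only within columns 40..60
  f <- matrix(1, 60, 100)
  f[c(1:10, 51:60), 40:60] <- 0
  forest <- new_grid(f, spec)
  wl <- weak_links(path, forest, width_threshold_km = 5)
  expect_equal(nrow(wl), 1)
  expect_equal(wl$min_width_km, 4, tolerance = 0.1)
  expect_equal(wl$cause, "constriction")

  # threshold zero flags nothing anywhere
  expect_equal(nrow(weak_links(path, forest, 0)), 0)
})

test_that("weak links are classed fragmentation under severe edge cost", {
  spec <- grid_spec(20, 40, 100)
  path <- straight_path(10, 1:40, spec)
  f <- matrix(1, 20, 40); f[c(1:7, 14:20), 15:25] <- 0
  ec <- uniform_grid(8, 20, 40, kind = "cost")
  wl <- weak_links(path, new_grid(f, spec), 4, edge_cost = ec)
  expect_true(nrow(wl) >= 1)
  expect_true(all(wl$cause == "fragmentation"))
})

test_that("corridor buffer approximates the rectangle-plus-caps area", {
  spec <- grid_spec(100, 160, 100)
  path <- straight_path(50, 31:130, spec) # 9.9 km of steps
  buf <- buffer_corridor(path, 2, 2)
  L <- path$length_km
  analytic <- 2 * 2 * L + pi * 2^2
  expect_equal(buf$area_km2, analytic, tolerance = 0.05)
  expect_true(all(buf$mask$values[path$cells] == 1))
  expect_true(all(buf$radius_km == 2))
  expect_error(buffer_corridor(path, 0, 2), "min_km")
})

test_that("buffer narrows inside weak links with a linear taper", {
  spec <- grid_spec(100, 160, 100)
  path <- straight_path(50, 31:130, spec)
  weak <- data.frame(link_id = 1, start_index = 45, end_index = 55,
                     length_km = 1, min_width_km = 1, cause = "constriction")
  buf <- buffer_corridor(path, 2, 6, weak = weak)
  expect_equal(buf$radius_km[50], 2)
  expect_equal(buf$radius_km[1], 6) # far from the weak span
  expect_equal(buf$radius_km[60], 2 + sum(path_lengths <- rep(0.1, 5)) * 1,
               tolerance = 1e-9) # 0.5 km past the span -> 2.5 km radius
  expect_true(all(diff(buf$radius_km[45:80]) >= -1e-9))
})

test_that("water gaps group dry spans and place covering waterholes", {
  spec <- grid_spec(20, 300, 100)
  path <- straight_path(10, 1:300, spec) # ~30 km path
  # water only at the two ends
  src <- matrix(0, 20, 300); src[10, 1] <- 1; src[10, 300] <- 1
  wd <- euclidean_distance(new_grid(src, spec), spec)

  res <- water_gaps(path, wd, max_km = 5)
  expect_equal(nrow(res$gaps), 1)
  expect_equal(res$gaps$length_km, 29.9 - 2 * 5, tolerance = 0.11)
  expect_gte(nrow(res$waterholes), 1)
  # post-placement: every path cell within 5 km of water or a waterhole
  cover <- res$dist_km
  for (k in seq_len(nrow(res$waterholes)))
    cover <- pmin(cover, sqrt((path$cells[, 1] - res$waterholes[k, 1])^2 +
                              (path$cells[, 2] - res$waterholes[k, 2])^2) * 0.1)
  expect_true(all(cover <= 5))

  # everything within reach -> no gaps; infinite allowance -> no gaps
  near <- water_gaps(path, wd, max_km = 20)
  expect_equal(nrow(near$gaps), 0)
  expect_equal(nrow(water_gaps(path, wd, max_km = Inf)$gaps), 0)
})
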