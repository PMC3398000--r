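test_that("rasterize marks exactly the traversed cells", {
  spec <- grid_spec(10, 10, 100)
  # horizontal line through the middle of row 5, crossing columns 2..6
  line <- vector_layer("polyline", list(
    list(geom = rbind(c(150, 550), c(590, 550)), attrs = list())))
  g <- rasterize(line, spec, "presence")
  expect_equal(sum(g$values), 5)
  expect_equal(unique(g$values[5, 2:6]), 1)

  # diagonal segment: every cell containing part of the segment
  diagline <- vector_layer("polyline", list(
    list(geom = rbind(c(50, 950), c(950, 50)), attrs = list())))
  gd <- rasterize(diagline, spec, "presence")
  # the main-diagonal cells must all be marked
  expect_true(all(gd$values[cbind(1:10, 1:10)] == 1))
})

test_that("rasterize handles empty layers and attribute mode", {
  spec <- grid_spec(8, 8, 100)
  expect_warning(g <- rasterize(vector_layer("point"), spec, "presence"),
                 "empty")
  expect_true(all(g$values == 0))

  pt <- vector_layer("point", list(
    list(geom = matrix(c(250, 350), 1, 2), attrs = list(population = 200))))
  ga <- rasterize(pt, spec, "attribute", attr = "population")
  expect_equal(ga$values[xy_to_cell(250, 350, spec)], 200)
  expect_equal(sum(!is.na(ga$values)), 1)
  expect_error(rasterize(pt, spec, "attribute", attr = "pcu"), "pcu")
})

test_that("polygon rasterization burns cells whose centre is inside", {
  spec <- grid_spec(10, 10, 100)
  sq <- vector_layer("polygon", list(
    list(geom = rbind(c(200, 200), c(600, 200), c(600, 600), c(200, 600)),
         attrs = list())))
  g <- rasterize(sq, spec, "presence")
  expect_equal(sum(g$values), 16) # 4 x 4 cell centres inside
})

test_that("reclassify applies the habitat table and flags unknown labels", {
  spec <- grid_spec(2, 3, 100)
  lab <- matrix(c("Teak", "Non-Forest", "Bamboo Mixed",
                  "Teak", "Mixed Bamboo", "Miscellaneous"), 2, 3)
  g <- reclassify(categorical_grid(lab, spec), habitat_cost_table())
  expect_equal(g$kind, "cost")
  expect_equal(g$values[1, 1], 4)
  expect_equal(g$values[2, 1], 10)
  expect_equal(g$values[1, 2], 1)

  bad <- categorical_grid(matrix("Sal", 2, 3), spec)
  expect_error(reclassify(bad, habitat_cost_table()), "Sal")
})

test_that("reclassify propagates nodata and is idempotent on identity tables", {
  spec <- grid_spec(3, 3, 100)
  # identity on already-classified cost ranks
  ranks <- new_grid(matrix(c(0, 4, 10, 0, NA, 4, 10, 0, 4), 3, 3),
                    spec, kind = "cost")
  self_map <- cost_table("self", c("0" = 0, "4" = 4, "10" = 10),
                         type = "categorical")
  relabeled <- categorical_grid(matrix(as.character(ranks$values), 3, 3),
                                spec, levels = c("0", "4", "10"))
  out <- reclassify(relabeled, self_map)
  expect_equal(out$values, ranks$values)
})

test_that("euclidean distance matches collinear and 3-4-5 closed forms", {
  spec <- grid_spec(10, 10, 100)
  src <- matrix(0, 10, 10); src[1, 1] <- 1
  d <- euclidean_distance(new_grid(src, spec), spec)
  expect_equal(d$values[1, 4], 300)
  expect_equal(d$values[4, 5], 500) # 3-4-5 triangle
  expect_equal(d$values[1, 1], 0)
  expect_error(euclidean_distance(new_grid(matrix(0, 10, 10), spec), spec),
               "no source")
})

test_that("euclidean distance equals the brute-force oracle on random masks", {
  set.seed(101)
  for (i in 1:20) {
    n_r <- sample(5:30, 1); n_c <- sample(5:30, 1)
    spec <- grid_spec(n_r, n_c, sample(c(50, 100), 1))
    m <- matrix(rbinom(n_r * n_c, 1, 0.08), n_r, n_c)
    if (!any(m == 1)) m[sample(n_r, 1), sample(n_c, 1)] <- 1
    fast <- euclidean_distance(new_grid(m, spec), spec)
    slow <- euclidean_distance_bruteforce(new_grid(m, spec), spec)
    expect_equal(fast$values, slow$values, tolerance = 1e-12)
  }
})

test_that("line density matches the chord closed form and is linear in weight", {
  spec <- grid_spec(21, 21, 100)
  # line through the centre cell's centre (1050, 1050)
  line <- function(w) vector_layer("polyline", list(
    list(geom = rbind(c(-2000, 1050), c(5000, 1050)), attrs = list(pcu = w))))
  r <- 800
  d1 <- line_density(line(1), spec, r, "pcu")
  expect_equal(d1$values[11, 11], 2 * r / (pi * r^2), tolerance = 1e-12)
  d3 <- line_density(line(3), spec, r, "pcu")
  expect_equal(d3$values, 3 * d1$values, tolerance = 1e-12)
  # far from any line: zero
  expect_equal(d1$values[1, 1], 0)
  expect_error(line_density(line(1), spec, -5, "pcu"), "radius")
})

test_that("line density agrees with a segment-sampling oracle at probe cells", {
  set.seed(7)
  spec <- grid_spec(20, 20, 100)
  feats <- lapply(1:4, function(i)
    list(geom = cbind(runif(3, 0, 2000), runif(3, 0, 2000)),
         attrs = list(pcu = sample(1:8, 1))))
  net <- vector_layer("polyline", feats)
  dens <- line_density(net, spec, 600, "pcu")
  cc <- cell_centres(spec)
  probes <- cbind(sample(20, 25, TRUE), sample(20, 25, TRUE))
  for (k in seq_len(nrow(probes))) {
    ctr <- c(cc$x[probes[k, 2]], cc$y[probes[k, 1]])
    expected <- sampled_line_density(net, ctr, 600, "pcu")
    expect_equal(dens$values[probes[k, 1], probes[k, 2]], expected,
                 tolerance = 0.02)
  }
})

test_that("point density matches the closed form and a neighbour-sum oracle", {
  spec <- grid_spec(20, 20, 100)
  cc <- cell_centres(spec)
  pt <- vector_layer("point", list(
    list(geom = matrix(c(cc$x[10], cc$y[10]), 1, 2),
         attrs = list(population = 1000))))
  d <- point_density(pt, spec, 1000, "population")
  expect_equal(d$values[10, 10], 1000 / (pi * 1e6), tolerance = 1e-12)
  expect_equal(d$values[1, 20], 0)

  set.seed(11)
  pts <- vector_layer("point", lapply(1:30, function(i)
    list(geom = matrix(runif(2, 0, 2000), 1, 2),
         attrs = list(population = sample(50:500, 1)))))
  dd <- point_density(pts, spec, 700, "population")
  probes <- cbind(sample(20, 25, TRUE), sample(20, 25, TRUE))
  xy <- do.call(rbind, lapply(pts$features, function(f) f$geom))
  w <- sapply(pts$features, function(f) f$attrs$population)
  for (k in seq_len(nrow(probes))) {
    ctr <- c(cc$x[probes[k, 2]], cc$y[probes[k, 1]])
    expected <- sum(w[(xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2 <= 700^2]) /
      (pi * 700^2)
    expect_equal(dd$values[probes[k, 1], probes[k, 2]], expected,
                 tolerance = 1e-12)
  }
  # linearity in weights
  pts2 <- vector_layer("point", lapply(pts$features, function(f) {
    f$attrs$population <- 2 * f$attrs$population; f
  }))
  expect_equal(point_density(pts2, spec, 700, "population")$values,
               2 * dd$values, tolerance = 1e-12)
})

test_that("ascii grid and geojson round-trips preserve data", {
  spec <- grid_spec(6, 8, 100, origin_x = 500, origin_y = 1100)
  v <- matrix(rnorm(48), 6, 8); v[3, 3] <- NA
  g <- new_grid(v, spec)
  f <- tempfile(fileext = ".asc")
  write_grid_asc(g, f)
  g2 <- read_grid_asc(f)
  expect_equal(g2$values, g$values, tolerance = 1e-9)
  expect_equal(g2$spec$origin_x, 500)

  lab <- categorical_grid(matrix(c("Teak", "Non-Forest"), 6, 8), spec)
  f2 <- tempfile(fileext = ".asc")
  write_grid_asc(lab, f2)
  lab2 <- read_grid_asc(f2)
  expect_equal(grid_labels(lab2), grid_labels(lab))

  roads <- vector_layer("polyline", list(
    list(geom = rbind(c(0, 0), c(100, 250)), attrs = list(pcu = 5))))
  fj <- tempfile(fileext = ".geojson")
  write_geojson(roads, fj)
  roads2 <- read_geojson(fj)
  expect_equal(roads2$features[[1]]$geom, roads$features[[1]]$geom)
  expect_equal(roads2$features[[1]]$attrs$pcu, 5)
})
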