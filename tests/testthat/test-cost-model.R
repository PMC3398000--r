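test_that("habitat cost layer carries the published ranks", {
  spec <- grid_spec(2, 3, 100)
  lab <- matrix(c("Bamboo Mixed", "Mixed Bamboo", "Teak",
                  "Teak Mixed", "Miscellaneous", "Non-Forest"), 2, 3)
  g <- build_habitat_cost(categorical_grid(lab, spec))
  expect_equal(as.vector(g$values), c(1, 2, 4, 2, 3, 10))
  allnf <- build_habitat_cost(categorical_grid(matrix("Non-Forest", 2, 3), spec))
  expect_true(all(allnf$values == 10))
})

test_that("water cost bins distance and ranks open water as a barrier", {
  spec <- grid_spec(5, 100, 100) # 10 km long strip
  tank <- vector_layer("point", list(
    list(geom = matrix(c(50, 250), 1, 2), attrs = list())))
  g <- build_water_cost(NULL, tank, spec)
  expect_equal(g$values[3, 1], 10)      # on the water body itself
  expect_equal(g$values[3, 6], 0)       # 0.5 km away
  expect_equal(g$values[3, 16], 1)      # 1.5 km
  expect_equal(g$values[3, 76], 7)      # 7.5 km -> top bin
  expect_s3_class(attr(g, "distance"), "tc_grid")
  expect_equal(attr(g, "distance")$values[3, 6], 500)
  expect_error(build_water_cost(NULL, vector_layer("point"), spec), "no water")
})

test_that("road cost categorizes PCU-weighted density", {
  expect_equal(reclass_value(road_cost_table(), c(8, 0, 2, 4.5, 0.05, 12)),
               c(10, 0, 2, 5, 2, 10))
  # boundary densities take the higher-cost bin
  expect_equal(reclass_value(road_cost_table(), c(4, 6)), c(5, 10))
  spec <- grid_spec(21, 21, 100)
  # a heavy road through the centre: expect High rank under the wheels
  road <- vector_layer("polyline", list(
    list(geom = rbind(c(-5000, 1050), c(8000, 1050)), attrs = list(pcu = 20000))))
  g <- build_road_cost(road, spec, radius = 1000)
  expect_equal(g$values[11, 11], 10)
  empty <- build_road_cost(vector_layer("polyline"), spec)
  expect_true(all(empty$values == 0))
})

test_that("rail cost is presence/absence", {
  spec <- grid_spec(10, 10, 100)
  rail <- vector_layer("polyline", list(
    list(geom = rbind(c(0, 450), c(1000, 450)), attrs = list())))
  g <- build_rail_cost(rail, spec)
  expect_equal(g$values[6, 3], 10)
  expect_equal(g$values[1, 1], 0)
  expect_true(all(build_rail_cost(NULL, spec)$values == 0))
})

test_that("settlement cost categorizes population density", {
  expect_equal(reclass_value(settlement_cost_table(),
                             c(0.0018, 0.0005, 0, 0.0012, 0.005)),
               c(10, 3, 0, 6, 10))
  spec <- grid_spec(21, 21, 100)
  cc <- cell_centres(spec)
  vill <- vector_layer("point", list(
    list(geom = matrix(c(cc$x[11], cc$y[11]), 1, 2),
         attrs = list(population = 5000))))
  g <- build_settlement_cost(vill, spec, radius = 1000)
  # 5000 / (pi * 1e6) ~ 0.00159 pop/m^2 -> High
  expect_equal(g$values[11, 11], 10)
  expect_equal(g$values[1, 1], 0)
})

test_that("expert rating averages reproduce the published panel summary", {
  avg <- average_expert_weights(expert_ratings())
  expect_equal(unname(avg), c(4, 3.4, 2.6, 1.2, 3, 0.8, 0.2))
  expect_equal(avg[["Food availability/Prey base"]], 3.4)
  expect_equal(avg[["Water availability"]], 2.6)
  expect_equal(unname(average_expert_weights(matrix(0, 3, 4))), c(0, 0, 0))
})

test_that("run options encode the three weighting schemes", {
  ro1 <- run_option("RO1")
  expect_true(all(ro1$weights == 1))
  ro2 <- run_option("RO2")
  expect_equal(ro2$weights[["TE"]], 5)
  expect_equal(ro2$weights[["H"]], 4)
  expect_equal(ro2$weights[["S"]], 3)
  expect_equal(ro2$weights[["WS"]], 2)
  expect_equal(ro2$weights[["RD"]], 1)
  expect_equal(ro2$weights[["R"]], 0)
  ro3 <- run_option("RO3")
  expect_equal(unname(ro3$weights[c("H", "TE", "WS")]), c(2, 2, 2))
  expect_equal(unname(ro3$weights[c("S", "RD", "R")]), c(1, 1, 1))
  expect_error(run_option("RO9"), "unknown")
  expect_error(weight_scheme("w", c(H = -1, S = 0, WS = 0, TE = 0,
                                    RD = 0, R = 0)))
})

test_that("composite cost is the cellwise weighted sum of the stack", {
  spec <- grid_spec(10, 10, 100)
  ones <- uniform_grid(1, 10, 10, kind = "cost")
  zeros <- uniform_grid(0, 10, 10, kind = "cost")
  stack1 <- cost_stack(ones, ones, ones, ones, ones, ones)
  cm1 <- composite_cost(stack1, run_option("RO1"))
  expect_true(all(cm1$values == 6))
  stack2 <- cost_stack(H = ones, S = zeros, WS = ones, TE = ones,
                       RD = zeros, R = zeros)
  expect_true(all(composite_cost(stack2, run_option("RO3"))$values == 6))

  set.seed(3)
  rand <- replicate(6, new_grid(matrix(sample(0:10, 100, TRUE), 10, 10),
                                spec, kind = "cost"), simplify = FALSE)
  st <- do.call(cost_stack, rand)
  for (sch in list(run_option("RO1"), run_option("RO2"), run_option("RO3"))) {
    cm <- composite_cost(st, sch)
    w <- sch$weights
    # independent per-cell dot product
    for (k in 1:25) {
      r <- sample(10, 1); c <- sample(10, 1)
      expected <- sum(w * vapply(st[names(w)], function(g) g$values[r, c],
                                 numeric(1)))
      expect_equal(cm$values[r, c], expected)
    }
    expect_true(all(cm$values >= 0))
  }
})

test_that("composite cost is linear in the weights and propagates nodata", {
  spec <- grid_spec(5, 5, 100)
  set.seed(4)
  layers <- replicate(6, new_grid(matrix(sample(0:10, 25, TRUE), 5, 5),
                                  spec, kind = "cost"), simplify = FALSE)
  layers[[3]]$values[2, 2] <- NA
  st <- do.call(cost_stack, layers)
  w <- c(H = 1, S = 2, WS = 1, TE = 3, RD = 1, R = 1)
  cm <- composite_cost(st, weight_scheme("w", w))
  cm2 <- composite_cost(st, weight_scheme("2w", 2 * w))
  expect_equal(cm2$values, 2 * cm$values)
  expect_true(is.na(cm$values[2, 2]))
  expect_error(cost_stack(layers[[1]], layers[[2]], layers[[3]], layers[[4]],
                          layers[[5]],
                          uniform_grid(1, 6, 6, kind = "cost")),
               "grid_spec")
})
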