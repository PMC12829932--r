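# a tiny scene wrapper around hand-built layers for criterion tests
mini_scene <- function(rasters = list(), vectors = list()) {
  if (!length(rasters))
    rasters$dem <- raster_create(matrix(0, 8, 8), 0, 2000, 250)
  structure(list(rasters = rasters, vectors = vectors,
                 extent = raster_extent(rasters[[1]])[c(1, 2, 3, 4)],
                 crs = "EPSG:32734"), class = "lucis_scene")
}

units_8 <- function() build_decision_units(c(0, 0, 2000, 2000))

test_that("inverted distance criterion hits the endpoint contract", {
  road <- features_create(list(list(type = "line",
    coords = cbind(c(0, 2000), c(1875, 1875)))))  # along the top unit row
  sc <- mini_scene(vectors = list(roads = road))
  spec <- criterion("road_access", "roads", "distance", 1, invert = TRUE)
  u <- evaluate_criterion(spec, sc, units_8())
  on_road <- u$y0 == 1750
  farthest <- u$y0 == 0
  expect_true(all(u$road_access[on_road] == 9))
  expect_equal(min(u$road_access[farthest]), 1)
  expect_true(all(u$road_access >= 1 & u$road_access <= 9))
})

test_that("the 300-m cattle-post buffer scores 1 inside and 9 outside", {
  posts <- features_create(list(list(type = "point",
                                     coords = cbind(1000, 1000))))
  sc <- mini_scene(vectors = list(cattle_posts = posts))
  spec <- criterion("livestock_buffer", "cattle_posts", "buffer_exclusion",
                    1, params = list(buffer_m = 300))
  u <- evaluate_criterion(spec, sc, units_8())
  ctr <- unit_centroids(u)
  d <- sqrt((ctr[, 1] - 1000)^2 + (ctr[, 2] - 1000)^2)
  expect_true(all(u$livestock_buffer[d <= 200] == 1))
  expect_true(all(u$livestock_buffer[d >= 500] == 9))
  expect_identical(sort(unique(u$livestock_buffer)), c(1, 9))
})

test_that("reclass criterion maps per-unit majority classes exactly", {
  # 4 units of 2x2 cells each; classes laid out per quadrant with one
  # dissenting cell per quadrant
  m <- matrix(c(1, 1, 2, 2,
                1, 3, 2, 2,
                3, 3, 1, 2,
                3, 3, 2, 2), 4, 4, byrow = TRUE)
  lulc <- raster_create(m, 0, 1000, 250, categorical = TRUE)
  sc <- mini_scene(rasters = list(dem = lulc, lulc = lulc))
  u <- build_decision_units(c(0, 0, 1000, 1000), fine_m = 500, coarse_m = 500)
  spec <- criterion("lu", "lulc", "reclass_table", 1,
                    params = list(table = c(`1` = 9, `2` = 5, `3` = 2)))
  u <- evaluate_criterion(spec, sc, u)
  # unit at (0,500)-(500,1000) holds rows 1:2, cols 1:2 -> classes 1,1,1,3
  expect_equal(u$lu[u$x0 == 0 & u$y0 == 500], 9)
  expect_equal(u$lu[u$x0 == 500 & u$y0 == 500], 5)
  expect_equal(u$lu[u$x0 == 0 & u$y0 == 0], 2)
  expect_equal(u$lu[u$x0 == 500 & u$y0 == 0], 5)
})

test_that("reclass rejects unmapped classes, naming them", {
  lulc <- raster_create(matrix(c(1, 2, 7, 7), 2, 2), 0, 500, 250,
                        categorical = TRUE)
  sc <- mini_scene(rasters = list(dem = lulc, lulc = lulc))
  u <- build_decision_units(c(0, 0, 500, 500), fine_m = 250, coarse_m = 250)
  spec <- criterion("lu", "lulc", "reclass_table", 1,
                    params = list(table = c(`1` = 9, `2` = 5)))
  expect_error(evaluate_criterion(spec, sc, u), "7")
})

test_that("missing layers are rejected by name", {
  sc <- mini_scene()
  u <- units_8()
  expect_error(evaluate_criterion(
    criterion("x", "nothere", "distance", 1), sc, u), "nothere")
  expect_error(evaluate_criterion(
    criterion("x", "nothere", "identity", 1), sc, u), "nothere")
})

test_that("hierarchy aggregation reproduces hand-computed composites", {
  u <- units_8()
  n <- nrow(u)
  u$road <- rep(9, n); u$dist_stl <- rep(5, n)
  econ <- hier_node("economic", "objective", 1, list(
    criterion("road", "roads", "distance", 0.5, invert = TRUE),
    criterion("dist_stl", "settlements", "distance", 0.5, invert = TRUE)))
  expect_equal(unique(lucisr:::node_composite(econ, u)), 7.0)

  # single child of weight 1 passes through
  solo <- hier_node("obj", "objective", 1, list(
    criterion("road", "roads", "distance", 1, invert = TRUE)))
  expect_equal(lucisr:::node_composite(solo, u), u$road)

  # crop 0.7 / livestock 0.3 goal split: 0.7*9 + 0.3*5 = 7.8
  u$crop <- rep(9, n); u$lvstk <- rep(5, n)
  goal <- hier_node("agriculture", "goal", 1, list(
    criterion("crop", "z", "identity", 0.7),
    criterion("lvstk", "z", "identity", 0.3)))
  expect_equal(unique(lucisr:::node_composite(goal, u)), 7.8)
})

test_that("goal suitability is invariant to sibling order", {
  sc <- small_scene(); u <- small_units()
  h <- default_hierarchies()
  a <- build_goal_suitability("agriculture", sc, u, h)
  h2 <- h
  h2$agriculture$children <- rev(h2$agriculture$children)
  h2$agriculture$children[[2]]$children <-
    rev(h2$agriculture$children[[2]]$children)
  b <- build_goal_suitability("agriculture", sc, u, h2)
  expect_equal(b$suit_agriculture, a$suit_agriculture, tolerance = 1e-12)
})

test_that("improving a benefit criterion never lowers goal suitability", {
  u <- units_8(); n <- nrow(u)
  set.seed(8)
  u$a <- runif(n, 1, 9); u$b <- runif(n, 1, 9); u$c <- runif(n, 1, 9)
  tree <- hier_node("g", "goal", 1, list(
    hier_node("o1", "objective", 0.6, list(
      criterion("a", "z", "identity", 0.5),
      criterion("b", "z", "identity", 0.5))),
    criterion("c", "z", "identity", 0.4)))
  base <- lucisr:::node_composite(tree, u)
  u2 <- u; u2$a[3] <- min(9, u2$a[3] + 2)
  up <- lucisr:::node_composite(tree, u2)
  expect_gte(up[3], base[3])
  expect_equal(up[-3], base[-3])
})

test_that("wildlife goal equals rescaled zonal means of a single layer", {
  sc <- small_scene(); u <- small_units()
  h <- default_hierarchies()
  h$wildlife$species <- "lion"
  got <- build_goal_suitability("wildlife", sc, u, h)
  z <- zonal_aggregate(sc$rasters$habitat_lion, u, "mean", name = "z")$z
  expect_equal(got$suit_wildlife, rescale_linear_1_9(z), tolerance = 1e-12)

  # identical layers: mean combination equals either layer
  sc2 <- sc
  sc2$rasters$habitat_leopard <- sc2$rasters$habitat_lion
  h2 <- default_hierarchies(); h2$wildlife$species <- c("lion", "leopard")
  both <- build_goal_suitability("wildlife", sc2, u, h2)
  expect_equal(both$suit_wildlife, got$suit_wildlife, tolerance = 1e-12)
})

test_that("wildlife goal rejects a missing species layer", {
  sc <- small_scene(); u <- small_units()
  h <- default_hierarchies(); h$wildlife$species <- c("lion", "rhino")
  expect_error(build_goal_suitability("wildlife", sc, u, h), "rhino")
})

test_that("full agriculture and settlement surfaces stay on the 1-9 scale", {
  sc <- small_scene(); u <- small_units()
  cache <- new.env()
  for (goal in c("agriculture", "settlement"))
    u <- build_goal_suitability(goal, sc, u, cache = cache)
  for (col in c("suit_agriculture", "suit_settlement")) {
    expect_true(all(u[[col]] >= 1 & u[[col]] <= 9))
    expect_equal(range(u[[col]]), c(1, 9))
  }
})
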