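template_50 <- function(n = 50, cs = 100)
  raster_create(matrix(0, n, n), 0, n * cs, cs)

test_that("rasterize burns polygon cells by center containment", {
  tpl <- template_50(4, 100)
  # polygon covering exactly the 2x2 block of cells in the lower-left
  poly <- features_create(list(list(type = "polygon",
    coords = cbind(c(0, 200, 200, 0), c(0, 0, 200, 200)))))
  r <- rasterize_features(poly, tpl, burn = 1)
  expect_equal(sum(r$values == 1, na.rm = TRUE), 4)
  expect_true(all(is.na(r$values[1:2, ])))  # top rows untouched
})

test_that("rasterizing an empty feature set warns and returns background", {
  tpl <- template_50(10)
  expect_warning(r <- rasterize_features(features_create(), tpl, burn = 7),
                 "empty")
  expect_true(all(is.na(r$values)))
})

test_that("rasterize matches per-cell point-in-polygon brute force", {
  tpl <- template_50(50, 100)
  set.seed(11)
  polys <- lapply(1:3, function(i) {
    cx <- runif(1, 500, 4500); cy <- runif(1, 500, 4500)
    ang <- sort(runif(6, 0, 2 * pi))
    rad <- runif(6, 150, 700)
    list(type = "polygon", coords = cbind(cx + rad * cos(ang),
                                          cy + rad * sin(ang)))
  })
  r <- rasterize_features(features_create(polys), tpl, burn = 1)
  cc <- cell_centers(tpl)
  expected <- matrix(FALSE, 50, 50)
  for (p in polys)
    expected <- expected | matrix(
      mapply(function(x, y) pip_winding(x, y, p$coords), cc[, 1], cc[, 2]),
      50, 50)
  expect_identical(!is.na(r$values), expected)
})

test_that("rasterize rejects CRS mismatch", {
  tpl <- template_50(5)
  fs <- features_create(list(list(type = "point",
                                  coords = cbind(100, 100))), crs = "EPSG:4326")
  expect_error(rasterize_features(fs, tpl), "CRS mismatch")
})

test_that("distance surface: 3-4-5 triangle and on-feature zero", {
  tpl <- template_50(10, 100)
  # point at the center of cell (row 10, col 1): (50, 50)
  fs <- features_create(list(list(type = "point", coords = cbind(50, 50))))
  d <- euclidean_distance_surface(fs, tpl)
  expect_equal(d$values[10, 1], 0)
  # cell center offset by (300, 400): col 4, row 6 -> (350, 450)
  expect_equal(d$values[6, 4], 500)
})

test_that("distance surface matches brute-force nearest-point scan", {
  tpl <- template_50(40, 100)
  set.seed(5)
  pts <- cbind(runif(5, 0, 4000), runif(5, 0, 4000))
  fs <- features_create(lapply(seq_len(5), function(i)
    list(type = "point", coords = pts[i, , drop = FALSE])))
  d <- euclidean_distance_surface(fs, tpl)
  cc <- cell_centers(tpl)
  brute <- apply(cc, 1, function(p)
    min(sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2)))
  expect_equal(as.vector(d$values), brute, tolerance = 1e-6)
})

test_that("distance surface rejects empty features", {
  expect_error(euclidean_distance_surface(features_create(), template_50(5)),
               "empty")
})

test_that("distance surface is symmetric under x-reflection", {
  n <- 20; cs <- 100; W <- n * cs
  tpl <- raster_create(matrix(0, n, n), 0, W, cs)
  set.seed(9)
  pts <- cbind(runif(4, 0, W), runif(4, 0, W))
  fs <- features_create(lapply(1:4, function(i)
    list(type = "point", coords = pts[i, , drop = FALSE])))
  fs_ref <- features_create(lapply(1:4, function(i)
    list(type = "point", coords = cbind(W - pts[i, 1], pts[i, 2]))))
  d <- euclidean_distance_surface(fs, tpl)$values
  d_ref <- euclidean_distance_surface(fs_ref, tpl)$values
  expect_equal(d, d_ref[, n:1])
})

test_that("slope: flat plane is zero, tilted plane is arctan of grade", {
  flat <- raster_create(matrix(7, 10, 10), 0, 1000, 100)
  expect_true(all(slope_from_dem(flat)$values == 0))
  # rising 1 m per 100 m eastwards
  tilted <- raster_create(matrix(rep(seq(0, 9, by = 1), each = 10), 10, 10),
                          0, 1000, 100)
  s <- slope_from_dem(tilted)
  expect_equal(s$values[5, 5], atan(0.01) * 180 / pi, tolerance = 1e-9)
  expect_equal(s$values[1, 1], atan(0.01) * 180 / pi, tolerance = 1e-9)
})

test_that("slope matches an independent finite-difference recomputation", {
  set.seed(21)
  n <- 30; cs <- 50
  z <- matrix(rnorm(n * n), n, n)
  z <- (z + z[, c(1, 1:(n - 1))] + z[c(1, 1:(n - 1)), ]) / 3  # mild smooth
  dem <- raster_create(z, 0, n * cs, cs)
  s <- slope_from_dem(dem)$values
  for (idx in list(c(2, 2), c(15, 7), c(29, 29), c(1, 15), c(30, 1))) {
    i <- idx[1]; j <- idx[2]
    jl <- max(1, j - 1); jr <- min(n, j + 1)
    iu <- max(1, i - 1); id <- min(n, i + 1)
    dzdx <- (z[i, jr] - z[i, jl]) / ((jr - jl) * cs)
    dzdy <- (z[iu, j] - z[id, j]) / ((id - iu) * cs)
    expect_equal(s[i, j], atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi,
                 tolerance = 1e-9)
  }
})

test_that("slope rejects grids smaller than 2x2", {
  expect_error(slope_from_dem(raster_create(matrix(1, 1, 5), 0, 100, 100)),
               "2 x 2")
})

test_that("align_to_grid: identity, constancy, categorical contract", {
  src <- raster_create(matrix(rnorm(100), 10, 10), 0, 1000, 100)
  expect_equal(align_to_grid(src, src, "nearest")$values, src$values)
  expect_equal(align_to_grid(src, src, "bilinear")$values, src$values)

  const <- raster_create(matrix(3.5, 20, 20), 0, 1000, 50)
  tpl <- raster_create(matrix(0, 10, 10), 0, 1000, 100)
  expect_true(all(align_to_grid(const, tpl, "bilinear")$values == 3.5))

  checker <- raster_create(outer(1:8, 1:8, function(i, j) (i + j) %% 2),
                           0, 800, 100, categorical = TRUE)
  tpl2 <- raster_create(matrix(0, 4, 4), 0, 800, 200)
  down <- align_to_grid(checker, tpl2, "nearest")
  expect_true(all(down$values %in% c(0, 1)))
  expect_error(align_to_grid(checker, tpl2, "bilinear"), "categorical")
})

test_that("align_to_grid nearest is idempotent on its own output", {
  src <- raster_create(matrix(rnorm(144), 12, 12), 0, 600, 50)
  tpl <- raster_create(matrix(0, 8, 8), 30, 580, 70)
  once <- align_to_grid(src, tpl, "nearest")
  twice <- align_to_grid(once, tpl, "nearest")
  expect_identical(once$values, twice$values)
})

test_that("decision units: degenerate all-fine and all-coarse grids", {
  ext <- c(0, 0, 4000, 4000)
  u_fine <- build_decision_units(ext, NULL, NULL)
  expect_true(all(u_fine$resolution_class == "fine"))
  expect_equal(nrow(u_fine), (4000 / 250)^2)

  whole <- features_create(list(list(type = "polygon",
    coords = cbind(c(-1, 4001, 4001, -1), c(-1, -1, 4001, 4001)))))
  u_coarse <- build_decision_units(ext, NULL, whole)
  expect_true(all(u_coarse$resolution_class == "coarse"))
  expect_equal(nrow(u_coarse), (4000 / 1000)^2)
})

test_that("a developed intrusion decomposes exactly one coarse cell", {
  ext <- c(0, 0, 2000, 2000)   # 4 coarse cells
  prot <- features_create(list(list(type = "polygon",
    coords = cbind(c(-1, 2001, 2001, -1), c(-1, -1, 2001, 2001)))))
  stl <- features_create(list(list(type = "point", coords = cbind(100, 100))))
  u <- build_decision_units(ext, stl, prot, developed_buffer_m = 300)
  expect_equal(sum(u$resolution_class == "coarse"), 3)
  expect_equal(sum(u$resolution_class == "fine"), 16)
  # the decomposed block is the lower-left coarse square
  expect_true(all(u$x0[u$resolution_class == "fine"] < 1000))
  expect_true(all(u$y0[u$resolution_class == "fine"] < 1000))
})

test_that("decision units partition the extent exactly", {
  sc <- small_scene()
  u <- small_units()
  ext <- sc$extent
  expect_equal(units_area_km2(u),
               (ext[3] - ext[1]) * (ext[4] - ext[2]) / 1e6)
  # no overlap: total cell coverage equals unit count when mapped to fine
  expect_equal(sum((u$size_m / 250)^2), (15000 / 250)^2)
})

test_that("fine_m must divide coarse_m", {
  expect_error(build_decision_units(c(0, 0, 3000, 3000), fine_m = 300,
                                    coarse_m = 1000), "divide")
})

test_that("zonal aggregation: constancy, majority, and hand arithmetic", {
  r_const <- raster_create(matrix(4.2, 8, 8), 0, 2000, 250)
  u <- build_decision_units(c(0, 0, 2000, 2000))
  for (st in c("mean", "max", "majority")) {
    z <- zonal_aggregate(r_const, u, st, name = "s")
    expect_true(all(z$s == 4.2))
  }
  # mean over a 2x2-cell unit with values 1..4 -> 2.5
  r4 <- raster_create(matrix(c(1, 3, 2, 4), 2, 2), 0, 500, 250)
  u1 <- build_decision_units(c(0, 0, 500, 500), fine_m = 500, coarse_m = 500)
  expect_equal(zonal_aggregate(r4, u1, "mean", name = "s")$s, 2.5)
  expect_equal(zonal_aggregate(r4, u1, "max", name = "s")$s, 4)
})

test_that("zonal aggregation on coarse units averages all covered cells", {
  vals <- matrix(seq_len(16), 4, 4)
  r <- raster_create(vals, 0, 1000, 250)
  prot <- features_create(list(list(type = "polygon",
    coords = cbind(c(-1, 1001, 1001, -1), c(-1, -1, 1001, 1001)))))
  u <- build_decision_units(c(0, 0, 1000, 1000), NULL, prot)
  expect_equal(nrow(u), 1L)
  expect_equal(zonal_aggregate(r, u, "mean", name = "s")$s, mean(vals))
})
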