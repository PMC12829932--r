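# Independent oracles used across the suite. These deliberately use
# different algorithms from the package implementation.

# Exhaustive Jenks oracle: enumerate every ordered partition of the sorted
# data into k contiguous classes, minimize within-class SSD. Ties keep the
# first partition in lexicographic order of break positions.
jenks_oracle <- function(x, k) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  sse <- function(v) sum((v - mean(v))^2)
  if (k == 1) {
    return(list(breaks = numeric(0), sdcm = sse(x),
                sizes = n))
  }
  best <- NULL; best_cost <- Inf
  for (cut_idx in utils::combn(n - 1, k - 1, simplify = FALSE)) {
    starts <- c(1, cut_idx + 1)
    ends <- c(cut_idx, n)
    cost <- sum(mapply(function(s, e) sse(x[s:e]), starts, ends))
    if (cost < best_cost - 1e-12) {
      best_cost <- cost
      best <- list(breaks = x[cut_idx], sdcm = cost, sizes = ends - starts + 1)
    }
  }
  best
}

# Moran's I with rook (lag-1) weights by direct double loop over cells.
moran_i_rook <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  z <- m - mean(m)
  num <- 0; wsum <- 0
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (i > 1) { num <- num + z[i, j] * z[i - 1, j]; wsum <- wsum + 1 }
      if (i < nr) { num <- num + z[i, j] * z[i + 1, j]; wsum <- wsum + 1 }
      if (j > 1) { num <- num + z[i, j] * z[i, j - 1]; wsum <- wsum + 1 }
      if (j < nc) { num <- num + z[i, j] * z[i, j + 1]; wsum <- wsum + 1 }
    }
  }
  (nr * nc / wsum) * num / sum(z^2)
}

# Winding-number point-in-polygon (different formulation from the
# package's even-odd ray casting).
pip_winding <- function(px, py, ring) {
  n <- nrow(ring)
  wn <- 0
  for (i in seq_len(n)) {
    a <- ring[i, ]; b <- ring[if (i == n) 1 else i + 1, ]
    cross <- (b[1] - a[1]) * (py - a[2]) - (px - a[1]) * (b[2] - a[2])
    if (a[2] <= py) {
      if (b[2] > py && cross > 0) wn <- wn + 1
    } else {
      if (b[2] <= py && cross < 0) wn <- wn - 1
    }
  }
  wn != 0
}

# A small scene + decision units shared by pipeline-level tests
# (60 x 60 cells at 250 m). Memoized per test run.
.small_env <- new.env()
small_scene <- function() {
  if (is.null(.small_env$scene)) {
    cfg <- landscape_config(extent = c(0, 0, 15000, 15000), seed = 42L,
                            n_roads = 2L, n_settlements = 4L, n_farms = 15L,
                            n_boreholes = 10L, n_cattle_posts = 6L,
                            protected_fraction = 0.3,
                            field_range_m = 1500)
    .small_env$scene <- generate_scene(cfg)
  }
  .small_env$scene
}

small_units <- function() {
  if (is.null(.small_env$units)) {
    sc <- small_scene()
    .small_env$units <- build_decision_units(
      sc$extent, developed_features(sc), sc$vectors$protected_areas)
  }
  .small_env$units
}

# settlements + farms as one "developed" feature set
developed_features <- function(scene) {
  dev <- scene$vectors$settlements
  dev$geoms <- c(dev$geoms, scene$vectors$farms$geoms)
  dev$attrs <- data.frame(row.names = seq_along(dev$geoms))
  dev
}

# Hand-built deterministic scene where farms sit squarely inside the
# high-wildlife (eastern) half while soils, settlements and boreholes
# favor the west: removing the existing-land-use criteria pulls
# agriculture westwards, off the wildlife hotspot.
toy_corridor_scene <- function() {
  cs <- 250; n <- 40
  ext <- c(0, 0, n * cs, n * cs)
  grad_e <- matrix(rep(seq(0, 1, length.out = n), each = n), n, n)  # east-high
  bump <- matrix(stats::dnorm(seq(-2, 2, length.out = n)), n, n)     # interior ridge
  mk <- function(m, categorical = FALSE)
    raster_create(m, ext[1], ext[4], cs, categorical = categorical)
  hab <- grad_e * 0.9 + 0.1 * bump
  rasters <- list(
    soil_ph = mk(6 + 2 * (1 - grad_e) + 0.2 * bump),
    root_zone_depth = mk(60 + 60 * (1 - grad_e)),
    drainage = mk(2 + 2 * (1 - grad_e) + 0.1 * t(grad_e)),
    dem = mk(1000 + 20 * grad_e + 5 * bump),
    habitat_lion = mk(hab), habitat_leopard = mk(hab),
    habitat_hyaena = mk(hab), habitat_elephant = mk(hab),
    lulc = mk(1 + round(3 * grad_e), categorical = TRUE),
    population_density = mk(100 * (1 - grad_e)))
  pt <- function(x, y) list(type = "point", coords = cbind(x, y))
  # road serves the western settlements only; the eastern wildlife zone
  # is reached by farms, not by general road access
  road <- list(type = "line", coords = cbind(c(0, 0.6 * n * cs),
                                             c(n, n) * cs / 2))
  # farms: cluster in the east (top-tercile habitat), on the road
  fx <- seq(0.75, 0.92, length.out = 6) * n * cs
  farms <- features_create(lapply(fx, function(x) {
    hs <- 200
    list(type = "polygon",
         coords = cbind(c(x - hs, x + hs, x + hs, x - hs),
                        n * cs / 2 + c(-hs, -hs, hs, hs)))
  }))
  settlements <- features_create(list(pt(0.1 * n * cs, n * cs / 2),
                                      pt(0.2 * n * cs, 0.4 * n * cs)))
  boreholes <- features_create(list(pt(0.15 * n * cs, 0.55 * n * cs),
                                    pt(0.25 * n * cs, 0.45 * n * cs)))
  cattle <- features_create(list(pt(0.3 * n * cs, 0.5 * n * cs)))
  protected <- features_create(list(list(type = "polygon",
    coords = cbind(c(0, 0.3, 0.3, 0) * n * cs, c(0, 0, 0.2, 0.2) * n * cs))))
  structure(list(
    rasters = rasters,
    vectors = list(roads = features_create(list(road)),
                   settlements = settlements, farms = farms,
                   cattle_posts = cattle, boreholes = boreholes,
                   protected_areas = protected),
    config = landscape_config(extent = ext, cell_size_m = cs, seed = 0L,
                              protected_fraction = 0.06),
    extent = ext, crs = "EPSG:32734"), class = "lucis_scene")
}
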