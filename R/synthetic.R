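#' Species for which synthetic habitat-suitability surfaces are generated
#'
#' The four conflict-relevant large mammals carried through the livestock
#' wildlife-condition weights (lion, leopard, spotted hyaena, elephant).
#'
#' @export
lucis_species <- c("lion", "leopard", "hyaena", "elephant")

#' Configuration for a synthetic landscape
#'
#' Defines the scene the generator produces: a rectangular extent in
#' projected meters, gridded at `cell_size_m`, with autocorrelated
#' environmental fields, roads crossing the extent, settlements and farms
#' clustered along roads, water points, cattle posts, and a protected-area
#' block covering `protected_fraction` of the extent.
#' `farm_wildlife_overlap` controls what fraction of farms is placed inside
#' the top tercile of the combined wildlife-habitat surface — the knob that
#' recreates farms sitting on a wildlife corridor, and hence downstream
#' conflict.
#'
#' @param extent `c(xmin, ymin, xmax, ymax)` in meters (default 50 x 50 km).
#' @param cell_size_m grid resolution in meters (default 250).
#' @param seed integer master seed; every layer derives its own seed from
#'   it at a fixed offset, so adding a layer does not perturb existing ones.
#' @param n_roads,n_settlements,n_farms,n_boreholes,n_cattle_posts feature
#'   counts.
#' @param protected_fraction fraction of the extent under protection, in
#'   `[0, 1]`.
#' @param field_range_m spatial autocorrelation range of the environmental
#'   fields in meters.
#' @param farm_wildlife_overlap fraction of farms placed in top-tercile
#'   wildlife habitat, in `[0, 1]`.
#' @param crs CRS identifier.
#' @return A list of class `landscape_config`.
#' @export
landscape_config <- function(extent = c(0, 0, 50000, 50000),
                             cell_size_m = 250, seed = 1L,
                             n_roads = 3L, n_settlements = 8L, n_farms = 40L,
                             n_boreholes = 25L, n_cattle_posts = 15L,
                             protected_fraction = 0.35,
                             field_range_m = 2500,
                             farm_wildlife_overlap = 0.7,
                             crs = "EPSG:32734") {
  w <- extent[3] - extent[1]; h <- extent[4] - extent[2]
  if (w <= 0 || h <= 0) stop("extent must have positive area", call. = FALSE)
  if (cell_size_m <= 0) stop("cell_size_m must be positive", call. = FALSE)
  for (edge in c(w, h)) {
    ncells <- edge / cell_size_m
    if (abs(ncells - round(ncells)) * cell_size_m > cell_size_m)
      stop("cell_size_m must divide the extent edges within one cell",
           call. = FALSE)
  }
  if (protected_fraction < 0 || protected_fraction > 1)
    stop("protected_fraction must be in [0, 1]", call. = FALSE)
  if (farm_wildlife_overlap < 0 || farm_wildlife_overlap > 1)
    stop("farm_wildlife_overlap must be in [0, 1]", call. = FALSE)
  if (field_range_m <= 0) stop("field_range_m must be positive", call. = FALSE)
  counts <- c(n_roads = n_roads, n_settlements = n_settlements,
              n_farms = n_farms, n_boreholes = n_boreholes,
              n_cattle_posts = n_cattle_posts)
  if (any(counts < 0)) stop("feature counts must be non-negative", call. = FALSE)
  structure(list(extent = as.numeric(extent), cell_size_m = cell_size_m,
                 seed = as.integer(seed), n_roads = as.integer(n_roads),
                 n_settlements = as.integer(n_settlements),
                 n_farms = as.integer(n_farms),
                 n_boreholes = as.integer(n_boreholes),
                 n_cattle_posts = as.integer(n_cattle_posts),
                 protected_fraction = protected_fraction,
                 field_range_m = field_range_m,
                 farm_wildlife_overlap = farm_wildlife_overlap,
                 crs = crs),
            class = "landscape_config")
}

# Fixed per-layer seed offsets: the master seed plus these drive each
# layer's RNG independently.
.layer_seed_offsets <- c(
  soil_ph = 11L, root_zone_depth = 12L, drainage = 13L, dem = 14L,
  habitat_base = 20L, habitat_lion = 21L, habitat_leopard = 22L,
  habitat_hyaena = 23L, habitat_elephant = 24L,
  roads = 31L, settlements = 32L, farms = 33L, cattle_posts = 34L,
  boreholes = 35L, lulc = 41L, population = 42L)

layer_seed <- function(config, layer) {
  off <- .layer_seed_offsets[[layer]]
  if (is.null(off)) stop("unknown layer: ", layer, call. = FALSE)
  (config$seed * 101L + off) %% 2147483562L
}

#' Generate a spatially autocorrelated random field
#'
#' White Gaussian noise smoothed with a separable Gaussian kernel whose
#' standard deviation is `range_m / 2` (so correlation between points
#' separated by 3 x `range_m` or more is practically zero), then affinely
#' rescaled so the realized grid mean and standard deviation equal
#' `mean` and `sd` exactly. `sd = 0` yields a constant raster.
#'
#' @param config a `landscape_config` (supplies grid and master seed).
#' @param mean,sd target field mean and standard deviation (`sd >= 0`).
#' @param range_m autocorrelation range in meters (default
#'   `config$field_range_m`).
#' @param seed RNG seed for this field (default the config master seed).
#' @return A `lucis_raster`.
#' @export
generate_random_field <- function(config, mean = 0, sd = 1,
                                  range_m = config$field_range_m,
                                  seed = config$seed) {
  if (sd < 0) stop("sd must be >= 0", call. = FALSE)
  if (range_m <= 0) stop("range_m must be positive", call. = FALSE)
  cs <- config$cell_size_m
  if (cs <= 0) stop("cell_size_m must be positive", call. = FALSE)
  nr <- as.integer(round((config$extent[4] - config$extent[2]) / cs))
  nc <- as.integer(round((config$extent[3] - config$extent[1]) / cs))
  if (sd == 0) {
    return(raster_create(matrix(mean, nr, nc), config$extent[1],
                         config$extent[4], cs, config$crs))
  }
  f <- withr::with_seed(seed, {
    w <- matrix(stats::rnorm(nr * nc), nr, nc)
    sigma <- range_m / 2 / cs                      # in cells
    kern <- function(n) {
      k <- exp(-outer(seq_len(n), seq_len(n), "-")^2 / (2 * sigma^2))
      k / rowSums(k)                               # edge renormalization
    }
    kern(nr) %*% w %*% t(kern(nc))
  })
  f <- (f - base::mean(f)) / stats::sd(f) * sd + mean
  raster_create(f, config$extent[1], config$extent[4], cs, config$crs)
}

# min-max rescale a matrix to [0, 1]
.unit_scale <- function(m) {
  lo <- min(m); hi <- max(m)
  if (hi - lo <= 0) return(m * 0 + 0.5)
  (m - lo) / (hi - lo)
}

# piecewise-linear road crossing the extent; horiz alternates per index
.make_road <- function(extent, horizontal, frac, n_interior = 3L) {
  w <- extent[3] - extent[1]; h <- extent[4] - extent[2]
  tpos <- seq(0, 1, length.out = n_interior + 2L)
  jitter_along <- c(0, stats::runif(n_interior, -0.05, 0.05), 0)
  jitter_across <- c(stats::runif(n_interior + 2L, -0.08, 0.08))
  tpos <- pmin(1, pmax(0, tpos + jitter_along))
  if (horizontal) {
    x <- extent[1] + tpos * w
    y <- extent[2] + pmin(0.98, pmax(0.02, frac + jitter_across)) * h
  } else {
    y <- extent[2] + tpos * h
    x <- extent[1] + pmin(0.98, pmax(0.02, frac + jitter_across)) * w
  }
  list(type = "line", coords = cbind(x, y))
}

# square polygon of side `side` centered at (x, y)
.square_poly <- function(x, y, side) {
  hs <- side / 2
  list(type = "polygon",
       coords = cbind(c(x - hs, x + hs, x + hs, x - hs),
                      c(y - hs, y - hs, y + hs, y + hs)))
}

#' Generate a complete synthetic scene
#'
#' Assembles the full layer inventory the suitability analysis consumes:
#' autocorrelated environmental rasters (soil pH, root-zone depth,
#' drainage, DEM), per-species wildlife habitat-suitability surfaces, a
#' categorical land-use/land-cover raster consistent with the vector
#' features, a settlement-anchored population-density surface, and vector
#' layers (roads crossing the extent; settlements seeded at road vertices;
#' farm polygons placed near roads with a controlled fraction inside
#' top-tercile wildlife habitat; cattle posts near roads; boreholes;
#' a protected-area block realizing `protected_fraction` exactly).
#' Identical config (including seed) always yields an identical scene.
#'
#' @param config a `landscape_config`.
#' @return A list of class `lucis_scene` with elements `rasters` (named
#'   `lucis_raster`s), `vectors` (named `lucis_features`), `config`,
#'   `extent`, `crs`.
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  ext <- config$extent; cs <- config$cell_size_m; crs <- config$crs
  rasters <- list()
  for (nm in c("soil_ph", "root_zone_depth", "drainage", "dem")) {
    pars <- switch(nm,
      soil_ph = c(6.5, 0.8, config$field_range_m),
      root_zone_depth = c(90, 30, config$field_range_m),
      drainage = c(3, 1, config$field_range_m),
      dem = c(1050, 12, 4 * config$field_range_m))  # flat, gently sloping
    rasters[[nm]] <- generate_random_field(config, pars[1], pars[2], pars[3],
                                           seed = layer_seed(config, nm))
  }

  # species habitat: shared structure plus species-specific variation, 0..1
  base_h <- generate_random_field(config, 0, 1, 2 * config$field_range_m,
                                  seed = layer_seed(config, "habitat_base"))
  for (sp in lucis_species) {
    own <- generate_random_field(config, 0, 1, 2 * config$field_range_m,
                                 seed = layer_seed(config,
                                                   paste0("habitat_", sp)))
    h <- base_h
    h$values <- .unit_scale(0.6 * base_h$values + 0.4 * own$values)
    rasters[[paste0("habitat_", sp)]] <- h
  }
  combined <- rasters[[paste0("habitat_", lucis_species[1])]]
  combined$values <- Reduce(`+`, lapply(lucis_species, function(sp)
    rasters[[paste0("habitat_", sp)]]$values)) / length(lucis_species)

  template <- rasters$dem

  # roads: piecewise-linear paths crossing the extent
  roads <- withr::with_seed(layer_seed(config, "roads"), {
    geoms <- lapply(seq_len(config$n_roads), function(i)
      .make_road(ext, horizontal = i %% 2L == 1L,
                 frac = (i + 0.5) / (config$n_roads + 1)))
    features_create(geoms, crs = crs)
  })

  road_dist <- if (config$n_roads > 0)
    euclidean_distance_surface(roads, template) else NULL

  # settlements: seeded at interior road vertices, jittered
  settlements <- withr::with_seed(layer_seed(config, "settlements"), {
    if (config$n_settlements == 0L || config$n_roads == 0L) {
      features_create(list(), crs = crs)
    } else {
      verts <- do.call(rbind, lapply(roads$geoms, function(g)
        g$coords[2:(nrow(g$coords) - 1L), , drop = FALSE]))
      idx <- sample.int(nrow(verts), config$n_settlements, replace = TRUE)
      pts <- verts[idx, , drop = FALSE] +
        matrix(stats::runif(2 * config$n_settlements, -400, 400), ncol = 2)
      pts[, 1] <- pmin(ext[3] - cs, pmax(ext[1] + cs, pts[, 1]))
      pts[, 2] <- pmin(ext[4] - cs, pmax(ext[2] + cs, pts[, 2]))
      features_create(lapply(seq_len(nrow(pts)), function(i)
        list(type = "point", coords = pts[i, , drop = FALSE])), crs = crs)
    }
  })

  # farms: a fraction farm_wildlife_overlap goes into top-tercile habitat
  # cells; all farms favor road proximity. Placement samples among the
  # road-nearest candidate cells so clustering is preserved.
  cc <- cell_centers(template)
  hab_vec <- as.vector(combined$values)
  top_thr <- stats::quantile(hab_vec, 2 / 3, names = FALSE)
  rd_vec <- if (!is.null(road_dist)) as.vector(road_dist$values)
            else rep(1, length(hab_vec))
  farms <- withr::with_seed(layer_seed(config, "farms"), {
    nf <- config$n_farms
    if (nf == 0L) features_create(list(), crs = crs) else {
      n_top <- round(config$farm_wildlife_overlap * nf)
      # road-proximity-weighted sampling over the whole habitat stratum:
      # farms line up along roads without collapsing into one patch
      pick <- function(cells, n) {
        if (length(cells) < n)
          stop("extent too small to place the requested number of farms",
               call. = FALSE)
        w <- exp(-rd_vec[cells] / 2000)
        cells[sample.int(length(cells), n, prob = w)]
      }
      # keep farm squares fully inside the extent
      interior <- cc[, 1] >= ext[1] + 1.5 * cs & cc[, 1] <= ext[3] - 1.5 * cs &
                  cc[, 2] >= ext[2] + 1.5 * cs & cc[, 2] <= ext[4] - 1.5 * cs
      top_cells <- which(hab_vec > top_thr & interior)
      low_cells <- which(hab_vec <= top_thr & interior)
      chosen <- c(if (n_top > 0L) pick(top_cells, n_top),
                  if (nf - n_top > 0L) pick(low_cells, nf - n_top))
      jit <- matrix(stats::runif(2 * nf, -cs / 6, cs / 6), ncol = 2)
      geoms <- lapply(seq_len(nf), function(i)
        .square_poly(cc[chosen[i], 1] + jit[i, 1],
                     cc[chosen[i], 2] + jit[i, 2], side = 2 * cs))
      features_create(geoms, attrs = data.frame(cell = chosen), crs = crs)
    }
  })

  # cattle posts: points in cells within 2 km of a road
  cattle_posts <- withr::with_seed(layer_seed(config, "cattle_posts"), {
    np <- config$n_cattle_posts
    if (np == 0L) features_create(list(), crs = crs) else {
      near <- which(rd_vec <= 2000)
      if (length(near) < np)
        stop("extent too small to place the requested cattle posts",
             call. = FALSE)
      chosen <- sample(near, np)
      pts <- cc[chosen, , drop = FALSE] +
        matrix(stats::runif(2 * np, -cs / 3, cs / 3), ncol = 2)
      features_create(lapply(seq_len(np), function(i)
        list(type = "point", coords = pts[i, , drop = FALSE])), crs = crs)
    }
  })

  # boreholes: uniform over the extent
  boreholes <- withr::with_seed(layer_seed(config, "boreholes"), {
    nb <- config$n_boreholes
    if (nb == 0L) features_create(list(), crs = crs) else {
      pts <- cbind(stats::runif(nb, ext[1], ext[3]),
                   stats::runif(nb, ext[2], ext[4]))
      features_create(lapply(seq_len(nb), function(i)
        list(type = "point", coords = pts[i, , drop = FALSE])), crs = crs)
    }
  })

  # protected areas: a northern block realizing the fraction exactly
  protected_areas <- if (config$protected_fraction > 0) {
    band_h <- config$protected_fraction * (ext[4] - ext[2])
    features_create(list(list(type = "polygon",
      coords = cbind(c(ext[1], ext[3], ext[3], ext[1]),
                     c(ext[4] - band_h, ext[4] - band_h, ext[4], ext[4])))),
      attrs = data.frame(name = "protected_block"), crs = crs)
  } else features_create(list(), crs = crs)

  # LULC: thresholded random field into 4 natural classes, then overrides
  # where farms (cropland = 5) and settlements (built = 6) are rasterized
  lulc_field <- generate_random_field(config, 0, 1, config$field_range_m,
                                      seed = layer_seed(config, "lulc"))
  qs <- stats::quantile(lulc_field$values, c(0.4, 0.7, 0.9), names = FALSE)
  lv <- matrix(1, nrow(lulc_field$values), ncol(lulc_field$values))
  lv[lulc_field$values > qs[1]] <- 2
  lv[lulc_field$values > qs[2]] <- 3
  lv[lulc_field$values > qs[3]] <- 4
  lulc <- raster_create(lv, ext[1], ext[4], cs, crs, categorical = TRUE)
  if (length(farms$geoms)) {
    fr <- rasterize_features(farms, template, burn = 5)
    lulc$values[!is.na(fr$values)] <- 5
  }
  if (length(settlements$geoms)) {
    for (g in settlements$geoms) {
      d <- sqrt((cc[, 1] - g$coords[1, 1])^2 + (cc[, 2] - g$coords[1, 2])^2)
      lulc$values[d <= 1.5 * cs] <- 6
    }
  }

  # population density: kernel bumps around settlements plus faint noise
  pop <- withr::with_seed(layer_seed(config, "population"), {
    base <- abs(stats::rnorm(length(hab_vec), 0, 0.05))
    if (length(settlements$geoms)) {
      for (g in settlements$geoms) {
        d <- sqrt((cc[, 1] - g$coords[1, 1])^2 + (cc[, 2] - g$coords[1, 2])^2)
        base <- base + 400 * exp(-d^2 / (2 * 1500^2))
      }
    }
    raster_create(matrix(base, nrow(template$values), ncol(template$values)),
                  ext[1], ext[4], cs, crs)
  })
  rasters$lulc <- lulc
  rasters$population_density <- pop

  scene <- structure(list(
    rasters = rasters,
    vectors = list(roads = roads, settlements = settlements, farms = farms,
                   cattle_posts = cattle_posts, boreholes = boreholes,
                   protected_areas = protected_areas),
    config = config, extent = ext, crs = crs),
    class = "lucis_scene")
  validate_scene(scene)
  scene
}

#' Validate scene invariants
#'
#' Checks that all rasters share one grid and CRS, all vector coordinates
#' fall inside the extent, and the realized protected fraction is within
#' 0.05 of the requested fraction.
#'
#' @param scene a `lucis_scene`.
#' @return `scene`, invisibly; errors on violation.
#' @export
validate_scene <- function(scene) {
  r0 <- scene$rasters[[1]]
  for (r in scene$rasters) {
    if (!same_grid(r, r0) || !identical(r$crs, r0$crs))
      stop("all scene rasters must share one grid and CRS", call. = FALSE)
  }
  ext <- scene$extent
  for (fs in scene$vectors) {
    for (g in fs$geoms) {
      xy <- g$coords
      if (any(xy[, 1] < ext[1] - 1e-6) || any(xy[, 1] > ext[3] + 1e-6) ||
          any(xy[, 2] < ext[2] - 1e-6) || any(xy[, 2] > ext[4] + 1e-6))
        stop("vector geometry outside the scene extent", call. = FALSE)
    }
  }
  tot <- (ext[3] - ext[1]) * (ext[4] - ext[2])
  realized <- features_area_m2(scene$vectors$protected_areas) / tot
  if (abs(realized - scene$config$protected_fraction) > 0.05)
    stop(sprintf("realized protected fraction %.3f is off the requested %.3f",
                 realized, scene$config$protected_fraction), call. = FALSE)
  invisible(scene)
}

#' Combined multi-species habitat surface
#'
#' Cell-statistic combination of the per-species habitat rasters.
#'
#' @param scene a `lucis_scene` (or any named raster list with
#'   `habitat_<species>` entries).
#' @param species character vector of species names.
#' @param stat `"mean"` (default) or `"max"`.
#' @return A `lucis_raster`.
#' @export
combine_habitat <- function(scene, species = lucis_species,
                            stat = c("mean", "max")) {
  stat <- match.arg(stat)
  rs <- lapply(species, function(sp) {
    r <- scene$rasters[[paste0("habitat_", sp)]]
    if (is.null(r)) stop("missing species habitat layer: ", sp, call. = FALSE)
    r
  })
  out <- rs[[1]]
  vals <- lapply(rs, `[[`, "values")
  out$values <- if (stat == "mean") Reduce(`+`, vals) / length(vals)
                else Reduce(pmax, vals)
  out
}

#' Write a scene to a directory
#'
#' Rasters as ESRI ASCII grids, vectors as GeoJSON, plus a YAML manifest
#' recording layer paths, the CRS, and the full generation config.
#'
#' @param scene a `lucis_scene`.
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- list(crs = scene$crs, extent = as.numeric(scene$extent),
              config = unclass(scene$config), rasters = list(),
              vectors = list())
  for (nm in names(scene$rasters)) {
    p <- file.path(dir, paste0(nm, ".asc"))
    write_ascii_grid(scene$rasters[[nm]], p)
    man$rasters[[nm]] <- list(path = basename(p),
                              categorical = scene$rasters[[nm]]$categorical)
  }
  for (nm in names(scene$vectors)) {
    p <- file.path(dir, paste0(nm, ".geojson"))
    write_geojson(scene$vectors[[nm]], p)
    man$vectors[[nm]] <- basename(p)
  }
  mp <- file.path(dir, "scene.yaml")
  yaml::write_yaml(man, mp)
  invisible(mp)
}

#' Read a scene written by [write_scene()]
#'
#' @param dir scene directory containing `scene.yaml`.
#' @return A `lucis_scene`.
#' @export
read_scene <- function(dir) {
  man <- yaml::read_yaml(file.path(dir, "scene.yaml"))
  rasters <- lapply(man$rasters, function(e)
    read_ascii_grid(file.path(dir, e$path), crs = man$crs,
                    categorical = isTRUE(e$categorical)))
  vectors <- lapply(man$vectors, function(p) read_geojson(file.path(dir, p)))
  cfg <- man$config
  config <- landscape_config(
    extent = as.numeric(cfg$extent), cell_size_m = cfg$cell_size_m,
    seed = cfg$seed, n_roads = cfg$n_roads,
    n_settlements = cfg$n_settlements, n_farms = cfg$n_farms,
    n_boreholes = cfg$n_boreholes, n_cattle_posts = cfg$n_cattle_posts,
    protected_fraction = cfg$protected_fraction,
    field_range_m = cfg$field_range_m,
    farm_wildlife_overlap = cfg$farm_wildlife_overlap, crs = man$crs)
  structure(list(rasters = rasters, vectors = vectors, config = config,
                 extent = config$extent, crs = man$crs),
            class = "lucis_scene")
}

#' @export
print.lucis_scene <- function(x, ...) {
  cat(sprintf("<lucis_scene> %g x %g km @ %g m, seed %d\n",
              (x$extent[3] - x$extent[1]) / 1000,
              (x$extent[4] - x$extent[2]) / 1000,
              x$config$cell_size_m, x$config$seed))
  cat("  rasters:", paste(names(x$rasters), collapse = ", "), "\n")
  cat("  vectors:", paste(sprintf("%s(%d)", names(x$vectors),
                                  vapply(x$vectors, length, 0L)),
                          collapse = ", "), "\n")
  invisible(x)
}
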