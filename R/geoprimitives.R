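#' Rasterize a feature set onto a template grid
#'
#' Cell membership follows the package's single stated convention:
#' polygons burn cells whose *centers* they contain; points burn the cell
#' containing the point; lines burn every cell their path passes through
#' (dense sampling at half-cell steps).
#'
#' @param features a `lucis_features`.
#' @param template a `lucis_raster` defining the output grid.
#' @param burn value to burn, or the name of an attribute column to take
#'   per-feature burn values from.
#' @param background value for untouched cells (default `NA`).
#' @return A `lucis_raster` on the template grid.
#' @export
rasterize_features <- function(features, template, burn = 1,
                               background = NA_real_) {
  if (!identical(features$crs, template$crs))
    stop("CRS mismatch: features are ", features$crs, ", template is ",
         template$crs, call. = FALSE)
  out <- matrix(background, nrow(template$values), ncol(template$values))
  if (length(features$geoms) == 0L) {
    warning("empty feature set: returning all-background raster")
    return(raster_create(out, template$xmin, template$ymax,
                         template$cell_size_m, template$crs,
                         categorical = is.character(burn) || template$categorical))
  }
  burn_vals <- if (is.character(burn)) features$attrs[[burn]]
               else rep(burn, length(features$geoms))
  cs <- template$cell_size_m
  cc <- NULL
  for (i in seq_along(features$geoms)) {
    g <- features$geoms[[i]]
    if (g$type == "point") {
      rc <- point_to_cell(template, g$coords[1, 1], g$coords[1, 2])
      if (!is.na(rc[1, 1])) out[rc[1, 1], rc[1, 2]] <- burn_vals[i]
    } else if (g$type == "line") {
      xy <- g$coords
      for (s in seq_len(nrow(xy) - 1L)) {
        a <- xy[s, ]; b <- xy[s + 1L, ]
        len <- sqrt(sum((b - a)^2))
        t <- seq(0, 1, length.out = max(2L, ceiling(len / (cs / 2)) + 1L))
        rc <- point_to_cell(template, a[1] + t * (b[1] - a[1]),
                            a[2] + t * (b[2] - a[2]))
        ok <- !is.na(rc[, 1])
        out[rc[ok, , drop = FALSE]] <- burn_vals[i]
      }
    } else {  # polygon: cell-center containment
      if (is.null(cc)) cc <- cell_centers(template)
      inside <- points_in_ring(cc[, 1], cc[, 2], g$coords)
      out[inside] <- burn_vals[i]
    }
  }
  raster_create(out, template$xmin, template$ymax, cs, template$crs,
                categorical = is.character(burn) || template$categorical)
}

#' Euclidean distance surface
#'
#' Each cell of the template receives the planar distance in meters from
#' its center to the nearest feature; cells whose center lies on or inside
#' a feature get 0.
#'
#' @param features a non-empty `lucis_features`.
#' @param template a `lucis_raster` defining the output grid.
#' @return A `lucis_raster` of distances in meters.
#' @export
euclidean_distance_surface <- function(features, template) {
  if (length(features$geoms) == 0L)
    stop("distance surface over an empty feature set is undefined",
         call. = FALSE)
  if (!identical(features$crs, template$crs))
    stop("CRS mismatch between features and template", call. = FALSE)
  cc <- cell_centers(template)
  d <- points_to_features_dist(features, cc[, 1], cc[, 2])
  raster_create(matrix(d, nrow(template$values), ncol(template$values)),
                template$xmin, template$ymax, template$cell_size_m,
                template$crs)
}

#' Slope in degrees from a DEM
#'
#' Central finite differences at interior cells, one-sided differences at
#' the border; `NA` elevation propagates to any cell whose stencil touches
#' it.
#'
#' @param dem a continuous `lucis_raster` of elevations in meters.
#' @return A `lucis_raster` of slope in degrees.
#' @export
slope_from_dem <- function(dem) {
  v <- dem$values
  nr <- nrow(v); nc <- ncol(v)
  if (nr < 2L || nc < 2L)
    stop("DEM must be at least 2 x 2 cells", call. = FALSE)
  cs <- dem$cell_size_m
  # column index increases eastwards, row index southwards
  left  <- v[, c(1L, seq_len(nc - 1L)), drop = FALSE]
  right <- v[, c(2:nc, nc), drop = FALSE]
  dxspan <- matrix(rep(ifelse(seq_len(nc) %in% c(1L, nc), cs, 2 * cs),
                       each = nr), nr, nc)
  dzdx <- (right - left) / dxspan
  up   <- v[c(1L, seq_len(nr - 1L)), , drop = FALSE]
  down <- v[c(2:nr, nr), , drop = FALSE]
  dyspan <- matrix(rep(ifelse(seq_len(nr) %in% c(1L, nr), cs, 2 * cs),
                       times = nc), nr, nc)
  dzdy <- (up - down) / dyspan  # y increases northwards = decreasing row
  slope <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  raster_create(slope, dem$xmin, dem$ymax, cs, dem$crs)
}

#' Align a raster to a template grid
#'
#' Resamples `src` onto the grid of `template`. Categorical layers must use
#' nearest-neighbor; bilinear never interpolates across `NA` (any `NA`
#' among the four contributing cells yields `NA`).
#'
#' @param src source `lucis_raster`.
#' @param template `lucis_raster` whose grid defines the output.
#' @param mode `"nearest"` or `"bilinear"`.
#' @return A `lucis_raster` on the template grid.
#' @export
align_to_grid <- function(src, template, mode = c("nearest", "bilinear")) {
  mode <- match.arg(mode)
  if (src$categorical && mode == "bilinear")
    stop("bilinear resampling is not valid for a categorical layer",
         call. = FALSE)
  if (same_grid(src, template)) {
    out <- src
    out$xmin <- template$xmin; out$ymax <- template$ymax
    return(out)
  }
  cc <- cell_centers(template)
  cs <- src$cell_size_m
  # fractional (row, col) position of template centers in src index space
  fc <- (cc[, 1] - src$xmin) / cs + 0.5
  fr <- (src$ymax - cc[, 2]) / cs + 0.5
  nr <- nrow(src$values); nc <- ncol(src$values)
  if (mode == "nearest") {
    ri <- pmin(nr, pmax(1L, round(fr)))
    ci <- pmin(nc, pmax(1L, round(fc)))
    outside <- fr < 0.5 - 1e-9 | fr > nr + 0.5 + 1e-9 |
               fc < 0.5 - 1e-9 | fc > nc + 0.5 + 1e-9
    vals <- src$values[cbind(ri, ci)]
    vals[outside] <- NA_real_
  } else {
    r0 <- floor(fr - 0.5) + 0.5; c0 <- floor(fc - 0.5) + 0.5
    wr <- fr - r0; wc <- fc - c0
    gi <- function(r, c) {
      ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
      v <- rep(NA_real_, length(r))
      v[ok] <- src$values[cbind(r[ok], c[ok])]
      v
    }
    r1 <- r0 + 0.5; r2 <- r1 + 1; c1 <- c0 + 0.5; c2 <- c1 + 1
    # clamp the off-grid neighbor back when the center row/col sits on the
    # outermost half-cell band (degenerates to 1-D/0-D interpolation)
    r1c <- pmin(nr, pmax(1, r1)); r2c <- pmin(nr, pmax(1, r2))
    c1c <- pmin(nc, pmax(1, c1)); c2c <- pmin(nc, pmax(1, c2))
    v11 <- gi(r1c, c1c); v12 <- gi(r1c, c2c)
    v21 <- gi(r2c, c1c); v22 <- gi(r2c, c2c)
    vals <- v11 * (1 - wr) * (1 - wc) + v12 * (1 - wr) * wc +
            v21 * wr * (1 - wc) + v22 * wr * wc
    outside <- fr < 0.5 | fr > nr + 0.5 | fc < 0.5 | fc > nc + 0.5
    vals[outside] <- NA_real_
  }
  raster_create(matrix(vals, nrow(template$values), ncol(template$values)),
                template$xmin, template$ymax, template$cell_size_m,
                template$crs, categorical = src$categorical)
}

#' Build a multi-resolution decision-unit grid
#'
#' Square decision units tile the extent exactly: fine cells (default
#' 250 m) everywhere except inside protected areas away from development,
#' where coarse cells (default 1000 m) suffice. A coarse unit is emitted
#' only where the *entire* coarse square lies inside a protected polygon
#' and no part of it is within `developed_buffer_m` of a developed
#' feature (tested at fine-cell centers); otherwise the square decomposes
#' into fine units.
#'
#' @param extent `c(xmin, ymin, xmax, ymax)` in meters; edges must be
#'   multiples of `coarse_m`.
#' @param developed `lucis_features` of developed features (settlements,
#'   farms), or an empty set.
#' @param protected `lucis_features` of protected-area polygons, or empty.
#' @param fine_m,coarse_m unit edge lengths in meters; `fine_m` must divide
#'   `coarse_m`.
#' @param developed_buffer_m proximity within which land is considered
#'   "near developed areas" (default 2000 m).
#' @param crs CRS identifier.
#' @return A `lucis_units` object: a data.frame with columns `id`, `x0`,
#'   `y0` (lower-left corner), `size_m`, `resolution_class`; score columns
#'   are appended by [zonal_aggregate()] and the suitability pipeline.
#' @export
build_decision_units <- function(extent, developed = NULL, protected = NULL,
                                 fine_m = 250, coarse_m = 1000,
                                 developed_buffer_m = 2000,
                                 crs = "EPSG:32734") {
  ratio <- coarse_m / fine_m
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("fine_m must divide coarse_m", call. = FALSE)
  ratio <- as.integer(round(ratio))
  w <- extent[3] - extent[1]; h <- extent[4] - extent[2]
  if (w <= 0 || h <= 0) stop("extent must have positive area", call. = FALSE)
  ncx <- w / coarse_m; ncy <- h / coarse_m
  if (abs(ncx - round(ncx)) > 1e-6 || abs(ncy - round(ncy)) > 1e-6)
    stop("extent edges must be whole multiples of coarse_m", call. = FALSE)
  ncx <- round(ncx); ncy <- round(ncy)

  # classify every fine cell: coarse-eligible iff center inside a protected
  # polygon and farther than the buffer from all developed features
  nfx <- as.integer(round(w / fine_m)); nfy <- as.integer(round(h / fine_m))
  fx <- extent[1] + (seq_len(nfx) - 0.5) * fine_m
  fy <- extent[2] + (seq_len(nfy) - 0.5) * fine_m
  px <- rep(fx, times = nfy); py <- rep(fy, each = nfx)
  in_prot <- rep(FALSE, length(px))
  if (!is.null(protected) && length(protected$geoms)) {
    for (g in protected$geoms)
      if (g$type == "polygon")
        in_prot <- in_prot | points_in_ring(px, py, g$coords)
  }
  near_dev <- rep(FALSE, length(px))
  if (!is.null(developed) && length(developed$geoms)) {
    d <- points_to_features_dist(developed, px, py)
    near_dev <- d <= developed_buffer_m
  }
  eligible <- matrix(in_prot & !near_dev, nfx, nfy)  # [fine x, fine y]

  units_x0 <- numeric(0); units_y0 <- numeric(0); units_sz <- numeric(0)
  units_cl <- character(0)
  for (cy in seq_len(ncy)) {
    for (cx in seq_len(ncx)) {
      ix <- ((cx - 1L) * ratio + 1L):(cx * ratio)
      iy <- ((cy - 1L) * ratio + 1L):(cy * ratio)
      x0 <- extent[1] + (cx - 1L) * coarse_m
      y0 <- extent[2] + (cy - 1L) * coarse_m
      if (all(eligible[ix, iy])) {
        units_x0 <- c(units_x0, x0); units_y0 <- c(units_y0, y0)
        units_sz <- c(units_sz, coarse_m); units_cl <- c(units_cl, "coarse")
      } else {
        gx <- x0 + (seq_len(ratio) - 1L) * fine_m
        gy <- y0 + (seq_len(ratio) - 1L) * fine_m
        units_x0 <- c(units_x0, rep(gx, times = ratio))
        units_y0 <- c(units_y0, rep(gy, each = ratio))
        units_sz <- c(units_sz, rep(fine_m, ratio^2))
        units_cl <- c(units_cl, rep("fine", ratio^2))
      }
    }
  }
  df <- data.frame(id = seq_along(units_x0), x0 = units_x0, y0 = units_y0,
                   size_m = units_sz, resolution_class = units_cl,
                   stringsAsFactors = FALSE)
  structure(df, extent = extent, crs = crs, fine_m = fine_m,
            coarse_m = coarse_m,
            class = c("lucis_units", "data.frame"))
}

#' Unit centroids
#'
#' @param units a `lucis_units`.
#' @return n x 2 matrix of square-unit centroids.
#' @export
unit_centroids <- function(units) {
  cbind(x = units$x0 + units$size_m / 2, y = units$y0 + units$size_m / 2)
}

#' Total area of the decision units
#'
#' @param units a `lucis_units`.
#' @return Area in square kilometers.
#' @export
units_area_km2 <- function(units) sum((units$size_m / 1000)^2)

#' Zonal aggregation of a raster over decision units
#'
#' Aggregates the raster cells whose centers fall in each unit and stores
#' the result as a new score column. Units containing only `NA` cells get
#' `NA`.
#'
#' @param raster a `lucis_raster` covering the units' extent.
#' @param units a `lucis_units`.
#' @param stat `"mean"`, `"max"`, or `"majority"` (most frequent value,
#'   ties broken toward the smallest).
#' @param name name of the score column to create (default `"score"`).
#' @return `units` with the new column appended.
#' @export
zonal_aggregate <- function(raster, units, stat = c("mean", "max", "majority"),
                            name = "score") {
  stat <- match.arg(stat)
  cs <- raster$cell_size_m
  nr <- nrow(raster$values); nc <- ncol(raster$values)
  v <- raster$values
  agg1 <- switch(stat,
    mean = function(x) { x <- x[!is.na(x)]
      if (length(x)) mean(x) else NA_real_ },
    max = function(x) { x <- x[!is.na(x)]
      if (length(x)) max(x) else NA_real_ },
    majority = function(x) { x <- x[!is.na(x)]
      if (!length(x)) return(NA_real_)
      tb <- table(x)
      as.numeric(names(tb)[which.max(tb)]) })  # which.max: first = smallest

  out <- rep(NA_real_, nrow(units))
  n_hit <- 0L
  # fast path: units exactly one raster cell, aligned to the grid
  ctr <- unit_centroids(units)
  aligned <- units$size_m == cs &
    abs((units$x0 - raster$xmin) / cs - round((units$x0 - raster$xmin) / cs)) < 1e-9
  if (any(aligned)) {
    rc <- point_to_cell(raster, ctr[aligned, 1], ctr[aligned, 2])
    ok <- !is.na(rc[, 1])
    vals <- rep(NA_real_, sum(aligned))
    vals[ok] <- v[rc[ok, , drop = FALSE]]
    out[aligned] <- vals
    n_hit <- n_hit + sum(ok)
  }
  slow <- which(!aligned)
  for (i in slow) {
    # cell centers x_c = xmin + (c - 0.5) cs inside [x0, x0 + size):
    a <- (units$x0[i] - raster$xmin) / cs
    b <- a + units$size_m[i] / cs
    c1 <- as.integer(ceiling(a + 0.5 - 1e-9))
    c2 <- as.integer(ceiling(b + 0.5 - 1e-9)) - 1L
    # cell centers y_r = ymax - (r - 0.5) cs inside [y0, y0 + size):
    p <- (raster$ymax - units$y0[i] - units$size_m[i]) / cs
    q <- (raster$ymax - units$y0[i]) / cs
    r1 <- as.integer(floor(p + 0.5 + 1e-9)) + 1L
    r2 <- as.integer(floor(q + 0.5 + 1e-9))
    c1 <- max(1L, c1); c2 <- min(nc, c2); r1 <- max(1L, r1); r2 <- min(nr, r2)
    if (c2 < c1 || r2 < r1) next
    out[i] <- agg1(v[r1:r2, c1:c2])
    n_hit <- n_hit + 1L
  }
  if (all(is.na(out)))
    stop("raster does not overlap any decision unit", call. = FALSE)
  units[[name]] <- out
  units
}
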