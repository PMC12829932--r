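#' Create a feature set
#'
#' A minimal vector layer in a projected metric CRS: a list of geometries
#' (points, linestrings, or single-ring polygons) plus a per-feature
#' attribute table. Polygon rings need not be explicitly closed; they are
#' treated as closed between the last and first vertex and must not
#' self-intersect.
#'
#' @param geoms list of geometries; each is `list(type = "point"|"line"|"polygon",
#'   coords = <n x 2 numeric matrix>)`. A point has one row.
#' @param attrs data.frame of per-feature attributes (or `NULL`).
#' @param crs CRS identifier string.
#' @return An object of class `lucis_features`.
#' @export
features_create <- function(geoms = list(), attrs = NULL, crs = "EPSG:32734") {
  for (i in seq_along(geoms)) {
    g <- geoms[[i]]
    if (!g$type %in% c("point", "line", "polygon"))
      stop("unknown geometry type: ", g$type, call. = FALSE)
    if (!is.matrix(g$coords) || ncol(g$coords) != 2L)
      stop("geometry coords must be an n x 2 matrix", call. = FALSE)
    storage.mode(geoms[[i]]$coords) <- "double"
  }
  if (is.null(attrs)) attrs <- data.frame(row.names = seq_along(geoms))
  structure(list(geoms = geoms, attrs = attrs, crs = crs),
            class = "lucis_features")
}

#' @export
print.lucis_features <- function(x, ...) {
  types <- vapply(x$geoms, `[[`, "", "type")
  cat(sprintf("<lucis_features> %d features [%s]\n", length(x$geoms), x$crs))
  if (length(types)) print(table(types))
  invisible(x)
}

#' @export
length.lucis_features <- function(x) length(x$geoms)

#' Feature centroids
#'
#' Point coordinates for points; vertex mean for lines; area-weighted
#' centroid for polygons.
#'
#' @param fs a `lucis_features`.
#' @return n x 2 matrix of `(x, y)`.
#' @export
feature_centroids <- function(fs) {
  out <- t(vapply(fs$geoms, function(g) {
    xy <- g$coords
    if (g$type == "polygon") polygon_centroid(xy) else colMeans(xy)
  }, numeric(2)))
  colnames(out) <- c("x", "y")
  out
}

# Shoelace area of a (possibly unclosed) simple polygon ring, always >= 0.
polygon_area <- function(xy) {
  n <- nrow(xy)
  if (n < 3L) return(0)
  j <- c(2:n, 1L)
  abs(sum(xy[, 1] * xy[j, 2] - xy[j, 1] * xy[, 2])) / 2
}

polygon_centroid <- function(xy) {
  n <- nrow(xy)
  j <- c(2:n, 1L)
  cr <- xy[, 1] * xy[j, 2] - xy[j, 1] * xy[, 2]
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(xy))
  c(sum((xy[, 1] + xy[j, 1]) * cr) / (6 * a),
    sum((xy[, 2] + xy[j, 2]) * cr) / (6 * a))
}

#' Total area of all polygon features
#'
#' @param fs a `lucis_features`.
#' @return Area in square meters.
#' @export
features_area_m2 <- function(fs) {
  sum(vapply(fs$geoms, function(g)
    if (g$type == "polygon") polygon_area(g$coords) else 0, 0))
}

# Vectorized even-odd (ray casting) point-in-polygon test.
# px, py: point vectors; ring: vertex matrix. Boundary points count as inside
# for the top/left-ish crossing convention; exact-boundary behavior is not
# relied upon anywhere (features are jittered off cell edges).
points_in_ring <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- logical(length(px))
  xj <- ring[n, 1]; yj <- ring[n, 2]
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    xj <- xi; yj <- yi
  }
  inside
}

# Minimum distance from each point to a segment (ax,ay)-(bx,by), vectorized
# over points.
point_segment_dist <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  len2 <- dx * dx + dy * dy
  if (len2 == 0) return(sqrt((px - ax)^2 + (py - ay)^2))
  t <- ((px - ax) * dx + (py - ay) * dy) / len2
  t <- pmin(1, pmax(0, t))
  sqrt((px - (ax + t * dx))^2 + (py - (ay + t * dy))^2)
}

# Distance from points to one geometry; polygons measure 0 inside.
points_to_geom_dist <- function(px, py, g) {
  xy <- g$coords
  if (g$type == "point") {
    d <- sqrt((px - xy[1, 1])^2 + (py - xy[1, 2])^2)
    return(d)
  }
  n <- nrow(xy)
  segs <- if (g$type == "polygon") cbind(seq_len(n), c(2:n, 1L))
          else cbind(seq_len(n - 1L), 2:n)
  d <- rep(Inf, length(px))
  for (s in seq_len(nrow(segs))) {
    a <- xy[segs[s, 1], ]; b <- xy[segs[s, 2], ]
    d <- pmin(d, point_segment_dist(px, py, a[1], a[2], b[1], b[2]))
  }
  if (g$type == "polygon") d[points_in_ring(px, py, xy)] <- 0
  d
}

#' Distance from arbitrary points to the nearest feature
#'
#' Planar Euclidean distance in meters; points inside a polygon feature are
#' at distance zero.
#'
#' @param fs a non-empty `lucis_features`.
#' @param px,py point coordinate vectors.
#' @return Numeric vector of distances.
#' @export
points_to_features_dist <- function(fs, px, py) {
  if (length(fs$geoms) == 0L)
    stop("distance to an empty feature set is undefined", call. = FALSE)
  d <- rep(Inf, length(px))
  for (g in fs$geoms) d <- pmin(d, points_to_geom_dist(px, py, g))
  d
}

#' Write features as GeoJSON
#'
#' Coordinates are written in the projected CRS of the layer (a
#' non-standard but widely accepted use of GeoJSON for analysis
#' interchange); the CRS id is recorded as a foreign member.
#'
#' @param fs a `lucis_features`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_geojson <- function(fs, path) {
  feat <- lapply(seq_along(fs$geoms), function(i) {
    g <- fs$geoms[[i]]
    coords <- switch(g$type,
      point   = as.numeric(g$coords[1, ]),
      line    = unname(apply(g$coords, 1L, as.numeric, simplify = FALSE)),
      polygon = {
        ring <- g$coords
        if (!all(ring[1, ] == ring[nrow(ring), ]))
          ring <- rbind(ring, ring[1, , drop = FALSE])
        list(unname(apply(ring, 1L, as.numeric, simplify = FALSE)))
      })
    type <- switch(g$type, point = "Point", line = "LineString",
                   polygon = "Polygon")
    props <- if (ncol(fs$attrs)) as.list(fs$attrs[i, , drop = FALSE])
             else stats::setNames(list(), character())
    list(type = "Feature",
         geometry = list(type = type, coordinates = coords),
         properties = props)
  })
  obj <- list(type = "FeatureCollection", crs_id = fs$crs, features = feat)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

#' Read features from GeoJSON written by [write_geojson()]
#'
#' @param path file path.
#' @return A `lucis_features`.
#' @export
read_geojson <- function(path) {
  obj <- jsonlite::read_json(path)
  geoms <- list(); rows <- list()
  for (f in obj$features) {
    ge <- f$geometry
    cm <- switch(ge$type,
      Point = matrix(unlist(ge$coordinates), ncol = 2),
      LineString = do.call(rbind, lapply(ge$coordinates, unlist)),
      Polygon = {
        ring <- do.call(rbind, lapply(ge$coordinates[[1]], unlist))
        ring[-nrow(ring), , drop = FALSE]  # drop closing vertex
      },
      stop("unsupported GeoJSON type: ", ge$type, call. = FALSE))
    type <- switch(ge$type, Point = "point", LineString = "line",
                   Polygon = "polygon")
    geoms[[length(geoms) + 1L]] <- list(type = type, coords = cm)
    rows[[length(rows) + 1L]] <- f$properties
  }
  has_props <- length(rows) && length(rows[[1]])
  attrs <- if (has_props)
    do.call(rbind, lapply(rows, function(r) as.data.frame(r))) else NULL
  features_create(geoms, attrs,
                  crs = if (!is.null(obj$crs_id)) obj$crs_id else "EPSG:32734")
}
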