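#' Create a raster
#'
#' A minimal single-band raster in a projected metric CRS. Values are stored
#' as a numeric matrix whose first row is the northern edge of the grid
#' (row-major, origin at the upper-left corner). Cells are half-open: cell
#' (r, c) covers `[xmin + (c-1)*cs, xmin + c*cs)` in x and
#' `(ymax - r*cs, ymax - (r-1)*cs]` in y, so every point of the extent
#' belongs to exactly one cell. Missing data are `NA`; a `nodata` sentinel is
#' only used on file I/O.
#'
#' @param values numeric matrix (row 1 = north).
#' @param xmin,ymax coordinates of the upper-left corner in projected meters.
#' @param cell_size_m positive cell edge length in meters.
#' @param crs CRS identifier string (default the UTM zone used throughout
#'   the demo landscape).
#' @param categorical logical; `TRUE` for class-coded layers (controls legal
#'   resampling in [align_to_grid()]).
#' @return An object of class `lucis_raster`.
#' @export
raster_create <- function(values, xmin, ymax, cell_size_m,
                          crs = "EPSG:32734", categorical = FALSE) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cell_size_m) || length(cell_size_m) != 1L || cell_size_m <= 0)
    stop("cell_size_m must be a single positive number", call. = FALSE)
  structure(
    list(values = values, xmin = as.numeric(xmin), ymax = as.numeric(ymax),
         cell_size_m = as.numeric(cell_size_m), crs = crs,
         categorical = isTRUE(categorical)),
    class = "lucis_raster")
}

#' @export
print.lucis_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<lucis_raster> %d x %d cells @ %g m  [%s]%s\n",
              nrow(v), ncol(v), x$cell_size_m, x$crs,
              if (x$categorical) " categorical" else ""))
  cat(sprintf("  extent: x [%g, %g]  y [%g, %g]\n",
              x$xmin, x$xmin + ncol(v) * x$cell_size_m,
              x$ymax - nrow(v) * x$cell_size_m, x$ymax))
  fin <- v[is.finite(v)]
  if (length(fin))
    cat(sprintf("  values: min %.4g  mean %.4g  max %.4g  (%d NA)\n",
                min(fin), mean(fin), max(fin), sum(is.na(v))))
  invisible(x)
}

#' Raster extent
#'
#' @param r a `lucis_raster`.
#' @return Numeric vector `c(xmin, ymin, xmax, ymax)` in meters.
#' @export
raster_extent <- function(r) {
  cs <- r$cell_size_m
  c(xmin = r$xmin, ymin = r$ymax - nrow(r$values) * cs,
    xmax = r$xmin + ncol(r$values) * cs, ymax = r$ymax)
}

#' Coordinates of all cell centers
#'
#' @param r a `lucis_raster`.
#' @return A two-column matrix `(x, y)` in row-major order (matching
#'   `as.vector(t(r$values))` ordering is *not* used; ordering matches
#'   `as.vector(r$values)`, i.e. column-major like the values matrix).
#' @export
cell_centers <- function(r) {
  cs <- r$cell_size_m
  nr <- nrow(r$values); nc <- ncol(r$values)
  xs <- r$xmin + (seq_len(nc) - 0.5) * cs
  ys <- r$ymax - (seq_len(nr) - 0.5) * cs
  cbind(x = rep(xs, each = nr), y = rep(ys, times = nc))
}

# Map point coordinates to (row, col); points outside the grid get NA.
# Half-open convention: a point on the left/top edge of a cell belongs to it.
point_to_cell <- function(r, x, y) {
  cs <- r$cell_size_m
  col <- floor((x - r$xmin) / cs) + 1
  row <- floor((r$ymax - y) / cs) + 1
  # the top edge (y == ymax) belongs to row 1, per the half-open convention
  row[y == r$ymax] <- 1L
  bad <- col < 1 | col > ncol(r$values) | row < 1 | row > nrow(r$values)
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

same_grid <- function(a, b, tol = 1e-6) {
  isTRUE(all.equal(a$cell_size_m, b$cell_size_m, tolerance = tol)) &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymax - b$ymax) < tol &&
    all(dim(a$values) == dim(b$values))
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text interchange format readable by every GIS. `NA` cells are
#' written as the `nodata` sentinel.
#'
#' @param r a `lucis_raster`.
#' @param path output file path (conventionally `.asc`).
#' @param nodata sentinel written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(r, path, nodata = -9999) {
  v <- r$values
  v[is.na(v)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", r$xmin),
    sprintf("yllcorner %.10g", r$ymax - nrow(v) * r$cell_size_m),
    sprintf("cellsize %.10g", r$cell_size_m),
    sprintf("NODATA_value %g", nodata))
  body <- apply(v, 1L, function(row) paste(format(row, trim = TRUE,
                                                  digits = 15), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file path.
#' @param crs CRS identifier to attach (ASCII grids carry none).
#' @param categorical logical, see [raster_create()].
#' @return A `lucis_raster`.
#' @export
read_ascii_grid <- function(path, crs = "EPSG:32734", categorical = FALSE) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  vals <- lapply(lines[i:length(lines)],
                 function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  m <- do.call(rbind, vals)
  stopifnot(nrow(m) == hdr$nrows, ncol(m) == hdr$ncols)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  raster_create(m, xmin = hdr$xllcorner,
                ymax = hdr$yllcorner + hdr$nrows * hdr$cellsize,
                cell_size_m = hdr$cellsize, crs = crs,
                categorical = categorical)
}
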