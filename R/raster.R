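# A small matrix-backed raster on a geographic (EPSG:4326) lat-lon lattice,
# cell-centre registered, north-up, with plain-text ESRI ASCII grid I/O.
# Values are stored as a numeric matrix (rows north to south); NA is nodata.

#' Construct a lat-lon raster
#'
#' @param values Numeric matrix, rows ordered north to south, columns west
#'   to east; `NA` marks nodata cells.
#' @param xll,yll Longitude/latitude of the lower-left corner of the grid
#'   (cell edges, degrees).
#' @param res Cell size in degrees (square cells; 5 arc-minutes is 1/12).
#' @return A `pv_raster` object.
#' @export
pv_raster <- function(values, xll, yll, res) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (res <= 0) stop("res must be > 0", call. = FALSE)
  if (yll < -90 - 1e-9 || yll + nrow(values) * res > 90 + 1e-9) {
    stop("raster extends beyond [-90, 90] latitude", call. = FALSE)
  }
  structure(list(values = values, xll = xll, yll = yll, res = res,
                 crs = "EPSG:4326"),
            class = "pv_raster")
}

#' @export
print.pv_raster <- function(x, ...) {
  cat(sprintf(
    "<pv_raster %d x %d @ %.6g deg, origin (%.4g, %.4g), %d valid cells>\n",
    nrow(x$values), ncol(x$values), x$res, x$xll, x$yll,
    sum(!is.na(x$values))))
  invisible(x)
}

#' @export
dim.pv_raster <- function(x) dim(x$values)

#' @export
as.matrix.pv_raster <- function(x, ...) x$values

#' Latitudes / longitudes of cell centres
#'
#' @param r A `pv_raster`.
#' @return `raster_lats()`: vector of row-centre latitudes (north to
#'   south); `raster_lons()`: vector of column-centre longitudes.
#' @export
raster_lats <- function(r) {
  n <- nrow(r$values)
  r$yll + (seq(n, 1) - 0.5) * r$res
}

#' @rdname raster_lats
#' @export
raster_lons <- function(r) {
  r$xll + (seq_len(ncol(r$values)) - 0.5) * r$res
}

same_lattice <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$xll - b$xll) < tol && abs(a$yll - b$yll) < tol &&
    abs(a$res - b$res) < tol
}

.check_lattice <- function(rasters) {
  ref <- rasters[[1]]
  for (r in rasters[-1]) {
    if (!same_lattice(ref, r)) stop("rasters are not on a shared lattice",
                                    call. = FALSE)
  }
  invisible(ref)
}

#' Area of a lat-lon cell in hectares
#'
#' Spherical band area of a square `resolution`-degree cell centred at
#' `lat_center`, on a sphere of authalic radius 6371.0088 km:
#' `R^2 * dlambda * (sin(phi2) - sin(phi1))`. Symmetric about the equator
#' and strictly decreasing in absolute latitude.
#'
#' @param lat_center Cell-centre latitude in degrees, within \[-90, 90\].
#' @param resolution Cell size in degrees (default 5 arc-minutes).
#' @return Cell area in hectares.
#' @export
cell_area <- function(lat_center, resolution = 1 / 12) {
  if (any(abs(lat_center) > 90)) stop("latitude out of range", call. = FALSE)
  if (resolution <= 0) stop("resolution must be > 0", call. = FALSE)
  R <- 6371008.8 # authalic radius, metres
  half <- resolution / 2
  phi1 <- pmax(-90, lat_center - half) * pi / 180
  phi2 <- pmin(90, lat_center + half) * pi / 180
  dlambda <- resolution * pi / 180
  m2 <- R^2 * dlambda * (sin(phi2) - sin(phi1))
  m2 / 1e4
}

#' Write / read a raster as an ESRI ASCII grid
#'
#' Plain-text interchange format readable by GDAL and desktop GIS.
#' Cell-centre registration is preserved through the `xllcorner` /
#' `yllcorner` header; nodata cells are written as the `NODATA_value`.
#'
#' @param r A `pv_raster`.
#' @param path Output path (conventionally `.asc`).
#' @param nodata Sentinel written for `NA` cells.
#' @return `write_ascii_grid()`: `path` invisibly; `read_ascii_grid()`:
#'   a `pv_raster`.
#' @export
write_ascii_grid <- function(r, path, nodata = -9999) {
  stopifnot(inherits(r, "pv_raster"))
  v <- r$values
  v[is.na(v)] <- nodata
  hdr <- c(
    paste("ncols", ncol(v)),
    paste("nrows", nrow(v)),
    paste("xllcorner", format(r$xll, digits = 15)),
    paste("yllcorner", format(r$yll, digits = 15)),
    paste("cellsize", format(r$res, digits = 15)),
    paste("NODATA_value", nodata))
  body <- apply(v, 1, function(row) paste(format(row, digits = 15,
                                                 trim = TRUE, scientific = FALSE),
                                          collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  kv <- strsplit(trimws(hdr), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1))
  vals <- as.numeric(vapply(kv, `[`, "", 2))
  names(vals) <- keys
  body <- lines[-(1:6)]
  v <- do.call(rbind, lapply(body, function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  v[v == vals[["nodata_value"]]] <- NA_real_
  pv_raster(v, vals[["xllcorner"]], vals[["yllcorner"]], vals[["cellsize"]])
}

#' Pearson correlation between two rasters
#'
#' Computed over cells where both layers are defined; invariant under
#' affine rescaling of either layer.
#'
#' @param a,b `pv_raster`s on the same lattice.
#' @return List with `r`, `n` and `flag` (`"ok"` or `"zero_variance"`).
#' @export
raster_correlation <- function(a, b) {
  .check_lattice(list(a, b))
  ok <- !is.na(a$values) & !is.na(b$values)
  if (sum(ok) < 3) stop("fewer than 3 jointly valid cells", call. = FALSE)
  x <- a$values[ok]; y <- b$values[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, n = sum(ok), flag = "zero_variance"))
  }
  list(r = stats::cor(x, y), n = sum(ok), flag = "ok")
}
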