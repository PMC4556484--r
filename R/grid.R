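#' Equal-area grid specification
#'
#' Defines the raster geometry every field in the pipeline lives on: a regular
#' lattice of square cells in a Lambert Azimuthal Equal Area (LAEA) projection
#' centred on (`center_lon`, `center_lat`). Because the projection is
#' equal-area, every cell covers `cell_size^2` square kilometres, so areas can
#' be read off the mask by counting cells. Cells are indexed `(row, col)` with
#' row 1 the northernmost row; cell centres are used throughout (cell-centre
#' registration, 1-based indices).
#'
#' @param n_rows,n_cols Grid dimensions (cells).
#' @param cell_size Cell edge length in km.
#' @param center_lon,center_lat Projection centre in degrees.
#' @param origin_x,origin_y Projected coordinates (km) of the centre of cell
#'   `(1, 1)`. Default places the grid symmetrically about the projection
#'   centre.
#' @return A `grid_spec` object.
#' @export
grid_spec <- function(n_rows, n_cols, cell_size,
                      center_lon = 0, center_lat = 0,
                      origin_x = NULL, origin_y = NULL) {
  stopifnot(n_rows >= 1, n_cols >= 1, cell_size > 0)
  origin_x <- origin_x %||% (-(n_cols - 1) / 2 * cell_size)
  origin_y <- origin_y %||% ((n_rows - 1) / 2 * cell_size)
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         cell_size = cell_size, center_lon = center_lon,
         center_lat = center_lat, origin_x = origin_x, origin_y = origin_y),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells, %.6g km cells, LAEA centre (%.6g, %.6g)\n",
              x$n_rows, x$n_cols, x$cell_size, x$center_lon, x$center_lat))
  invisible(x)
}

# authalic Earth radius, km
.R_EARTH <- 6371.0088

#' Lambert Azimuthal Equal Area forward projection (spherical)
#'
#' @param lon,lat Coordinates in degrees.
#' @param spec A [grid_spec()] giving the projection centre.
#' @return Tibble with projected `x`, `y` in km.
#' @export
laea_forward <- function(lon, lat, spec) {
  lam0 <- spec$center_lon * pi / 180
  phi1 <- spec$center_lat * pi / 180
  lam <- lon * pi / 180
  phi <- lat * pi / 180
  denom <- 1 + sin(phi1) * sin(phi) + cos(phi1) * cos(phi) * cos(lam - lam0)
  if (any(denom < 1e-12, na.rm = TRUE))
    abort("point antipodal to the projection centre cannot be projected")
  k <- sqrt(2 / denom)
  tibble(x = .R_EARTH * k * cos(phi) * sin(lam - lam0),
         y = .R_EARTH * k * (cos(phi1) * sin(phi) -
                               sin(phi1) * cos(phi) * cos(lam - lam0)))
}

#' Inverse Lambert Azimuthal Equal Area projection (spherical)
#'
#' @param x,y Projected coordinates in km.
#' @inheritParams laea_forward
#' @return Tibble with `lon`, `lat` in degrees.
#' @export
laea_inverse <- function(x, y, spec) {
  lam0 <- spec$center_lon * pi / 180
  phi1 <- spec$center_lat * pi / 180
  rho <- sqrt(x^2 + y^2)
  cc <- 2 * asin(pmin(1, rho / (2 * .R_EARTH)))
  phi <- ifelse(rho < 1e-12, phi1,
                asin(cos(cc) * sin(phi1) + y * sin(cc) * cos(phi1) / rho))
  lam <- ifelse(rho < 1e-12, lam0,
                lam0 + atan2(x * sin(cc),
                             rho * cos(phi1) * cos(cc) - y * sin(phi1) * sin(cc)))
  tibble(lon = lam * 180 / pi, lat = phi * 180 / pi)
}

#' Map geographic coordinates to grid cells
#'
#' Projects lon/lat forward and snaps to the nearest cell centre. The
#' round-trip `cell -> lonlat -> cell` is the identity, and any point within
#' half a cell of a centre snaps to that centre.
#'
#' @inheritParams laea_forward
#' @param strict Error when a point falls outside the raster extent
#'   (default); otherwise such points get `NA` indices.
#' @return Tibble with `row`, `col` (1-based) and the projected `x`, `y`.
#' @export
lonlat_to_cell <- function(lon, lat, spec, strict = TRUE) {
  pr <- laea_forward(lon, lat, spec)
  col <- as.integer(round((pr$x - spec$origin_x) / spec$cell_size)) + 1L
  row <- as.integer(round((spec$origin_y - pr$y) / spec$cell_size)) + 1L
  bad <- is.na(row) | is.na(col) |
    row < 1L | row > spec$n_rows | col < 1L | col > spec$n_cols
  if (any(bad)) {
    if (strict)
      abort(sprintf("%d point(s) outside the raster extent", sum(bad)))
    row[bad] <- NA_integer_
    col[bad] <- NA_integer_
  }
  tibble(row = row, col = col, x = pr$x, y = pr$y)
}

#' Projected coordinates of cell centres
#'
#' @param row,col Cell indices (1-based).
#' @inheritParams laea_forward
#' @return Tibble with `x`, `y` in km.
#' @export
cell_to_xy <- function(row, col, spec) {
  tibble(x = spec$origin_x + (col - 1) * spec$cell_size,
         y = spec$origin_y - (row - 1) * spec$cell_size)
}

#' Geographic coordinates of cell centres
#'
#' @inheritParams cell_to_xy
#' @return Tibble with `lon`, `lat` in degrees.
#' @export
cell_to_lonlat <- function(row, col, spec) {
  xy <- cell_to_xy(row, col, spec)
  laea_inverse(xy$x, xy$y, spec)
}

#' Read and write single-band rasters as ESRI ASCII grids
#'
#' Plain-text raster interchange. `NA` is written as the nodata value. The
#' header records the extent and cell size; the projection centre is not part
#' of the format and must be supplied when rebuilding a [grid_spec()].
#'
#' @param mat Numeric matrix (row 1 = northernmost row).
#' @param path File path.
#' @param spec A [grid_spec()] describing the grid geometry.
#' @param nodata Value standing for `NA` on disk.
#' @return `write_ascii_grid()` returns `path` invisibly; `read_ascii_grid()`
#'   returns a list with `data` (matrix) and `header` (named list).
#' @export
write_ascii_grid <- function(mat, path, spec, nodata = -9999) {
  stopifnot(nrow(mat) == spec$n_rows, ncol(mat) == spec$n_cols)
  hdr <- c(
    sprintf("ncols %d", spec$n_cols),
    sprintf("nrows %d", spec$n_rows),
    sprintf("xllcorner %.10g", spec$origin_x - spec$cell_size / 2),
    sprintf("yllcorner %.10g",
            spec$origin_y - (spec$n_rows - 1) * spec$cell_size - spec$cell_size / 2),
    sprintf("cellsize %.10g", spec$cell_size),
    sprintf("NODATA_value %.10g", nodata))
  m <- mat
  m[is.na(m)] <- nodata
  body <- apply(m, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  required <- c("ncols", "nrows", "cellsize")
  if (!all(required %in% names(hdr)))
    abort("not an ESRI ASCII grid: header incomplete")
  body <- lines[i:length(lines)]
  vals <- scan(text = body, quiet = TRUE)
  if (length(vals) != hdr$nrows * hdr$ncols)
    abort("ASCII grid body does not match declared dimensions")
  mat <- matrix(vals, nrow = hdr$nrows, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) mat[mat == hdr$nodata_value] <- NA
  list(data = mat, header = hdr)
}
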