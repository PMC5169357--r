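# Mean Earth radius (km) used by every spherical computation in the package.
EARTH_RADIUS_KM <- 6371.0088

RESCALED_UNITS <- "0-1 rescaled"

#' Define a raster grid
#'
#' A grid is the shared lattice every surface in an analysis lives on:
#' regular cells in geographic (lon/lat) coordinates, cell-centre
#' registered, row-major from the upper-left corner. The validity mask
#' marks cells inside the study region that are not permanent water;
#' everything downstream treats invalid cells as NoData.
#'
#' @param n_rows,n_cols Grid dimensions (each >= 1).
#' @param cell_size Cell edge length in decimal degrees. The default
#'   0.0833 degrees (~10 km at the equator) matches the resolution at
#'   which subregional road screening is typically run.
#' @param origin Numeric `c(lon, lat)` of the upper-left *corner* of the
#'   grid. Latitude decreases down the rows.
#' @param valid_mask Logical matrix (`n_rows` x `n_cols`); `FALSE` marks
#'   water / out-of-region cells. Default: all valid.
#' @return An object of class `rs_grid`.
#' @examples
#' g <- rs_grid(20, 20)
#' g
#' @export
rs_grid <- function(n_rows, n_cols, cell_size = 0.0833, origin = c(98, 25),
                    valid_mask = NULL) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 1L || n_cols < 1L)
    stop("grid must have at least one row and one column")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a single positive number (degrees)")
  if (length(origin) != 2L || !is.numeric(origin))
    stop("origin must be c(lon, lat) of the upper-left corner")
  if (is.null(valid_mask)) {
    valid_mask <- matrix(TRUE, n_rows, n_cols)
  } else {
    valid_mask <- as.matrix(valid_mask)
    if (!is.logical(valid_mask)) storage.mode(valid_mask) <- "logical"
    if (nrow(valid_mask) != n_rows || ncol(valid_mask) != n_cols)
      stop("valid_mask must be an ", n_rows, " x ", n_cols, " logical matrix")
  }
  if (!any(valid_mask)) stop("grid must contain at least one valid cell")
  structure(
    list(n_rows = n_rows, n_cols = n_cols, cell_size = cell_size,
         origin = as.numeric(origin), valid_mask = valid_mask),
    class = "rs_grid")
}

#' @export
print.rs_grid <- function(x, ...) {
  cat(sprintf("<rs_grid> %d x %d cells, %.6g deg, UL corner (%.6g, %.6g)\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin[1], x$origin[2]))
  cat(sprintf("  valid cells: %d / %d\n", sum(x$valid_mask),
              x$n_rows * x$n_cols))
  invisible(x)
}

#' Cell-centre coordinates of a grid
#'
#' @param grid An `rs_grid`.
#' @return List with `lon` (length `n_cols`), `lat` (length `n_rows`), and
#'   full matrices `lon_mat`, `lat_mat`.
#' @export
cell_centres <- function(grid) {
  lon <- grid$origin[1] + (seq_len(grid$n_cols) - 0.5) * grid$cell_size
  lat <- grid$origin[2] - (seq_len(grid$n_rows) - 0.5) * grid$cell_size
  list(lon = lon, lat = lat,
       lon_mat = matrix(lon, grid$n_rows, grid$n_cols, byrow = TRUE),
       lat_mat = matrix(lat, grid$n_rows, grid$n_cols))
}

same_grid <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$cell_size - b$cell_size) <= tol &&
    all(abs(a$origin - b$origin) <= tol) &&
    identical(a$valid_mask, b$valid_mask)
}

stop_if_grid_mismatch <- function(a, b, what = "surfaces") {
  if (!same_grid(a, b))
    stop("grid mismatch: ", what, " must share one grid")
  invisible(TRUE)
}

#' Create a surface on a grid
#'
#' A surface carries one value per cell plus a free-text units tag.
#' Cells outside the grid's validity mask are always NoData (`NA`);
#' valid cells may also be NoData (e.g. a layer with local gaps).
#'
#' @param grid An `rs_grid`.
#' @param values Numeric matrix (`n_rows` x `n_cols`) or vector of length
#'   `n_rows * n_cols` (column-major).
#' @param units Units tag, e.g. `"min"`, `"t/ha"`, `"GJ/cell/y"`,
#'   `"0-1 rescaled"`.
#' @return An object of class `rs_surface`.
#' @export
rs_surface <- function(grid, values, units = "") {
  stopifnot(inherits(grid, "rs_grid"))
  if (!is.matrix(values))
    values <- matrix(as.numeric(values), grid$n_rows, grid$n_cols)
  if (nrow(values) != grid$n_rows || ncol(values) != grid$n_cols)
    stop("values must be ", grid$n_rows, " x ", grid$n_cols)
  storage.mode(values) <- "double"
  values[!grid$valid_mask] <- NA_real_
  if (identical(units, RESCALED_UNITS)) {
    v <- values[!is.na(values)]
    if (length(v) && (min(v) < 0 || max(v) > 1))
      stop("a surface tagged '", RESCALED_UNITS, "' must lie in [0, 1]")
  }
  structure(list(grid = grid, values = values, units = units),
            class = "rs_surface")
}

#' @export
print.rs_surface <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<rs_surface> %d x %d [%s], %d data cells",
              x$grid$n_rows, x$grid$n_cols, x$units, length(v)))
  if (length(v))
    cat(sprintf(", range [%.4g, %.4g]", min(v), max(v)))
  cat("\n")
  invisible(x)
}

#' @export
as.matrix.rs_surface <- function(x, ...) x$values

n_data_cells <- function(surface) sum(!is.na(surface$values))

#' Equal-area decile rescaling of a surface
#'
#' Maps a surface onto a 0-1 scale so that each tenth of the data cells
#' occupies one decile interval: the empirical rank transform
#' `(rank - 0.5) / n` with midranks for ties. Because the transform is
#' rank-based it is invariant to any strictly increasing change of units
#' and robust to outlying values, which is why every layer is passed
#' through it before layers are multiplied or averaged.
#'
#' An all-constant surface maps every cell to 0.5 (one big tie group);
#' this is documented behaviour, not an error. NoData cells stay NoData.
#'
#' @param surface An `rs_surface` with at least 10 data cells.
#' @return An `rs_surface` with units `"0-1 rescaled"`.
#' @export
equal_area_rescale <- function(surface) {
  stopifnot(inherits(surface, "rs_surface"))
  n <- n_data_cells(surface)
  if (n < 10L)
    stop("equal_area_rescale: need at least 10 data cells, have ", n)
  rs_surface(surface$grid, rescale01(surface$values), units = RESCALED_UNITS)
}

# rank transform on a matrix with NAs; ties get midranks
rescale01 <- function(values) {
  ok <- !is.na(values)
  out <- values
  out[ok] <- (rank(values[ok]) - 0.5) / sum(ok)
  out
}

#' Mask a surface with a grid's validity mask
#'
#' Sets cells that are invalid in `grid` (water, outside the study
#' region) to NoData; valid cells keep their values. The returned
#' surface is registered on `grid`.
#'
#' @param surface An `rs_surface` whose dimensions match `grid`.
#' @param grid An `rs_grid`.
#' @return An `rs_surface` on `grid`.
#' @export
apply_mask <- function(surface, grid) {
  stopifnot(inherits(surface, "rs_surface"), inherits(grid, "rs_grid"))
  if (surface$grid$n_rows != grid$n_rows || surface$grid$n_cols != grid$n_cols)
    stop("shape error: surface is ", surface$grid$n_rows, " x ",
         surface$grid$n_cols, " but grid is ", grid$n_rows, " x ", grid$n_cols)
  rs_surface(grid, surface$values, units = surface$units)
}

#' Geodesic cell areas of a grid
#'
#' Per-cell areas in km2 on a sphere of radius 6371.0088 km, from the
#' exact spherical band formula
#' `R^2 * dlon * (sin(lat_top) - sin(lat_bottom))`: every cell in a row
#' has the same area, and areas shrink towards the poles. Cell areas feed
#' proportional range size (cell area over a species' global range area),
#' carbon totals, and road density (km per km2).
#'
#' @param grid An `rs_grid` whose cell centres satisfy `|lat| < 90`.
#' @return An object of class `rs_cell_areas` with an `area` matrix (km2),
#'   defined for all cells including invalid ones.
#' @export
cell_areas <- function(grid) {
  stopifnot(inherits(grid, "rs_grid"))
  cc <- cell_centres(grid)
  if (any(abs(cc$lat) >= 90))
    stop("grid rows must have cell-centre |latitude| < 90")
  lat_top <- grid$origin[2] - (seq_len(grid$n_rows) - 1) * grid$cell_size
  lat_bot <- lat_top - grid$cell_size
  dlon <- grid$cell_size * pi / 180
  row_area <- EARTH_RADIUS_KM^2 * dlon *
    (sin(lat_top * pi / 180) - sin(lat_bot * pi / 180))
  structure(
    list(grid = grid,
         area = matrix(row_area, grid$n_rows, grid$n_cols)),
    class = "rs_cell_areas")
}

#' @export
print.rs_cell_areas <- function(x, ...) {
  cat(sprintf("<rs_cell_areas> %d x %d, %.4g - %.4g km2 per cell\n",
              x$grid$n_rows, x$grid$n_cols, min(x$area), max(x$area)))
  invisible(x)
}
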