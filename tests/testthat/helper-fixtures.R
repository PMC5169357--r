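# Small builders used across test files.

tiny_grid <- function(nr = 10, nc = 10, cell_size = 0.0833,
                      origin = c(100, 15), mask = NULL) {
  rs_grid(nr, nc, cell_size, origin, mask)
}

# surface from a vector (column-major) or matrix on a fresh grid
surf <- function(values, grid = NULL, units = "", nr = NULL, nc = NULL) {
  if (is.matrix(values)) { nr <- nrow(values); nc <- ncol(values) }
  if (is.null(grid)) grid <- tiny_grid(nr, nc)
  rs_surface(grid, values, units)
}

# uniform random 0-1-rescaled surface
random_rescaled <- function(grid) {
  equal_area_rescale(rs_surface(grid, matrix(runif(grid$n_rows * grid$n_cols),
                                             grid$n_rows), units = "x"))
}

small_params <- function(seed = 1, ...) {
  landscape_params(n_rows = 30, n_cols = 30, seed = seed,
                   n_species = c(mammal = 5, bird = 5, amphibian = 5),
                   n_cities = 3, n_crops = 3, n_ecoregions = 4,
                   n_proposals = 3, ...)
}

# an axis-aligned rectangle polygon (lon/lat)
rect_poly <- function(x0, y0, x1, y1) {
  cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
}

# area of one cell of a grid at row i, in km2, via the package formula
cell_area_at <- function(grid, i) cell_areas(grid)$area[i, 1]
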