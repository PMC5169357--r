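#' Define a crop layer
#'
#' One crop's contribution to the production gap: a yield-gap surface
#' (difference between attainable and current yield, t/ha/y), a harvested
#' area surface (ha per cell), and an energy content (GJ/t) used to put
#' all crops on a common food-energy scale.
#'
#' @param name Crop name.
#' @param yield_gap `rs_surface`, t/ha/y, non-negative.
#' @param harvested_area `rs_surface`, ha per cell, non-negative.
#' @param energy_content GJ per tonne, positive.
#' @return An object of class `rs_crop`.
#' @export
rs_crop <- function(name, yield_gap, harvested_area, energy_content) {
  stopifnot(inherits(yield_gap, "rs_surface"),
            inherits(harvested_area, "rs_surface"))
  stop_if_grid_mismatch(yield_gap$grid, harvested_area$grid,
                        paste0("crop '", name, "' layers"))
  if (any(yield_gap$values < 0, na.rm = TRUE))
    stop("validation error: crop '", name, "' has negative yield gaps")
  if (any(harvested_area$values < 0, na.rm = TRUE))
    stop("validation error: crop '", name, "' has negative harvested areas")
  if (!is.numeric(energy_content) || length(energy_content) != 1L ||
      energy_content <= 0)
    stop("validation error: energy_content must be a positive scalar (GJ/t)")
  structure(list(name = as.character(name), yield_gap = yield_gap,
                 harvested_area = harvested_area,
                 energy_content = as.numeric(energy_content)),
            class = "rs_crop")
}

#' Production gap surface
#'
#' The extra food energy each cell could produce without cropland
#' expansion: for each crop, yield gap (t/ha/y) times current harvested
#' area (ha), converted to energy (GJ/t) and summed over crops. Cells with
#' no cropland get 0 (they genuinely have no closable gap), not NoData.
#' A crop surface that is NoData on a valid cell contributes 0 there.
#'
#' @param crops List of [rs_crop] layers on `grid`.
#' @param grid An `rs_grid`.
#' @param energy If `FALSE`, skip the energy conversion and return
#'   tonnes/cell/y instead of GJ/cell/y.
#' @return `rs_surface` with units `"GJ/cell/y"` (or `"t/cell/y"`).
#' @export
production_gap <- function(crops, grid, energy = TRUE) {
  stopifnot(inherits(grid, "rs_grid"))
  if (!length(crops)) stop("need at least one crop layer")
  total <- matrix(0, grid$n_rows, grid$n_cols)
  for (cr in crops) {
    stopifnot(inherits(cr, "rs_crop"))
    stop_if_grid_mismatch(cr$yield_gap$grid, grid,
                          paste0("crop '", cr$name, "' and target grid"))
    gap <- cr$yield_gap$values
    area <- cr$harvested_area$values
    gap[is.na(gap)] <- 0
    area[is.na(area)] <- 0
    e <- if (energy) cr$energy_content else 1
    total <- total + gap * area * e
  }
  rs_surface(grid, total, units = if (energy) "GJ/cell/y" else "t/cell/y")
}

# shared benefit pipeline: rescale each factor, multiply, optionally
# rescale the product
benefit_pipeline <- function(weight, travel_time, final_rescale) {
  stop_if_grid_mismatch(weight$grid, travel_time$grid,
                        "benefit factor and travel time")
  rw <- equal_area_rescale(weight)
  rt <- equal_area_rescale(travel_time)
  prod <- rs_surface(weight$grid, rw$values * rt$values,
                     units = "product of rescaled factors")
  if (final_rescale) equal_area_rescale(prod) else prod
}

#' Aggregate food-production benefit surface
#'
#' The potential food-production benefit of better roads: the production
#' gap weighted by isolation. Both factors are first put on the 0-1
#' equal-area decile scale (so neither units nor outliers dominate), then
#' multiplied, and by default the product is rescaled once more so the
#' aggregate is itself an equal-area decile surface. Cells that are both
#' remote and have large closable gaps score highest.
#'
#' @param prod_gap Production-gap `rs_surface` (see [production_gap]).
#' @param travel_time Travel time to the nearest city (minutes),
#'   `rs_surface` on the same grid.
#' @param final_rescale Rescale the product again (default `TRUE`).
#' @return `rs_surface`, `"0-1 rescaled"` when `final_rescale = TRUE`.
#' @export
benefit_surface <- function(prod_gap, travel_time, final_rescale = TRUE) {
  benefit_pipeline(prod_gap, travel_time, final_rescale)
}

#' Population-based benefit surface
#'
#' Sensitivity variant of [benefit_surface]: replaces the production gap
#' with human population density, giving a measure of how many people
#' might benefit from improved access rather than how much extra food
#' could be grown. Same rescale-multiply-rescale pipeline.
#'
#' @param population Population density `rs_surface` (persons/km2).
#' @param travel_time Travel-time `rs_surface` (minutes), same grid.
#' @param final_rescale Rescale the product again (default `TRUE`).
#' @return `rs_surface`.
#' @export
population_benefit <- function(population, travel_time, final_rescale = TRUE) {
  benefit_pipeline(population, travel_time, final_rescale)
}
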