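#' Define a species range
#'
#' A species' distribution as one or more polygons in lon/lat, with the
#' vertebrate class it belongs to and its global range area. The global
#' area is the denominator of proportional range size (cell area over
#' global range area), so a small-ranged endemic contributes far more to
#' a cell's importance than a widespread species.
#'
#' @param species_id Identifier.
#' @param v_class One of `"mammal"`, `"bird"`, `"amphibian"`.
#' @param geometry A two-column lon/lat matrix, or a list of such
#'   matrices (multi-polygon). Rings need not be closed.
#' @param global_range_area Total range area in km2, > 0.
#' @return An object of class `rs_species_range`.
#' @export
rs_species_range <- function(species_id, v_class, geometry, global_range_area) {
  v_class <- match.arg(v_class, c("mammal", "bird", "amphibian"))
  if (is.matrix(geometry)) geometry <- list(geometry)
  if (!length(geometry) || !all(vapply(geometry, function(p)
    is.matrix(p) && ncol(p) == 2 && nrow(p) >= 3, logical(1))))
    stop("geometry must be one or more lon/lat matrices with >= 3 vertices")
  if (!is.numeric(global_range_area) || length(global_range_area) != 1L ||
      global_range_area <= 0)
    stop("validation error: global_range_area must be > 0")
  structure(list(species_id = as.character(species_id), v_class = v_class,
                 geometry = geometry,
                 global_range_area = as.numeric(global_range_area)),
            class = "rs_species_range")
}

VERT_CLASSES <- c("mammal", "bird", "amphibian")

# raw (un-rescaled) importance for one class:
# sum over species present of cell_area / global_range_area, times cover
vertebrate_raw_class <- function(ranges, natural_cover, areas) {
  grid <- natural_cover$grid
  cc <- cell_centres(grid)
  cs <- grid$cell_size
  raw <- matrix(0, grid$n_rows, grid$n_cols)
  # cell rectangles, column-major over the matrix
  x0 <- rep(cc$lon - cs / 2, each = grid$n_rows)
  x1 <- rep(cc$lon + cs / 2, each = grid$n_rows)
  y0 <- rep(cc$lat - cs / 2, times = grid$n_cols)
  y1 <- rep(cc$lat + cs / 2, times = grid$n_cols)
  for (sp in ranges) {
    present <- logical(length(x0))
    for (poly in sp$geometry)
      present <- present | rect_polygon_intersects(x0, y0, x1, y1, poly)
    raw <- raw + matrix(present, grid$n_rows, grid$n_cols) *
      (areas$area / sp$global_range_area)
  }
  raw * natural_cover$values
}

#' Terrestrial-vertebrate importance surface
#'
#' For each vertebrate class, each cell accumulates the proportional
#' range size (geodesic cell area divided by global range area) of every
#' species whose range intersects the cell, weighted by the proportion of
#' the cell still under natural vegetation. Class totals are rescaled to
#' equal-area deciles and the output is the mean across the classes
#' supplied. Presence is any overlap between the range polygon and the
#' cell square.
#'
#' @param ranges List of [rs_species_range] (any mix of classes; a class
#'   with no species is skipped with a warning).
#' @param natural_cover `rs_surface`, proportion 0-1.
#' @param areas [cell_areas] of the same grid.
#' @param rescale_output Rescale the across-class mean once more
#'   (default `FALSE`: the mean of rescaled class layers is returned as
#'   is, and the cost aggregation step handles the final rescale).
#' @return `rs_surface`; attribute `"class_surfaces"` holds the per-class
#'   rescaled layers and `"raw_class_surfaces"` the un-rescaled scores.
#' @export
vertebrate_importance <- function(ranges, natural_cover, areas,
                                  rescale_output = FALSE) {
  stopifnot(inherits(natural_cover, "rs_surface"),
            inherits(areas, "rs_cell_areas"))
  stop_if_grid_mismatch(natural_cover$grid, areas$grid)
  if (!length(ranges)) stop("need at least one species range")
  by_class <- split(ranges, vapply(ranges, `[[`, "", "v_class"))
  class_surf <- list(); raw_surf <- list()
  for (cl in VERT_CLASSES) {
    if (is.null(by_class[[cl]])) {
      warning("no ", cl, " ranges supplied; class skipped")
      next
    }
    raw <- vertebrate_raw_class(by_class[[cl]], natural_cover, areas)
    raw_surf[[cl]] <- rs_surface(natural_cover$grid, raw, "sum 1/range x cover")
    class_surf[[cl]] <- equal_area_rescale(raw_surf[[cl]])
  }
  vals <- Reduce(`+`, lapply(class_surf, `[[`, "values")) / length(class_surf)
  out <- rs_surface(natural_cover$grid, vals, units = RESCALED_UNITS)
  if (rescale_output) out <- equal_area_rescale(out)
  attr(out, "class_surfaces") <- class_surf
  attr(out, "raw_class_surfaces") <- raw_surf
  out
}

#' Carbon-loss cost surface
#'
#' The carbon a cell would lose if its remaining natural vegetation were
#' converted to agriculture (largely rice in the region this framework
#' was designed for): all biomass carbon is lost, while soil carbon in
#' the upper 30 cm gains 10% under paddy management. The per-hectare net
#' loss is floored at zero (a conversion cost cannot be negative here),
#' multiplied by the natural-cover proportion and the cell area, and
#' rescaled to equal-area deciles.
#'
#' @param biomass Above+below-ground biomass carbon `rs_surface` (t/ha).
#' @param soil30 Soil carbon in the top 30 cm, `rs_surface` (t/ha).
#' @param natural_cover `rs_surface`, proportion 0-1.
#' @param areas [cell_areas] of the same grid.
#' @return `rs_surface` `"0-1 rescaled"`; attribute `"raw"` holds the
#'   un-rescaled per-cell carbon loss (tonnes).
#' @export
carbon_cost <- function(biomass, soil30, natural_cover, areas) {
  for (s in list(soil30, natural_cover))
    stop_if_grid_mismatch(biomass$grid, s$grid)
  stop_if_grid_mismatch(biomass$grid, areas$grid)
  if (any(biomass$values < 0, na.rm = TRUE) ||
      any(soil30$values < 0, na.rm = TRUE))
    stop("validation error: carbon stocks must be non-negative")
  net_per_ha <- pmax(biomass$values - 0.10 * soil30$values, 0)
  raw <- net_per_ha * natural_cover$values * (areas$area * 100)  # km2 -> ha
  out <- equal_area_rescale(rs_surface(biomass$grid, raw, "t C/cell"))
  attr(out, "raw") <- rs_surface(biomass$grid, raw, "t C/cell")
  out
}

#' Local climate-regulation cost surface
#'
#' How much removing a cell's remaining vegetation would alter local
#' climate, from per-ecoregion heat (HRI, deg C) and moisture (MRI, mm/d)
#' regulation indices: each index is assigned to cells by ecoregion,
#' rescaled to equal-area deciles, multiplied by the natural-cover
#' proportion, and the two are averaged; the mean is rescaled once more
#' so the component enters the cost aggregate on the decile scale.
#'
#' @param ecoregion_id Integer-valued `rs_surface` of ecoregion membership.
#' @param indices Data frame with columns `ecoregion_id`, `hri`, `mri`
#'   (one row per ecoregion appearing in the surface).
#' @param natural_cover `rs_surface`, proportion 0-1.
#' @return `rs_surface` `"0-1 rescaled"`.
#' @export
climate_cost <- function(ecoregion_id, indices, natural_cover) {
  stop_if_grid_mismatch(ecoregion_id$grid, natural_cover$grid)
  stopifnot(all(c("ecoregion_id", "hri", "mri") %in% names(indices)))
  ids <- ecoregion_id$values
  present <- unique(ids[!is.na(ids)])
  missing <- setdiff(present, indices$ecoregion_id)
  if (length(missing))
    stop("validation error: no indices for ecoregion id(s) ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(indices$ecoregion_id))
    stop("validation error: duplicated ecoregion ids in indices table")
  lookup <- function(col) {
    v <- indices[[col]][match(ids, indices$ecoregion_id)]
    matrix(v, nrow(ids), ncol(ids))
  }
  per_index <- lapply(c("hri", "mri"), function(col)
    rescale01(lookup(col)) * natural_cover$values)
  mean_val <- (per_index[[1]] + per_index[[2]]) / 2
  equal_area_rescale(rs_surface(ecoregion_id$grid, mean_val,
                                "mean of cover-weighted indices"))
}

#' Aggregate environmental-cost surface
#'
#' Combines the 0-1 component cost layers (vertebrates, carbon, climate
#' regulation) into one surface: the per-cell mean by default, or the
#' per-cell maximum as a sensitivity variant, rescaled to equal-area
#' deciles.
#'
#' @param layers List of `rs_surface`s, each already on the 0-1 scale and
#'   sharing one grid.
#' @param rule `"mean"` (default) or `"max"`.
#' @param final_rescale Rescale the combined layer (default `TRUE`).
#' @return `rs_surface` `"0-1 rescaled"`.
#' @export
aggregate_cost <- function(layers, rule = c("mean", "max"),
                           final_rescale = TRUE) {
  rule <- match.arg(rule)
  if (!length(layers)) stop("need at least one cost layer")
  g <- layers[[1]]$grid
  for (s in layers) {
    stopifnot(inherits(s, "rs_surface"))
    stop_if_grid_mismatch(g, s$grid, "cost layers")
    if (any(s$values < 0 | s$values > 1, na.rm = TRUE))
      stop("validation error: cost layers must be 0-1 rescaled")
  }
  mats <- lapply(layers, `[[`, "values")
  comb <- if (rule == "mean") Reduce(`+`, mats) / length(mats)
          else Reduce(pmax, mats)
  out <- rs_surface(g, comb, units = paste0(rule, " of 0-1 layers"))
  if (final_rescale) out <- equal_area_rescale(out)
  attr(out, "rule") <- rule
  out
}
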