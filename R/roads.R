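#' Define a road polyline
#'
#' An existing road with a 4-level functional class (1 = highway down to
#' 4 = track/footpath, the latter excluded from density by default
#' because it is not usable by vehicles), or a named proposal for a new
#' or upgraded road.
#'
#' @param road_id Identifier.
#' @param level Integer 1-4, or `"proposal"`.
#' @param coords Two-column lon/lat matrix, >= 2 vertices.
#' @return Object of class `rs_road`.
#' @export
rs_road <- function(road_id, level, coords) {
  if (!identical(level, "proposal")) {
    level <- as.integer(level)
    if (is.na(level) || !level %in% 1:4)
      stop("level must be 1, 2, 3, 4 or \"proposal\"")
  }
  coords <- as.matrix(coords)
  if (ncol(coords) != 2 || nrow(coords) < 2)
    stop("coords must be a lon/lat matrix with >= 2 vertices")
  structure(list(road_id = as.character(road_id), level = level,
                 coords = coords),
            class = "rs_road")
}

#' @export
print.rs_road <- function(x, ...) {
  cat(sprintf("<rs_road> %s (level %s), %d vertices, %.1f km\n",
              x$road_id, as.character(x$level), nrow(x$coords),
              polyline_length_km(x$coords)))
  invisible(x)
}

#' Road density surface
#'
#' Total road length per cell (km) for roads in the selected levels,
#' divided by geodesic cell area (km2). Each polyline segment is split
#' exactly at the grid lines it crosses and each piece credited to the
#' cell containing it. Cells without roads get density 0; invalid cells
#' stay NoData.
#'
#' @param network List of [rs_road] (non-proposal roads are filtered by
#'   `levels`; proposals are ignored).
#' @param grid `rs_grid`.
#' @param areas [cell_areas] of the grid.
#' @param levels Integer levels to include; default `1:3` (tracks and
#'   footpaths excluded).
#' @return `rs_surface` with units `"km/km2"`.
#' @export
road_density <- function(network, grid, areas, levels = 1:3) {
  stopifnot(inherits(grid, "rs_grid"), inherits(areas, "rs_cell_areas"))
  if (!length(network)) stop("network must contain at least one road")
  len <- matrix(0, grid$n_rows, grid$n_cols)
  for (rd in network) {
    if (identical(rd$level, "proposal") || !(rd$level %in% levels)) next
    cd <- rd$coords
    if (nrow(cd) < 2 || polyline_length_km(cd) == 0) {
      warning("road '", rd$road_id, "' has degenerate geometry; skipped")
      next
    }
    for (i in seq_len(nrow(cd) - 1)) {
      pieces <- clip_segment_to_grid(cd[i, 1], cd[i, 2],
                                     cd[i + 1, 1], cd[i + 1, 2], grid)
      if (is.null(pieces)) next
      for (k in seq_len(nrow(pieces)))
        len[pieces$row[k], pieces$col[k]] <-
          len[pieces$row[k], pieces$col[k]] + pieces$len_km[k]
    }
  }
  rs_surface(grid, len / areas$area, units = "km/km2")
}

#' Cells within a buffer of a road
#'
#' All valid cells whose centre lies within `width_km` of the polyline
#' (centre-distance membership matches the analysis resolution: a 10 km
#' buffer at a ~10 km cell size). `mode = "overlap"` instead includes any
#' cell whose square intersects the buffer, approximated by widening the
#' centre criterion by half a cell diagonal.
#'
#' @param road [rs_road].
#' @param grid `rs_grid`.
#' @param width_km Buffer half-width in km, > 0.
#' @param mode `"centre"` (default) or `"overlap"`.
#' @return Data frame of `row`, `col` of member cells.
#' @export
buffer_cells <- function(road, grid, width_km = 10,
                         mode = c("centre", "overlap")) {
  mode <- match.arg(mode)
  stopifnot(inherits(road, "rs_road"), inherits(grid, "rs_grid"))
  if (width_km <= 0) stop("width_km must be > 0")
  cc <- cell_centres(grid)
  eff <- width_km
  if (mode == "overlap") {
    half_diag <- haversine_km(0, mean(cc$lat), grid$cell_size,
                              mean(cc$lat) + grid$cell_size) / 2
    eff <- width_km + half_diag
  }
  # candidate cells: bounding box of the road expanded by the width
  pad <- eff / (EARTH_RADIUS_KM * pi / 180) /
    max(cos(deg2rad(max(abs(cc$lat)))), 0.05) + grid$cell_size
  cols <- which(cc$lon >= min(road$coords[, 1]) - pad &
                  cc$lon <= max(road$coords[, 1]) + pad)
  rows <- which(cc$lat >= min(road$coords[, 2]) - pad &
                  cc$lat <= max(road$coords[, 2]) + pad)
  if (!length(cols) || !length(rows))
    stop("degenerate input: road buffer contains no grid cells")
  plon <- rep(cc$lon[cols], each = length(rows))
  plat <- rep(cc$lat[rows], times = length(cols))
  dmin <- rep(Inf, length(plon))
  cd <- road$coords
  for (i in seq_len(nrow(cd) - 1))
    dmin <- pmin(dmin, point_segment_dist_km(plon, plat, cd[i, 1], cd[i, 2],
                                             cd[i + 1, 1], cd[i + 1, 2]))
  keep <- dmin <= eff
  row_idx <- rep(rows, times = length(cols))[keep]
  col_idx <- rep(cols, each = length(rows))[keep]
  valid <- grid$valid_mask[cbind(row_idx, col_idx)]
  out <- data.frame(row = row_idx[valid], col = col_idx[valid])
  if (!nrow(out))
    stop("degenerate input: road buffer contains no valid cells")
  out
}

#' Buffer zonal summary for one road
#'
#' Unweighted means of each supplied surface over the road's buffer
#' cells — the per-proposal summary line (mean benefit, mean cost, mean
#' travel time, population density, existing-road density). NoData cells
#' are dropped from each mean independently; a surface with no data in
#' the buffer is reported as `NA`.
#'
#' @param road [rs_road].
#' @param surfaces Named list of `rs_surface`s on `grid`.
#' @param grid `rs_grid`.
#' @param width_km Buffer half-width in km (default 10).
#' @param mode Buffer membership rule, see [buffer_cells].
#' @return One-row data frame: `road_id`, `n_buffer_cells`, then
#'   `mean_<name>` for each surface.
#' @export
road_summary <- function(road, surfaces, grid, width_km = 10,
                         mode = c("centre", "overlap")) {
  mode <- match.arg(mode)
  stopifnot(length(surfaces) > 0, !is.null(names(surfaces)),
            all(nzchar(names(surfaces))))
  for (s in surfaces) stop_if_grid_mismatch(s$grid, grid)
  cells <- buffer_cells(road, grid, width_km, mode)
  idx <- cbind(cells$row, cells$col)
  means <- vapply(surfaces, function(s) {
    v <- s$values[idx]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  out <- data.frame(road_id = road$road_id, n_buffer_cells = nrow(cells))
  out[paste0("mean_", names(surfaces))] <- as.list(unname(means))
  out
}

#' Along-route benefit/cost profile
#'
#' The cells a road passes through, in traversal order from its first
#' vertex, with the benefit and cost score of each — impacts often vary
#' substantially along a single road, and the profile shows where the
#' sensitive stretches are. Each cell is reported once, at its first
#' entry.
#'
#' @param road [rs_road].
#' @param benefit,cost `rs_surface`s on `grid`.
#' @param grid `rs_grid`.
#' @return Data frame: `road_id`, `seq`, `row`, `col`, `dist_km` (along
#'   route at first entry), `benefit`, `cost`.
#' @export
road_profile <- function(road, benefit, cost, grid) {
  stop_if_grid_mismatch(benefit$grid, grid)
  stop_if_grid_mismatch(cost$grid, grid)
  cd <- road$coords
  rows <- integer(0); cols <- integer(0); dist <- numeric(0)
  travelled <- 0
  for (i in seq_len(nrow(cd) - 1)) {
    seg_len <- haversine_km(cd[i, 1], cd[i, 2], cd[i + 1, 1], cd[i + 1, 2])
    pieces <- clip_segment_to_grid(cd[i, 1], cd[i, 2],
                                   cd[i + 1, 1], cd[i + 1, 2], grid)
    if (!is.null(pieces)) {
      ord <- order(pieces$t0)
      rows <- c(rows, pieces$row[ord])
      cols <- c(cols, pieces$col[ord])
      dist <- c(dist, travelled + pieces$t0[ord] * seg_len)
    }
    travelled <- travelled + seg_len
  }
  if (!length(rows))
    stop("degenerate input: road lies outside the grid")
  first <- !duplicated(cbind(rows, cols))
  rows <- rows[first]; cols <- cols[first]; dist <- dist[first]
  idx <- cbind(rows, cols)
  data.frame(road_id = road$road_id, seq = seq_along(rows),
             row = rows, col = cols, dist_km = dist,
             benefit = benefit$values[idx], cost = cost$values[idx])
}
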