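# Raster exchange uses the ESRI ASCII grid format (.asc): a plain-text,
# GDAL-readable single-band raster with georeferencing header and NoData
# tag. Values are printed with 17 significant digits so doubles
# round-trip exactly.

NODATA_TAG <- -9999

fmt_full <- function(x) formatC(x, digits = 17, format = "g", width = -1)

#' Write a surface to an ESRI ASCII grid
#'
#' NoData cells (invalid or missing) are written as the NoData tag. The
#' grid's validity mask is not stored in the raster itself (a validity
#' raster can be written as its own 0/1 surface); on reading, the mask
#' defaults to "has data".
#'
#' @param surface `rs_surface`.
#' @param path Output path (conventionally `.asc`).
#' @return `path`, invisibly.
#' @export
write_surface <- function(surface, path) {
  g <- surface$grid
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", g$n_cols),
    paste("nrows", g$n_rows),
    paste("xllcorner", fmt_full(g$origin[1])),
    paste("yllcorner", fmt_full(g$origin[2] - g$n_rows * g$cell_size)),
    paste("cellsize", fmt_full(g$cell_size)),
    paste("NODATA_value", NODATA_TAG)), con)
  v <- surface$values
  v[is.na(v)] <- NODATA_TAG
  for (i in seq_len(g$n_rows))
    writeLines(paste(fmt_full(v[i, ]), collapse = " "), con)
  invisible(path)
}

#' Read a surface from an ESRI ASCII grid
#'
#' @param path Path to a `.asc` file.
#' @param units Units tag to attach.
#' @param valid_mask Optional validity mask; default marks every cell
#'   with data as valid.
#' @return `rs_surface`.
#' @export
read_surface <- function(path, units = "", valid_mask = NULL) {
  if (!file.exists(path)) stop("format error: no such file: ", path)
  lines <- readLines(path)
  if (length(lines) < 7) stop("format error: truncated ASCII grid: ", path)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(parts) != 2) stop("format error: bad header in ", path)
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% names(hdr)))
    stop("format error: missing header fields in ", path)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(vals) != nr * nc)
    stop("format error: expected ", nr * nc, " values in ", path,
         ", found ", length(vals))
  m <- matrix(vals, nr, nc, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA_real_
  if (is.null(valid_mask)) valid_mask <- !is.na(m)
  if (!any(valid_mask)) stop("format error: ", path, " has no data cells")
  grid <- rs_grid(nr, nc, hdr$cellsize,
                  origin = c(hdr$xllcorner, hdr$yllcorner + nr * hdr$cellsize),
                  valid_mask = valid_mask)
  rs_surface(grid, m, units = units)
}

# ---- GeoJSON vectors ------------------------------------------------------

roads_to_geojson <- function(roads) {
  list(type = "FeatureCollection", features = lapply(roads, function(r) {
    list(type = "Feature",
         properties = list(road_id = r$road_id,
                           level = as.character(r$level)),
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(r$coords)),
                                              function(i) r$coords[i, ])))
  }))
}

#' Write roads to GeoJSON
#' @param roads List of [rs_road].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roads_geojson <- function(roads, path) {
  jsonlite::write_json(roads_to_geojson(roads), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read roads from GeoJSON
#' @param path Path to a GeoJSON FeatureCollection of LineStrings.
#' @return List of [rs_road].
#' @export
read_roads_geojson <- function(path) {
  if (!file.exists(path)) stop("format error: no such file: ", path)
  j <- jsonlite::read_json(path)
  lapply(j$features, function(f) {
    cd <- do.call(rbind, lapply(f$geometry$coordinates,
                                function(p) c(p[[1]], p[[2]])))
    lev <- f$properties$level
    if (!identical(lev, "proposal")) lev <- as.integer(lev)
    rs_road(f$properties$road_id, lev, cd)
  })
}

#' Write species ranges to GeoJSON
#' @param ranges List of [rs_species_range].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranges_geojson <- function(ranges, path) {
  fc <- list(type = "FeatureCollection", features = lapply(ranges, function(r) {
    rings <- lapply(r$geometry, function(poly) {
      closed <- rbind(poly, poly[1, ])
      list(lapply(seq_len(nrow(closed)), function(i) closed[i, ]))
    })
    list(type = "Feature",
         properties = list(species_id = r$species_id, v_class = r$v_class,
                           global_range_area_km2 = r$global_range_area),
         geometry = list(type = "MultiPolygon", coordinates = rings))
  }))
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read species ranges from GeoJSON
#' @param path Path to a GeoJSON FeatureCollection of MultiPolygons.
#' @return List of [rs_species_range].
#' @export
read_ranges_geojson <- function(path) {
  if (!file.exists(path)) stop("format error: no such file: ", path)
  j <- jsonlite::read_json(path)
  lapply(j$features, function(f) {
    polys <- lapply(f$geometry$coordinates, function(ring) {
      cd <- do.call(rbind, lapply(ring[[1]], function(pt) c(pt[[1]], pt[[2]])))
      cd[-nrow(cd), , drop = FALSE]  # drop closing vertex
    })
    rs_species_range(f$properties$species_id, f$properties$v_class, polys,
                     f$properties$global_range_area_km2)
  })
}

# ---- bundle I/O -----------------------------------------------------------

#' Write a landscape bundle to a directory
#'
#' Emits every raster as an ASCII grid, vectors as GeoJSON, tables as
#' CSV, plus a YAML manifest recording files, units, and the generating
#' parameters (so `generate_landscape(manifest params)` reproduces the
#' stored bundle exactly).
#'
#' @param bundle `rs_bundle`.
#' @param directory Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
write_bundle <- function(bundle, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (file.access(directory, 2) != 0)
    stop("I/O error: directory not writable: ", directory)
  files <- list()
  put_surface <- function(s, name) {
    f <- paste0(name, ".asc")
    write_surface(s, file.path(directory, f))
    files[[name]] <<- list(file = f, kind = "raster", units = s$units)
  }
  put_surface(rs_surface(bundle$grid, bundle$grid$valid_mask * 1, "0/1"),
              "valid_mask")
  put_surface(bundle$travel_time, "travel_time")
  put_surface(bundle$natural_cover, "natural_cover")
  put_surface(bundle$carbon_biomass, "carbon_biomass")
  put_surface(bundle$carbon_soil30, "carbon_soil30")
  put_surface(bundle$ecoregion_id, "ecoregion_id")
  put_surface(bundle$population, "population")
  crop_table <- function(crops, prefix) {
    rows <- lapply(crops, function(cr) {
      gap_name <- paste0(prefix, "_", cr$name, "_gap")
      area_name <- paste0(prefix, "_", cr$name, "_area")
      put_surface(cr$yield_gap, gap_name)
      put_surface(cr$harvested_area, area_name)
      data.frame(crop = cr$name, yield_gap_file = paste0(gap_name, ".asc"),
                 area_file = paste0(area_name, ".asc"),
                 energy_gj_per_t = cr$energy_content)
    })
    do.call(rbind, rows)
  }
  crops_csv <- crop_table(bundle$crops, "crop")
  crops_alt_csv <- crop_table(bundle$crops_alt, "cropalt")
  utils::write.csv(crops_csv, file.path(directory, "crops.csv"),
                   row.names = FALSE)
  utils::write.csv(crops_alt_csv, file.path(directory, "crops_alt.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$ecoregion_indices,
                   file.path(directory, "ecoregion_indices.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$cities, file.path(directory, "cities.csv"),
                   row.names = FALSE)
  write_roads_geojson(bundle$roads_existing,
                      file.path(directory, "roads_existing.geojson"))
  write_roads_geojson(bundle$road_proposals,
                      file.path(directory, "road_proposals.geojson"))
  write_ranges_geojson(bundle$species_ranges,
                       file.path(directory, "species_ranges.geojson"))
  files$crops <- list(file = "crops.csv", kind = "table")
  files$crops_alt <- list(file = "crops_alt.csv", kind = "table")
  files$ecoregion_indices <- list(file = "ecoregion_indices.csv",
                                  kind = "table")
  files$cities <- list(file = "cities.csv", kind = "table")
  files$roads_existing <- list(file = "roads_existing.geojson",
                               kind = "vector")
  files$road_proposals <- list(file = "road_proposals.geojson",
                               kind = "vector")
  files$species_ranges <- list(file = "species_ranges.geojson",
                               kind = "vector")
  pp <- unclass(bundle$params)
  pp$n_species <- as.list(pp$n_species)   # keep class names in YAML
  manifest <- list(format = "roadscape bundle v1",
                   params = pp, files = files)
  yaml::write_yaml(manifest, file.path(directory, "manifest.yml"),
                   precision = 15)
  invisible(manifest)
}

#' Read a landscape bundle from a directory
#'
#' Inverse of [write_bundle]; `read_bundle(write_bundle(b))` reproduces
#' the bundle's values exactly.
#'
#' @param directory Directory containing `manifest.yml`.
#' @return `rs_bundle`.
#' @export
read_bundle <- function(directory) {
  mf_path <- file.path(directory, "manifest.yml")
  if (!file.exists(mf_path))
    stop("I/O error: no manifest.yml in ", directory)
  mf <- yaml::read_yaml(mf_path)
  p <- mf$params
  params <- landscape_params(
    n_rows = p$n_rows, n_cols = p$n_cols, cell_size = p$cell_size,
    origin = unlist(p$origin), n_cities = p$n_cities, n_crops = p$n_crops,
    n_ecoregions = p$n_ecoregions, n_species = unlist(p$n_species),
    n_proposals = p$n_proposals,
    conversion_steepness = p$conversion_steepness,
    yieldgap_isolation_slope = p$yieldgap_isolation_slope,
    noise_sd = p$noise_sd, travel_speed_kmh = p$travel_speed_kmh,
    seed = p$seed)
  getf <- function(name) file.path(directory, mf$files[[name]]$file)
  mask_s <- read_surface(getf("valid_mask"))
  mask <- !is.na(mask_s$values) & mask_s$values == 1
  grid <- rs_grid(params$n_rows, params$n_cols, params$cell_size,
                  params$origin, mask)
  surf <- function(name) {
    s <- read_surface(getf(name), units = mf$files[[name]]$units %||% "",
                      valid_mask = mask)
    rs_surface(grid, s$values, units = s$units)
  }
  read_crops <- function(csv_name) {
    tab <- utils::read.csv(file.path(directory, csv_name))
    lapply(seq_len(nrow(tab)), function(i) {
      gap <- read_surface(file.path(directory, tab$yield_gap_file[i]),
                          "t/ha/y", mask)
      area <- read_surface(file.path(directory, tab$area_file[i]),
                           "ha/cell", mask)
      rs_crop(tab$crop[i],
              rs_surface(grid, gap$values, "t/ha/y"),
              rs_surface(grid, area$values, "ha/cell"),
              tab$energy_gj_per_t[i])
    })
  }
  structure(list(params = params, grid = grid,
                 cities = utils::read.csv(getf("cities")),
                 travel_time = surf("travel_time"),
                 natural_cover = surf("natural_cover"),
                 crops = read_crops("crops.csv"),
                 crops_alt = read_crops("crops_alt.csv"),
                 carbon_biomass = surf("carbon_biomass"),
                 carbon_soil30 = surf("carbon_soil30"),
                 ecoregion_id = surf("ecoregion_id"),
                 ecoregion_indices = utils::read.csv(getf("ecoregion_indices")),
                 population = surf("population"),
                 species_ranges = read_ranges_geojson(getf("species_ranges")),
                 roads_existing = read_roads_geojson(getf("roads_existing")),
                 road_proposals = read_roads_geojson(getf("road_proposals"))),
            class = "rs_bundle")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
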