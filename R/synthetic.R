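# Named sub-streams off one master seed, so adding a generator stage
# never perturbs the draws of another.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 97)
  as.integer((as.double(seed) * 10007 + h) %% 2147483629)
}

with_substream <- function(seed, name, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, name))
  code
}

#' Default crop energy-content table
#'
#' Food energy per tonne of product for the major crop groups the
#' production-gap accounting covers, in GJ/t. Values are standard
#' food-composition figures for fresh/paddy product; users supplying
#' their own crop layers can pass any table with the same columns.
#'
#' @return Data frame with columns `crop` and `energy_gj_per_t`.
#' @export
default_crop_energy <- function() {
  data.frame(
    crop = c("rice", "maize", "cassava", "sugarcane", "soybean",
             "groundnut", "sweet_potato", "wheat", "banana", "potato",
             "sorghum", "millet", "dry_bean", "barley", "rapeseed",
             "sunflower", "oil_palm_kernel"),
    energy_gj_per_t = c(15.2, 16.3, 6.7, 1.9, 18.3,
                        24.0, 3.6, 15.7, 3.7, 3.2,
                        14.2, 15.9, 14.5, 14.8, 20.8,
                        21.5, 22.0),
    stringsAsFactors = FALSE)
}

#' Parameters of the synthetic landscape generator
#'
#' Bundles every knob of [generate_landscape] with validation. The
#' defaults describe a 100 x 100 cell (~830 km square) landscape with
#' the structure the benefit/cost screening assumes: habitat conversion
#' concentrated near cities, cropland (with isolation-dependent yield
#' gaps) only on converted land, carbon and species importance tied to
#' remaining natural cover, a handful of contiguous ecoregions, and
#' city-centred population.
#'
#' @param n_rows,n_cols Grid dimensions (product >= 100).
#' @param cell_size Cell size in degrees (default 0.0833).
#' @param origin Upper-left corner `c(lon, lat)`.
#' @param n_cities Number of cities (travel-time / population anchors).
#' @param n_crops Number of crops (drawn from [default_crop_energy]).
#' @param n_ecoregions Number of contiguous ecoregions.
#' @param n_species Named counts per vertebrate class.
#' @param n_proposals Number of proposed roads.
#' @param conversion_steepness Logistic steepness (per minute) of the
#'   decline of habitat conversion with travel time; > 0.
#' @param yieldgap_isolation_slope Increase of yield gap with travel time
#'   (t/ha/y per minute).
#' @param noise_sd Baseline noise level (dimensionless; layer-specific
#'   noise scales are proportional to it); >= 0.
#' @param travel_speed_kmh Assumed road speed converting distance to
#'   travel time.
#' @param seed Master seed; all generation is deterministic given it.
#' @return Object of class `rs_landscape_params`.
#' @export
landscape_params <- function(n_rows = 100, n_cols = 100, cell_size = 0.0833,
                             origin = c(98, 25),
                             n_cities = 5, n_crops = 5, n_ecoregions = 6,
                             n_species = c(mammal = 25, bird = 25,
                                           amphibian = 25),
                             n_proposals = 8,
                             conversion_steepness = 0.05,
                             yieldgap_isolation_slope = 0.004,
                             noise_sd = 0.15,
                             travel_speed_kmh = 40,
                             seed = 1) {
  counts <- c(n_rows = n_rows, n_cols = n_cols, n_cities = n_cities,
              n_crops = n_crops, n_ecoregions = n_ecoregions,
              n_proposals = n_proposals, n_species)
  if (any(counts < 1))
    stop("parameter error: all counts must be >= 1")
  if (n_rows * n_cols < 100)
    stop("parameter error: grid must have at least 100 cells")
  if (!all(VERT_CLASSES %in% names(n_species)))
    stop("parameter error: n_species needs named counts for ",
         paste(VERT_CLASSES, collapse = ", "))
  if (conversion_steepness <= 0)
    stop("parameter error: conversion_steepness must be > 0")
  if (noise_sd < 0) stop("parameter error: noise_sd must be >= 0")
  if (n_crops > nrow(default_crop_energy()))
    stop("parameter error: at most ", nrow(default_crop_energy()), " crops")
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 cell_size = cell_size, origin = as.numeric(origin),
                 n_cities = as.integer(n_cities),
                 n_crops = as.integer(n_crops),
                 n_ecoregions = as.integer(n_ecoregions),
                 n_species = vapply(n_species, as.integer, 0L),
                 n_proposals = as.integer(n_proposals),
                 conversion_steepness = conversion_steepness,
                 yieldgap_isolation_slope = yieldgap_isolation_slope,
                 noise_sd = noise_sd,
                 travel_speed_kmh = travel_speed_kmh,
                 seed = as.integer(seed)),
            class = "rs_landscape_params")
}

# one pass of 3x3 mean smoothing (edge-padded), used to give noise
# fields spatial structure
smooth3 <- function(m, passes = 2) {
  for (p in seq_len(passes)) {
    padded <- m[c(1, seq_len(nrow(m)), nrow(m)),
                c(1, seq_len(ncol(m)), ncol(m))]
    acc <- matrix(0, nrow(m), ncol(m))
    for (di in 0:2) for (dj in 0:2)
      acc <- acc + padded[di + seq_len(nrow(m)), dj + seq_len(ncol(m))]
    m <- acc / 9
  }
  m
}

#' Generate a synthetic landscape bundle
#'
#' Builds a complete, internally consistent input set for the screening
#' pipeline. The construction deliberately embeds the structure observed
#' in heavily converted, biodiverse regions: conversion follows access
#' (natural cover is a logistic function of travel time, low near
#' cities), cropland exists only on the converted fraction of each cell,
#' yield gaps grow linearly with isolation, carbon stocks and species
#' ranges track natural cover, and population decays away from cities.
#' Because the production-dependent benefit needs cropland (converted,
#' accessible cells) while all three cost layers scale with natural
#' cover (intact, remote cells), the downstream benefit and cost
#' aggregates come out broadly negatively associated in space.
#'
#' All randomness is drawn from named sub-streams of `params$seed`, so
#' the same parameters always reproduce the same bundle bit for bit.
#'
#' @param params [landscape_params].
#' @return Object of class `rs_bundle`: grid, travel time, natural
#'   cover, crop layers (plus an independent alternative crop set for
#'   sensitivity analysis), carbon stocks, ecoregions and their climate
#'   indices, population, species ranges, existing roads and proposals.
#' @export
generate_landscape <- function(params) {
  stopifnot(inherits(params, "rs_landscape_params"))
  p <- params
  nr <- p$n_rows; nc <- p$n_cols

  # --- validity mask: one water body (lake) blob --------------------------
  mask <- with_substream(p$seed, "mask", {
    m <- matrix(TRUE, nr, nc)
    ci <- runif(1, 0.2, 0.8) * nr; cj <- runif(1, 0.2, 0.8) * nc
    r <- max(1.5, 0.03 * sqrt(nr * nc))
    ii <- matrix(seq_len(nr), nr, nc); jj <- matrix(seq_len(nc), nr, nc,
                                                   byrow = TRUE)
    m[(ii - ci)^2 + (jj - cj)^2 < r^2] <- FALSE
    m
  })
  grid <- rs_grid(nr, nc, p$cell_size, p$origin, mask)
  areas <- cell_areas(grid)
  cc <- cell_centres(grid)

  # --- cities -------------------------------------------------------------
  cities <- with_substream(p$seed, "cities", {
    valid_idx <- which(mask)
    pick <- sample(valid_idx, p$n_cities)
    data.frame(city_id = paste0("C", seq_len(p$n_cities)),
               row = ((pick - 1) %% nr) + 1,
               col = ((pick - 1) %/% nr) + 1)
  })
  cities$lon <- cc$lon[cities$col]
  cities$lat <- cc$lat[cities$row]

  # distance (km) from every cell centre to the nearest city
  d_city <- matrix(Inf, nr, nc)
  for (k in seq_len(nrow(cities)))
    d_city <- pmin(d_city, matrix(
      haversine_km(as.vector(cc$lon_mat), as.vector(cc$lat_mat),
                   cities$lon[k], cities$lat[k]), nr, nc))

  # --- travel time (min): distance / speed, mild multiplicative noise -----
  travel_time <- with_substream(p$seed, "travel", {
    tt <- d_city / p$travel_speed_kmh * 60
    tt <- tt * pmax(1 + matrix(rnorm(nr * nc, 0, p$noise_sd / 2), nr, nc), 0.1)
    rs_surface(grid, tt, units = "min")
  })

  # --- natural cover: logistic in travel time + smoothed noise ------------
  natural_cover <- with_substream(p$seed, "cover", {
    tt <- travel_time$values
    t_mid <- stats::quantile(tt, 0.45, na.rm = TRUE)
    base <- 1 / (1 + exp(-p$conversion_steepness * (tt - t_mid)))
    noise <- smooth3(matrix(rnorm(nr * nc), nr, nc))
    # smoothing shrinks the amplitude; restore it so the field's sd is
    # noise_sd — this is the conversion variance not explained by access
    # (soils, terrain, settlement history)
    if (stats::sd(noise) > 0) noise <- noise * (p$noise_sd / stats::sd(noise))
    rs_surface(grid, pmin(1, pmax(0, base + noise)), units = "proportion")
  })

  # --- ecoregions: nearest-seed contiguous partition ----------------------
  eco <- with_substream(p$seed, "ecoregions", {
    seeds <- sample(which(mask), p$n_ecoregions)
    si <- ((seeds - 1) %% nr) + 1; sj <- ((seeds - 1) %/% nr) + 1
    ii <- matrix(seq_len(nr), nr, nc)
    jj <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    best <- matrix(1L, nr, nc); bestd <- (ii - si[1])^2 + (jj - sj[1])^2
    for (k in seq_len(p$n_ecoregions)[-1]) {
      d <- (ii - si[k])^2 + (jj - sj[k])^2
      upd <- d < bestd
      best[upd] <- k; bestd[upd] <- d[upd]
    }
    list(id = rs_surface(grid, best, units = "ecoregion id"),
         indices = data.frame(ecoregion_id = seq_len(p$n_ecoregions),
                              hri = runif(p$n_ecoregions, 1, 4),
                              mri = runif(p$n_ecoregions, 0.5, 3)))
  })

  # --- carbon stocks: increase with natural cover -------------------------
  carbon <- with_substream(p$seed, "carbon", {
    cov <- natural_cover$values
    biomass <- pmax(160 * cov + matrix(rnorm(nr * nc, 0, 120 * p$noise_sd),
                                       nr, nc), 0)
    soil <- pmax(60 + 50 * cov + matrix(rnorm(nr * nc, 0, 60 * p$noise_sd),
                                        nr, nc), 0)
    list(biomass = rs_surface(grid, biomass, units = "t/ha"),
         soil30 = rs_surface(grid, soil, units = "t/ha"))
  })

  # --- population: decaying kernels around cities -------------------------
  population <- with_substream(p$seed, "population", {
    pop <- matrix(2, nr, nc)
    for (k in seq_len(nrow(cities))) {
      p0 <- exp(rnorm(1, log(1500), 0.5))
      d <- matrix(haversine_km(as.vector(cc$lon_mat), as.vector(cc$lat_mat),
                               cities$lon[k], cities$lat[k]), nr, nc)
      pop <- pop + p0 * exp(-d / 25)
    }
    pop <- pop * pmax(1 + matrix(rnorm(nr * nc, 0, p$noise_sd / 2), nr, nc), 0)
    rs_surface(grid, pop, units = "persons/km2")
  })

  # --- crops: areas only on the converted fraction, gaps ~ isolation ------
  make_crops <- function(stream, n_crops, slope, disagreement = 0) {
    with_substream(p$seed, stream, {
      energy <- default_crop_energy()[seq_len(n_crops), ]
      shares <- rgamma(n_crops, 2); shares <- shares / sum(shares)
      conv_ha <- (1 - natural_cover$values) * areas$area * 100 * 0.9
      tt <- travel_time$values
      # alternative databases disagree spatially (different climate
      # binning, attainable-yield definitions): a smoothed lognormal
      # field multiplies the gaps when disagreement > 0
      field <- 1
      if (disagreement > 0) {
        f <- smooth3(matrix(rnorm(nr * nc), nr, nc))
        field <- exp(f * (disagreement / stats::sd(f)))
      }
      lapply(seq_len(n_crops), function(i) {
        base <- runif(1, 0.5, 2)
        gap <- pmax(base + slope * tt +
                      matrix(rnorm(nr * nc, 0, p$noise_sd), nr, nc), 0) * field
        rs_crop(energy$crop[i],
                yield_gap = rs_surface(grid, gap, units = "t/ha/y"),
                harvested_area = rs_surface(grid, conv_ha * shares[i],
                                            units = "ha/cell"),
                energy_content = energy$energy_gj_per_t[i])
      })
    })
  }
  crops <- make_crops("crops", p$n_crops, p$yieldgap_isolation_slope)
  # independently derived alternative crop set for sensitivity test 1
  crops_alt <- make_crops("crops_alt", max(p$n_crops - 1L, 1L),
                          p$yieldgap_isolation_slope * 0.7,
                          disagreement = 0.5)

  species_ranges <- generate_species_ranges(p, natural_cover)

  # --- roads: existing network between cities, plus proposals -------------
  jitter_line <- function(a, b, n_mid = 4, sd_deg = NULL) {
    if (is.null(sd_deg)) sd_deg <- p$cell_size
    t <- seq(0, 1, length.out = n_mid + 2)
    lon <- a[1] + t * (b[1] - a[1])
    lat <- a[2] + t * (b[2] - a[2])
    mid <- seq(2, n_mid + 1)
    lon[mid] <- lon[mid] + rnorm(n_mid, 0, sd_deg)
    lat[mid] <- lat[mid] + rnorm(n_mid, 0, sd_deg)
    cbind(lon, lat)
  }
  roads_existing <- with_substream(p$seed, "roads", {
    out <- list(); rid <- 0
    add <- function(a, b, level) {
      rid <<- rid + 1
      out[[rid]] <<- rs_road(sprintf("R%02d", rid), level,
                             jitter_line(a, b))
    }
    if (nrow(cities) > 1) {
      for (k in seq_len(nrow(cities))) {
        d <- haversine_km(cities$lon[k], cities$lat[k],
                          cities$lon, cities$lat)
        d[k] <- Inf
        m <- which.min(d)
        add(c(cities$lon[k], cities$lat[k]), c(cities$lon[m], cities$lat[m]),
            sample(1:2, 1))
      }
    }
    # secondary / minor roads between random city pairs or offsets
    for (k in seq_len(max(2 * nrow(cities), 4))) {
      a <- cities[sample(nrow(cities), 1), ]
      b <- c(a$lon + runif(1, -1.5, 1.5), a$lat + runif(1, -1.5, 1.5))
      add(c(a$lon, a$lat), b, sample(2:4, 1, prob = c(0.3, 0.4, 0.3)))
    }
    out
  })
  road_proposals <- with_substream(p$seed, "proposals", {
    cov <- natural_cover$values
    valid_idx <- which(mask)
    w_low <- pmax(1 - cov[valid_idx], 0.01)   # converted end
    w_high <- pmax(cov[valid_idx], 0.01)      # intact end
    lapply(seq_len(p$n_proposals), function(k) {
      a_i <- sample(valid_idx, 1, prob = w_low)
      b_i <- sample(valid_idx, 1, prob = w_high)
      a <- c(cc$lon[((a_i - 1) %/% nr) + 1], cc$lat[((a_i - 1) %% nr) + 1])
      b <- c(cc$lon[((b_i - 1) %/% nr) + 1], cc$lat[((b_i - 1) %% nr) + 1])
      rs_road(sprintf("P%02d", k), "proposal", jitter_line(a, b, n_mid = 3))
    })
  })

  structure(list(params = p, grid = grid, cities = cities,
                 travel_time = travel_time, natural_cover = natural_cover,
                 crops = crops, crops_alt = crops_alt,
                 carbon_biomass = carbon$biomass,
                 carbon_soil30 = carbon$soil30,
                 ecoregion_id = eco$id, ecoregion_indices = eco$indices,
                 population = population,
                 species_ranges = species_ranges,
                 roads_existing = roads_existing,
                 road_proposals = road_proposals),
            class = "rs_bundle")
}

#' @export
print.rs_bundle <- function(x, ...) {
  cat(sprintf(paste0("<rs_bundle> %d x %d grid, %d cities, %d crops, ",
                     "%d ecoregions,\n  %d species ranges, %d existing roads, ",
                     "%d proposals (seed %d)\n"),
              x$grid$n_rows, x$grid$n_cols, nrow(x$cities), length(x$crops),
              nrow(x$ecoregion_indices), length(x$species_ranges),
              length(x$roads_existing), length(x$road_proposals),
              x$params$seed))
  invisible(x)
}

#' Generate synthetic species ranges
#'
#' Draws elliptical ranges per vertebrate class with a log-uniform size
#' distribution spanning more than two orders of magnitude (100 to
#' 50,000 km2), centred preferentially on cells with high natural cover
#' (uniform if cover is zero everywhere). The recorded global range area
#' is the geodesic area of the generating polygon itself, so
#' proportional range sizes are exact by construction.
#'
#' @param params [landscape_params].
#' @param natural_cover `rs_surface` of natural-cover proportions.
#' @param stream Sub-stream name (change to draw an independent set).
#' @return List of [rs_species_range].
#' @export
generate_species_ranges <- function(params, natural_cover,
                                    stream = "ranges") {
  p <- params
  grid <- natural_cover$grid
  cc <- cell_centres(grid)
  nr <- grid$n_rows
  with_substream(p$seed, stream, {
    valid_idx <- which(grid$valid_mask)
    w <- natural_cover$values[valid_idx]
    w[is.na(w)] <- 0
    if (sum(w) == 0) w <- rep(1, length(w))
    out <- list(); n_tot <- 0
    for (cl in VERT_CLASSES) {
      for (s in seq_len(p$n_species[[cl]])) {
        n_tot <- n_tot + 1
        idx <- sample(valid_idx, 1, prob = w)
        clon <- cc$lon[((idx - 1) %/% nr) + 1]
        clat <- cc$lat[((idx - 1) %% nr) + 1]
        area_target <- 10^runif(1, 2, log10(5e4))   # km2, log-uniform
        ratio <- runif(1, 1, 3)
        a_km <- sqrt(area_target * ratio / pi)      # semi-major
        b_km <- a_km / ratio
        th <- runif(1, 0, pi)
        ang <- seq(0, 2 * pi, length.out = 49)[-49]
        ex <- a_km * cos(ang) * cos(th) - b_km * sin(ang) * sin(th)
        ey <- a_km * cos(ang) * sin(th) + b_km * sin(ang) * cos(th)
        lon <- clon + ex / (EARTH_RADIUS_KM * pi / 180 * cos(deg2rad(clat)))
        lat <- clat + ey / (EARTH_RADIUS_KM * pi / 180)
        poly <- cbind(lon, lat)
        g_area <- abs(geosphere::areaPolygon(
          poly, a = EARTH_RADIUS_KM * 1000, f = 0)) / 1e6
        out[[n_tot]] <- rs_species_range(
          sprintf("%s_%03d", substr(cl, 1, 3), s), cl, poly, g_area)
      }
    }
    out
  })
}
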