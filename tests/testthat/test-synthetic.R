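test_that("parameter validation rejects bad inputs", {
  expect_error(landscape_params(n_rows = 5, n_cols = 5), "100 cells")
  expect_error(landscape_params(n_cities = 0), "counts")
  expect_error(landscape_params(conversion_steepness = 0), "steepness")
  expect_error(landscape_params(noise_sd = -1), "noise_sd")
  expect_error(landscape_params(n_species = c(mammal = 3, bird = 3)),
               "n_species")
})

test_that("generation is deterministic given the seed", {
  p <- small_params(seed = 9)
  b1 <- generate_landscape(p)
  b2 <- generate_landscape(p)
  expect_identical(b1, b2)
  b3 <- generate_landscape(small_params(seed = 10))
  expect_false(identical(b1$travel_time$values, b3$travel_time$values))
})

test_that("vanishing conversion steepness gives near-uniform cover", {
  p <- landscape_params(n_rows = 40, n_cols = 40, seed = 2,
                        conversion_steepness = 1e-9, noise_sd = 0.05,
                        n_species = c(mammal = 2, bird = 2, amphibian = 2))
  b <- generate_landscape(p)
  cov <- b$natural_cover$values
  expect_lte(sd(cov[!is.na(cov)]), 2 * p$noise_sd)
})

test_that("yield gaps recover the isolation slope by regression", {
  p <- landscape_params(n_rows = 100, n_cols = 100, seed = 4,
                        noise_sd = 0.05,
                        n_species = c(mammal = 2, bird = 2, amphibian = 2))
  b <- generate_landscape(p)
  fit <- lm(as.vector(b$crops[[1]]$yield_gap$values) ~
              as.vector(b$travel_time$values))
  expect_lt(abs(coef(fit)[2] - p$yieldgap_isolation_slope) /
              p$yieldgap_isolation_slope, 0.2)
})

test_that("land accounting: cropland never exceeds the converted fraction", {
  b <- generate_landscape(small_params(seed = 5))
  areas <- cell_areas(b$grid)
  tot_ha <- Reduce(`+`, lapply(b$crops, function(cr) {
    v <- cr$harvested_area$values
    v[is.na(v)] <- 0
    v
  }))
  cap <- (1 - b$natural_cover$values) * areas$area * 100
  ok <- !is.na(b$natural_cover$values)
  expect_true(all(tot_ha[ok] <= cap[ok] + 1e-9))
})

test_that("species ranges span two orders of magnitude in size", {
  p <- landscape_params(n_rows = 40, n_cols = 40, seed = 1,
                        n_species = c(mammal = 50, bird = 1, amphibian = 1))
  ratios <- vapply(1:10, function(s) {
    p$seed <- s
    b_cov <- rs_surface(rs_grid(40, 40), matrix(runif(1600), 40))
    rg <- generate_species_ranges(p, b_cov)
    sizes <- vapply(rg, `[[`, 0, "global_range_area")
    sizes <- sizes[vapply(rg, `[[`, "", "v_class") == "mammal"]
    max(sizes) / min(sizes)
  }, numeric(1))
  expect_gte(median(ratios), 100)
})

test_that("range centres degrade gracefully under zero natural cover", {
  p <- small_params(seed = 3)
  g <- rs_grid(30, 30)
  zero_cov <- rs_surface(g, matrix(0, 30, 30))
  rg <- generate_species_ranges(p, zero_cov)
  expect_length(rg, 15)
  # every range still intersects at least one valid cell (centre is one)
  areas <- cell_areas(g)
  raw <- vertebrate_importance(rg, rs_surface(g, matrix(1, 30, 30)), areas)
  expect_true(all(vapply(attr(raw, "raw_class_surfaces"), function(s)
    any(s$values > 0, na.rm = TRUE), logical(1))))
})

test_that("a whole-area species yields proportional-range normalization", {
  g <- rs_grid(12, 12, 0.5, origin = c(100, 16))
  areas <- cell_areas(g)
  # polygon covering the full grid, with parallels densified so the
  # geodesic-edged oracle polygon follows the latitude-bounded cells
  lons <- seq(100, 106, by = 0.05)
  poly <- rbind(cbind(lons, 10), cbind(rev(lons), 16))
  tot_area <- abs(geosphere::areaPolygon(poly, a = 6371008.8, f = 0)) / 1e6
  sp <- rs_species_range("sp1", "mammal", poly, tot_area)
  cover1 <- rs_surface(g, matrix(1, 12, 12))
  suppressWarnings(out <- vertebrate_importance(list(sp), cover1, areas))
  raw <- attr(out, "raw_class_surfaces")$mammal$values
  expect_equal(sum(raw), 1, tolerance = 1e-4)
})

test_that("bundles round-trip through a directory exactly", {
  p <- landscape_params(n_rows = 20, n_cols = 20, seed = 6,
                        n_species = c(mammal = 3, bird = 3, amphibian = 3),
                        n_cities = 2, n_crops = 2, n_ecoregions = 3,
                        n_proposals = 2)
  b <- generate_landscape(p)
  dir <- withr::local_tempdir()
  manifest <- write_bundle(b, dir)
  # manifest lists every emitted file
  listed <- vapply(manifest$files, `[[`, "", "file")
  on_disk <- setdiff(list.files(dir), "manifest.yml")
  expect_setequal(unname(listed), on_disk)
  b2 <- read_bundle(dir)
  expect_equal(b2$travel_time$values, b$travel_time$values)
  expect_equal(b2$natural_cover$values, b$natural_cover$values)
  expect_equal(b2$grid$valid_mask, b$grid$valid_mask)
  expect_equal(b2$crops[[1]]$yield_gap$values, b$crops[[1]]$yield_gap$values)
  expect_equal(b2$crops[[2]]$energy_content, b$crops[[2]]$energy_content)
  expect_equal(b2$ecoregion_indices, b$ecoregion_indices)
  expect_equal(length(b2$species_ranges), length(b$species_ranges))
  expect_equal(b2$species_ranges[[5]]$geometry[[1]],
               b$species_ranges[[5]]$geometry[[1]],
               ignore_attr = TRUE)
  expect_equal(b2$roads_existing[[1]]$coords, b$roads_existing[[1]]$coords,
               ignore_attr = TRUE)
  # regeneration from the manifest's params reproduces the stored bundle
  b3 <- generate_landscape(do.call(landscape_params, c(
    manifest$params[setdiff(names(manifest$params), "n_species")],
    list(n_species = unlist(manifest$params$n_species)))))
  expect_equal(b3$travel_time$values, b$travel_time$values)
  expect_equal(b3$population$values, b$population$values)
})
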