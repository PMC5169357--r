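test_that("vertebrate importance does direct proportional-range arithmetic", {
  # two species of one class, each covering the same 10 cells incl. X
  g <- rs_grid(2, 5, 0.2, origin = c(100, 10))   # 10 equal-ish cells
  areas <- cell_areas(g)
  poly <- rect_poly(100, 10 - 0.4, 101, 10)      # whole grid
  a10 <- sum(areas$area)
  sp <- list(rs_species_range("s1", "bird", poly, a10),
             rs_species_range("s2", "bird", poly, a10))
  cover <- rs_surface(g, matrix(0.5, 2, 5))
  suppressWarnings(out <- vertebrate_importance(sp, cover, areas))
  raw <- attr(out, "raw_class_surfaces")$bird$values
  # per cell: (area/(10a) + area/(10a)) * 0.5 = 0.1 for equal-area cells
  expect_equal(raw[1, 3], 2 * areas$area[1, 3] / a10 * 0.5, tolerance = 1e-12)
  expect_equal(mean(raw), 0.1, tolerance = 1e-3)
})

test_that("zero natural cover annihilates the vertebrate layer", {
  g <- tiny_grid(5, 5)
  areas <- cell_areas(g)
  poly <- rect_poly(100, 14.8, 100.2, 15)
  sp <- list(rs_species_range("s1", "mammal", poly, 500))
  cover0 <- rs_surface(g, matrix(0, 5, 5))
  suppressWarnings(out <- vertebrate_importance(sp, cover0, areas))
  raw <- attr(out, "raw_class_surfaces")$mammal$values
  expect_true(all(raw == 0))
  expect_length(unique(as.vector(out$values)), 1)  # all tied
})

test_that("vertebrate raw scores match a polygon-cell intersection oracle", {
  set.seed(31)
  g <- rs_grid(20, 20, 0.1, origin = c(100, 16))
  areas <- cell_areas(g)
  cc <- cell_centres(g)
  mk_blob <- function(id, cl) {
    clon <- runif(1, 100.1, 101.9); clat <- runif(1, 14.1, 15.9)
    r <- runif(1, 0.05, 0.5)
    ang <- seq(0, 2 * pi, length.out = 13)[-13]
    rad <- r * runif(12, 0.6, 1.4)     # star-shaped blob, possibly nonconvex
    poly <- cbind(clon + rad * cos(ang), clat + rad * sin(ang))
    rs_species_range(id, cl, poly,
                     abs(geosphere::areaPolygon(poly, a = 6371008.8,
                                                f = 0)) / 1e6)
  }
  ranges <- lapply(1:30, function(i)
    mk_blob(paste0("s", i), c("mammal", "bird", "amphibian")[(i %% 3) + 1]))
  cover <- rs_surface(g, matrix(runif(400), 20))
  out <- vertebrate_importance(ranges, cover, areas)
  for (cl in c("mammal", "bird", "amphibian")) {
    mine <- attr(out, "raw_class_surfaces")[[cl]]$values
    keep <- vapply(ranges, `[[`, "", "v_class") == cl
    oracle <- oracle_vertebrate_raw(ranges[keep], cover$values, areas$area, g)
    expect_equal(mine, oracle, tolerance = 1e-12)
  }
})

test_that("splitting a range into disjoint halves preserves raw scores", {
  g <- rs_grid(10, 10, 0.1, origin = c(100, 16))
  areas <- cell_areas(g)
  whole <- rect_poly(100.05, 15.25, 100.75, 15.85)
  left <- rect_poly(100.05, 15.25, 100.45, 15.85)
  right <- rect_poly(100.45001, 15.25, 100.75, 15.85)
  a_tot <- 3000
  cover <- rs_surface(g, matrix(runif(100), 10))
  suppressWarnings({
    s_whole <- vertebrate_importance(
      list(rs_species_range("w", "mammal", whole, a_tot)), cover, areas)
    s_split <- vertebrate_importance(
      list(rs_species_range("l", "mammal", left, a_tot),
           rs_species_range("r", "mammal", right, a_tot)), cover, areas)
  })
  raw_w <- attr(s_whole, "raw_class_surfaces")$mammal$values
  raw_s <- attr(s_split, "raw_class_surfaces")$mammal$values
  # cells covered by exactly one half score the same; the boundary column
  # (touched by both halves) may count twice, so compare off-boundary
  boundary_col <- 5
  expect_equal(raw_w[, -boundary_col], raw_s[, -boundary_col])
})

test_that("an empty class is skipped with a warning", {
  g <- tiny_grid(5, 5)
  areas <- cell_areas(g)
  sp <- list(rs_species_range("s1", "mammal",
                              rect_poly(100, 14.6, 100.4, 15), 500))
  cover <- rs_surface(g, matrix(1, 5, 5))
  w <- capture_warnings(vertebrate_importance(sp, cover, areas))
  expect_match(w, "bird", all = FALSE)
  expect_match(w, "amphibian", all = FALSE)
  expect_error(rs_species_range("bad", "mammal",
                                rect_poly(0, 0, 1, 1), 0), "range_area")
})

test_that("carbon cost applies the 10% soil rule and floors at zero", {
  # 1 degree cells near the equator are ~100x100 km; use a synthetic area
  g <- rs_grid(2, 5, 0.5, origin = c(100, 1))
  areas <- cell_areas(g)
  bio <- rs_surface(g, matrix(120, 2, 5)); soil <- rs_surface(g, matrix(60, 2, 5))
  cover <- rs_surface(g, matrix(1, 2, 5))
  out <- carbon_cost(bio, soil, cover, areas)
  raw <- attr(out, "raw")$values
  expect_equal(raw[1, 1], (120 - 6) * areas$area[1, 1] * 100)
  # biomass 0 -> net loss <= 0 -> floored
  out0 <- carbon_cost(rs_surface(g, matrix(0, 2, 5)), soil, cover, areas)
  expect_true(all(attr(out0, "raw")$values == 0))
  expect_error(carbon_cost(rs_surface(g, matrix(-1, 2, 5)), soil, cover,
                           areas), "non-negative")
})

test_that("carbon cost matches a scalar loop oracle and is linear in cover", {
  set.seed(32)
  g <- tiny_grid(15, 15)
  areas <- cell_areas(g)
  bio <- surf(matrix(runif(225, 0, 200), 15), g)
  soil <- surf(matrix(runif(225, 0, 150), 15), g)
  cover <- surf(matrix(runif(225), 15), g)
  out <- carbon_cost(bio, soil, cover, areas)
  expect_equal(attr(out, "raw")$values,
               oracle_carbon_raw(bio$values, soil$values, cover$values,
                                 areas$area))
  half <- carbon_cost(bio, soil, surf(cover$values / 2, g), areas)
  expect_equal(attr(half, "raw")$values, attr(out, "raw")$values / 2)
})

test_that("climate cost follows the assign-rescale-weight-mean recipe", {
  set.seed(33)
  g <- tiny_grid(10, 10)
  eco_ids <- matrix(sample(1:5, 100, replace = TRUE), 10)
  idx <- data.frame(ecoregion_id = 1:5, hri = runif(5, 1, 4),
                    mri = runif(5, 0.5, 3))
  cover <- surf(matrix(runif(100), 10), g)
  out <- climate_cost(surf(eco_ids, g), idx, cover)
  # independent step-by-step oracle
  hri_cells <- idx$hri[eco_ids]; mri_cells <- idx$mri[eco_ids]
  step <- (oracle_midrank_rescale(hri_cells) * as.vector(cover$values) +
             oracle_midrank_rescale(mri_cells) * as.vector(cover$values)) / 2
  expect_equal(as.vector(out$values), oracle_midrank_rescale(step))
})

test_that("climate cost degenerate structures behave as documented", {
  g <- tiny_grid(6, 6)
  idx1 <- data.frame(ecoregion_id = 1, hri = 2, mri = 1)
  cover <- surf(matrix(runif(36), 6), g)
  one <- climate_cost(surf(matrix(1, 6, 6), g), idx1, cover)
  expect_equal(cor(as.vector(one$values), as.vector(cover$values),
                   method = "spearman"), 1)
  # full cover, 2 ecoregions -> exactly 2 levels
  ids2 <- matrix(rep(1:2, each = 18), 6)
  idx2 <- data.frame(ecoregion_id = 1:2, hri = c(1, 3), mri = c(0.5, 2))
  two <- climate_cost(surf(ids2, g), idx2, surf(matrix(1, 6, 6), g))
  expect_length(unique(as.vector(two$values)), 2)
  expect_error(climate_cost(surf(matrix(7, 6, 6), g), idx2, cover),
               "no indices for ecoregion")
})

test_that("cost aggregation matches loop oracles under both rules", {
  set.seed(34)
  g <- tiny_grid(12, 12)
  layers <- replicate(3, random_rescaled(g), simplify = FALSE)
  mats <- lapply(layers, `[[`, "values")
  for (rule in c("mean", "max")) {
    agg <- aggregate_cost(layers, rule = rule, final_rescale = FALSE)
    expect_equal(agg$values, oracle_aggregate(mats, rule))
  }
  # pre-rescale max >= mean everywhere
  expect_true(all(oracle_aggregate(mats, "max") >=
                    oracle_aggregate(mats, "mean"), na.rm = TRUE))
  # identical layers: both rules give a monotone relabeling of the input
  same <- list(layers[[1]], layers[[1]], layers[[1]])
  for (rule in c("mean", "max"))
    expect_equal(cor(as.vector(aggregate_cost(same, rule)$values),
                     as.vector(layers[[1]]$values), method = "spearman"), 1)
  expect_error(aggregate_cost(list(surf(matrix(2, 12, 12), g))), "0-1")
})
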