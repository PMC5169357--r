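test_that("road density handles the simple textbook cases", {
  # straight level-1 road crossing one cell row fully, west to east
  g <- rs_grid(3, 3, 0.1, origin = c(100, 1))   # near-equator 0.1 deg cells
  areas <- cell_areas(g)
  mid_lat <- cell_centres(g)$lat[2]
  rd <- rs_road("r1", 1, cbind(c(99.9, 100.4), c(mid_lat, mid_lat)))
  dens <- road_density(list(rd), g, areas)
  # each middle-row cell contains exactly one cell-width of road
  expected <- hav_km(100, mid_lat, 100.1, mid_lat) / areas$area[2, 1]
  expect_equal(dens$values[2, 1], expected, tolerance = 1e-9)
  expect_equal(dens$values[2, 2], expected, tolerance = 1e-9)
  expect_true(all(dens$values[c(1, 3), ] == 0))
  # level-4-only network with the default filter -> all zero
  rd4 <- rs_road("r4", 4, rd$coords)
  expect_true(all(road_density(list(rd4), g, areas)$values == 0))
  expect_equal(dens$units, "km/km2")
})

test_that("road density matches a per-cell clipping oracle", {
  set.seed(51)
  g <- rs_grid(20, 20, 0.1, origin = c(100, 16))
  areas <- cell_areas(g)
  network <- lapply(1:20, function(i) {
    n_pts <- sample(2:5, 1)
    rs_road(paste0("r", i), sample(1:4, 1),
            cbind(runif(n_pts, 99.8, 102.2), runif(n_pts, 13.8, 16.2)))
  })
  dens <- road_density(network, g, areas, levels = 1:3)
  oracle_len <- oracle_road_length_per_cell(network, g, levels = 1:3)
  expect_equal(dens$values, oracle_len / areas$area, tolerance = 1e-6)
  # total length conservation: sum(density * area) = clipped network length
  expect_equal(sum(dens$values * areas$area), sum(oracle_len),
               tolerance = 1e-4)
})

test_that("buffer membership is by centre distance and grows monotonically", {
  g <- rs_grid(15, 15, 0.1, origin = c(100, 16))
  cc <- cell_centres(g)
  # road passing exactly through a cell centre: included at any width
  rd <- rs_road("p", "proposal",
                cbind(c(cc$lon[7] - 0.3, cc$lon[7] + 0.3),
                      c(cc$lat[8], cc$lat[8])))
  tiny <- buffer_cells(rd, g, width_km = 0.1)
  expect_true(any(tiny$row == 8 & tiny$col == 7))
  widths <- c(2, 5, 10, 20)
  sets <- lapply(widths, function(w) buffer_cells(rd, g, w))
  for (k in 2:4) {
    prev <- paste(sets[[k - 1]]$row, sets[[k - 1]]$col)
    cur <- paste(sets[[k]]$row, sets[[k]]$col)
    expect_true(all(prev %in% cur))
  }
  expect_error(buffer_cells(rd, g, -1), "width_km")
})

test_that("buffer distances agree with an independent geodesic oracle", {
  g <- rs_grid(15, 15, 0.1, origin = c(100, 16))
  cc <- cell_centres(g)
  rd <- rs_road("p", "proposal",
                cbind(c(100.2, 101.1, 101.4), c(15.2, 15.6, 14.9)))
  width <- 12
  cells <- buffer_cells(rd, g, width)
  in_set <- matrix(FALSE, 15, 15)
  in_set[cbind(cells$row, cells$col)] <- TRUE
  # oracle: geosphere dist2Line on the WGS84 ellipsoid
  pts <- cbind(as.vector(cell_centres(g)$lon_mat),
               as.vector(cell_centres(g)$lat_mat))
  d_oracle <- geosphere::dist2Line(pts, rd$coords)[, 1] / 1000
  claimed <- as.vector(in_set)
  # allow disagreement only within 3% of the width: the package uses a
  # spherical tangent-plane distance, the oracle the WGS84 ellipsoid
  definite_in <- d_oracle < width * 0.97
  definite_out <- d_oracle > width * 1.03
  expect_true(all(claimed[definite_in]))
  expect_true(all(!claimed[definite_out]))
})

test_that("road summaries are buffer means of each surface", {
  set.seed(52)
  g <- rs_grid(15, 15, 0.1, origin = c(100, 16))
  rd <- rs_road("P1", "proposal", cbind(c(100.2, 101.2), c(15.2, 15.5)))
  const <- rs_surface(g, matrix(7.5, 15, 15), "u")
  s_rand <- rs_surface(g, matrix(rnorm(225), 15), "v")
  sm <- road_summary(rd, list(a = const, b = s_rand), g, width_km = 10)
  expect_equal(sm$mean_a, 7.5)
  cells <- buffer_cells(rd, g, 10)
  expect_equal(sm$n_buffer_cells, nrow(cells))
  # loop oracle for the mean
  acc <- 0
  for (k in seq_len(nrow(cells)))
    acc <- acc + s_rand$values[cells$row[k], cells$col[k]]
  expect_equal(sm$mean_b, acc / nrow(cells))
  expect_gte(sm$mean_b, min(s_rand$values[cbind(cells$row, cells$col)]))
  expect_lte(sm$mean_b, max(s_rand$values[cbind(cells$row, cells$col)]))
  # all-NoData surface in the buffer reported as missing
  na_vals <- matrix(NA_real_, 15, 15); na_vals[15, 15] <- 1
  mask <- matrix(TRUE, 15, 15)
  s_na <- rs_surface(g, na_vals, "w")
  sm2 <- road_summary(rd, list(w = s_na), g, width_km = 5)
  expect_true(is.na(sm2$mean_w))
})

test_that("single-cell buffers reduce to that cell's values", {
  g <- rs_grid(9, 9, 0.1, origin = c(100, 10))
  cc <- cell_centres(g)
  rd <- rs_road("P1", "proposal",
                cbind(c(cc$lon[5] - 0.001, cc$lon[5] + 0.001),
                      c(cc$lat[5], cc$lat[5])))
  s <- rs_surface(g, matrix(seq_len(81), 9), "u")
  sm <- road_summary(rd, list(u = s), g, width_km = 0.5)
  expect_equal(sm$n_buffer_cells, 1)
  expect_equal(sm$mean_u, s$values[5, 5])
})

test_that("road profiles traverse cells in order and dedupe on first entry", {
  g <- rs_grid(10, 10, 0.1, origin = c(100, 11))
  ben <- random_rescaled(g); cst <- random_rescaled(g)
  mid <- cell_centres(g)$lat[4]
  rd <- rs_road("T1", "proposal",
                cbind(c(100.05, 100.55), c(mid, mid)))  # crosses 5+ cells
  pr <- road_profile(rd, ben, cst, g)
  expect_equal(pr$row, rep(4, nrow(pr)))
  expect_equal(pr$col, seq_len(nrow(pr)))
  expect_true(all(diff(pr$dist_km) > 0))
  expect_equal(pr$benefit, ben$values[cbind(pr$row, pr$col)])
  # closed loop: each cell once
  loop <- rs_road("L", "proposal",
                  cbind(c(100.15, 100.75, 100.75, 100.15, 100.15),
                        c(10.85, 10.85, 10.25, 10.25, 10.85)))
  pl <- road_profile(loop, ben, cst, g)
  expect_equal(anyDuplicated(paste(pl$row, pl$col)), 0)
  # outside the grid -> degenerate input
  far <- rs_road("F", "proposal", cbind(c(10, 11), c(0, 0)))
  expect_error(road_profile(far, ben, cst, g), "degenerate")
})

test_that("random profiles match a dense-sampling oracle; reversal reverses", {
  set.seed(53)
  g <- rs_grid(20, 20, 0.1, origin = c(100, 16))
  ben <- random_rescaled(g); cst <- random_rescaled(g)
  for (k in 1:5) {
    n_pts <- sample(3:6, 1)
    cd <- cbind(runif(n_pts, 100.05, 101.95), runif(n_pts, 14.05, 15.95))
    rd <- rs_road(paste0("T", k), "proposal", cd)
    pr <- road_profile(rd, ben, cst, g)
    oracle <- oracle_profile_cells(cd, g)
    expect_equal(pr[, c("row", "col")], oracle, ignore_attr = TRUE)
    # reversed polyline visits the same cells in reverse order
    rev_rd <- rs_road("rev", "proposal", cd[n_pts:1, ])
    pr_rev <- road_profile(rev_rd, ben, cst, g)
    expect_setequal(paste(pr$row, pr$col), paste(pr_rev$row, pr_rev$col))
    expect_equal(utils::tail(pr_rev$col, 1), pr$col[1])
    expect_equal(utils::tail(pr_rev$row, 1), pr$row[1])
  }
})
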