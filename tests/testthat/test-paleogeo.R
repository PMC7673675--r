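tide0 <- list(aM2_m = 1.8, aS2_m = 0.6)   # +/- 2.4 m springs

test_that("spring water levels are the constituent-amplitude sum", {
  expect_equal(water_levels(tide0), c(MHWS = 2.4, MLWS = -2.4))
  expect_equal(water_levels(list(aM2_m = 0, aS2_m = 0)),
               c(MHWS = 0, MLWS = 0))
  # doubling both amplitudes doubles the band width
  w1 <- water_levels(tide0)
  w2 <- water_levels(list(aM2_m = 3.6, aS2_m = 1.2))
  expect_equal(w2["MHWS"] - w2["MLWS"], 2 * (w1["MHWS"] - w1["MLWS"]))
  expect_error(water_levels(list(aM2_m = -1, aS2_m = 0)), ">= 0")
})

test_that("reconstruction classifies cells against the tidal frame", {
  plate <- make_dem(list(type = "plate", height = 10, extent = 1000), 10)
  g <- reconstruct(plate, rsl = -20, tide0)
  expect_equal(g$intertidal_area_km2, 0)
  expect_equal(g$land_area_km2, 1)        # all 100x100 cells of 100 m2
  expect_equal(g$island_count, 1)
  # cone island: land area above the MHWS contour matches the analytic
  # cone cross-section within 1%
  cone <- make_dem(list(type = "cone", peak = 20, radius = 1000,
                        extent = 2500), 10)
  g2 <- reconstruct(cone, rsl = 0, list(aM2_m = 1.5, aS2_m = 0.5))
  expect_lt(abs(g2$land_area_km2 * 1e6 / (pi * (1000 * 0.9)^2) - 1), 0.01)
  # full submergence
  g3 <- reconstruct(cone, rsl = 25, tide0)
  expect_equal(g3$land_area_km2, 0)
  expect_equal(g3$island_count, 0)
  # a cell exactly at MHWS is intertidal, not land (closed upper bound)
  z <- matrix(c(2.4, 5, -5, -5), 2, 2)
  g4 <- reconstruct(elevation_grid(z, 10), rsl = 0, tide0)
  expect_equal(g4$n_land, 1)
  expect_equal(g4$n_intertidal, 1)
  expect_error(reconstruct(elevation_grid(matrix(NA_real_, 2, 2), 10),
                           0, tide0), "all-nodata")
})

test_that("island counting uses 8-connectivity by default", {
  one <- matrix(FALSE, 5, 5); one[2:3, 2:4] <- TRUE
  expect_equal(island_count(one), 1)
  two <- matrix(FALSE, 5, 7); two[2:3, 2] <- TRUE; two[2:3, 5:6] <- TRUE
  expect_equal(island_count(two), 2)
  # two blocks touching only at a corner
  diag <- matrix(FALSE, 4, 4); diag[1:2, 1:2] <- TRUE; diag[3:4, 3:4] <- TRUE
  expect_equal(island_count(diag), 1)                      # 8-connected
  expect_equal(island_count(diag, connectivity = 4), 2)    # 4-connected
  expect_equal(island_count(matrix(FALSE, 3, 3)), 0)
  # minimum-size screening drops single-cell skerries
  sk <- two; sk[5, 7] <- TRUE
  expect_equal(island_count(sk), 3)
  expect_equal(island_count(sk, min_cells = 2), 2)
})

test_that("cell classes are conserved at every epoch", {
  dem <- make_dem(default_island_shape(6000), 150, seed = 2)
  dem$z[1:3, 1:5] <- NA    # nodata margin
  rsl <- data.frame(time_ka = 0:8,
                    rsl_m = scilly_like_truth()$rsl_truth(0:8))
  ser <- area_series(dem, rsl, make_tide_history(0:9))
  total <- prod(dim(dem$z))
  expect_true(all(ser$n_land + ser$n_intertidal + ser$n_subtidal +
                    ser$n_nodata == total))
  expect_true(all(ser$n_nodata == 15))
  # monotone forcing on a cone: land area non-increasing toward present
  cone <- make_dem(list(type = "cone", peak = 30, radius = 2000,
                        extent = 5000), 50)
  ser2 <- area_series(cone, rsl, make_tide_history(0:9))
  young_to_old <- order(ser2$time_ka)
  expect_true(all(diff(ser2$land_km2[young_to_old]) >= 0))
  # constant forcing: every epoch identical
  ser3 <- area_series(cone, data.frame(time_ka = 0:3, rsl_m = -5),
                      data.frame(time_ka = c(0, 9), aM2_m = 1.8,
                                 aS2_m = 0.6))
  expect_equal(length(unique(ser3$land_km2)), 1)
  expect_equal(length(unique(ser3$intertidal_km2)), 1)
})

test_that("a low-gradient shelf produces the intertidal spike", {
  # two-level DEM: high plateau plus a broad shelf at -1 m
  z <- matrix(-1, 40, 40); z[1:10, 1:40] <- 20
  dem <- elevation_grid(z, 100)
  tides <- data.frame(time_ka = c(0, 9), aM2_m = 0.9, aS2_m = 0.3)
  rsl <- data.frame(time_ka = c(6, 4, 2), rsl_m = c(-10, -1, 5))
  ser <- area_series(dem, rsl, tides)
  # band (+/- 1.2 m) off the shelf at 6 ka, crossing it at 4 ka
  s <- ser[order(ser$time_ka, decreasing = TRUE), ]
  expect_equal(s$intertidal_km2[1], 0)
  expect_equal(s$intertidal_km2[2], 30 * 40 * 0.01)  # whole shelf
  expect_equal(s$intertidal_km2[3], 0)
})

test_that("areas are stable under grid refinement", {
  shp <- list(type = "paraboloid", peak = 25, radius = 1500, extent = 4000)
  a <- vapply(c(50, 25), function(cs) {
    g <- reconstruct(make_dem(shp, cs), rsl = -3, tide0)
    g$land_area_km2
  }, numeric(1))
  expect_lt(abs(a[2] / a[1] - 1), 0.02)
})

test_that("change metrics rescale per-millennium rates to human windows", {
  # the 5-4 ka interval: -10 km2 land, +5 km2 intertidal per millennium
  s <- data.frame(time_ka = c(5, 4), land_km2 = c(27.8, 17.8),
                  intertidal_km2 = c(7.8, 12.8))
  life <- change_metrics(s, 70)
  expect_equal(life$land_change_m2, -70 * 1e4)        # -700,000 m2
  expect_equal(life$intertidal_change_m2, 350000)
  dec <- change_metrics(s, 10)
  expect_equal(dec$land_change_m2, -100000)
  expect_equal(dec$land_change_pct, -100 * 0.1 / 27.8)  # ~ -0.36%
  expect_gte(dec$intertidal_change_m2, 50000)
  # 12.5 km2/millennium over a 70-yr lifespan: 875,000 m2
  s2 <- data.frame(time_ka = c(6, 5), land_km2 = c(40, 27.5),
                   intertidal_km2 = c(5, 6))
  expect_equal(change_metrics(s2, 70)$land_change_m2, -875000)
  # degenerate cases
  s3 <- data.frame(time_ka = c(5, 4), land_km2 = c(20, 20),
                   intertidal_km2 = c(5, 5))
  expect_equal(change_metrics(s3, 70)$land_change_m2, 0)
  expect_error(change_metrics(s, 2000), "exceeds")
})

test_that("lateral inundation rate follows displacement over time", {
  # uniform slope 0.001 m/m: a 1 m rise in 1000 yr moves the shoreline
  # 1000 m, i.e. 1 m/yr
  plane <- make_dem(list(type = "plane", base = 0, gradient = -0.001,
                         extent = 8000), 20)
  tides <- list(aM2_m = 0.8, aS2_m = 0.2)
  g1 <- reconstruct(plane, rsl = -3, tides, time_ka = 5)
  g2 <- reconstruct(plane, rsl = -2, tides, time_ka = 4)
  tr <- cbind(row = 200, col = 1:400)
  expect_equal(lateral_rate(g1, g2, tr), 1.0, tolerance = 1e-6)
  # no sea-level change: zero lateral rate
  g3 <- reconstruct(plane, rsl = -3, tides, time_ka = 4)
  expect_equal(lateral_rate(g1, g3, tr), 0)
  # vertical cliff: shoreline pinned despite the rise below the crest
  z <- matrix(10, 50, 50); z[, 26:50] <- -100
  cliff <- elevation_grid(z, 10)
  c1 <- reconstruct(cliff, rsl = -20, tides, time_ka = 5)
  c2 <- reconstruct(cliff, rsl = -19, tides, time_ka = 4)
  expect_lt(lateral_rate(c1, c2, cbind(row = 25, col = 1:50)), 0.01)
  # transect that never crosses the shoreline
  expect_error(lateral_rate(g1, g2, cbind(row = 200, col = 1:3)),
               "cross")
})
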