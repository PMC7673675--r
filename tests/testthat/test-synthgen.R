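test_that("ground truth is internally consistent", {
  tr <- scilly_like_truth()
  # rate is the derivative of the level history (interior points, < 1%)
  for (t0 in c(1.3, 3.7, 5.2, 6.8)) {
    h <- 1e-4
    num <- -(tr$rsl_truth(t0 + h) - tr$rsl_truth(t0 - h)) / (2 * h)
    expect_lt(abs(num / tr$rate_truth(t0) - 1), 0.01)
  }
  # population curves are nonnegative densities integrating to 1
  for (pop in tr$population_curves) {
    grid <- seq(tr$pop_support[1], tr$pop_support[2], length.out = 2000)
    expect_true(all(pop(grid) >= 0))
    expect_equal(integrate(pop, tr$pop_support[1], tr$pop_support[2],
                           subdivisions = 500)$value, 1, tolerance = 1e-4)
  }
})

test_that("parametric DEMs match analytic hypsometry", {
  # degenerate flat plate: every cell exactly at +10 m
  plate <- make_dem(list(type = "plate", height = 10, extent = 1000),
                    cell_size = 10, seed = 1)
  expect_true(all(plate$z == 10))
  # cone: area above contour z is pi * (R * (1 - z/peak))^2
  cone <- make_dem(list(type = "cone", peak = 20, radius = 1000,
                        extent = 2500), cell_size = 10, seed = 1)
  for (zc in c(0, 5, 10)) {
    grid_area <- sum(cone$z > zc) * 10^2
    true_area <- pi * (1000 * (1 - zc / 20))^2
    expect_lt(abs(grid_area / true_area - 1), 0.01)
  }
  # paraboloid: area above z is pi * R^2 * (1 - z/peak)
  par <- make_dem(list(type = "paraboloid", peak = 20, radius = 1000,
                       extent = 2500), cell_size = 10, seed = 1)
  expect_lt(abs(sum(par$z > 5) * 100 / (pi * 1e6 * (1 - 5 / 20)) - 1), 0.01)
})

test_that("generators are bit-reproducible and substream-isolated", {
  shape <- default_island_shape()
  d1 <- make_dem(shape, 100, seed = 7)
  d2 <- make_dem(shape, 100, seed = 7)
  expect_identical(d1$z, d2$z)
  expect_false(identical(d1$z, make_dem(shape, 100, seed = 8)$z))
  tr <- linear_truth()
  s1 <- sample_slips(tr, 20, seed = 3)
  # an unrelated generator call in between must not shift the stream
  invisible(make_dem(shape, 200, seed = 99))
  s2 <- sample_slips(tr, 20, seed = 3)
  expect_identical(s1, s2)
})

test_that("make_dem rejects bad specifications", {
  expect_error(make_dem(list(type = "plate", height = 1, extent = 100), 0),
               "cell_size")
  expect_error(make_dem(list(type = "cone", peak = 10, radius = 500,
                             extent = 600), 10), "footprint")
  expect_error(make_dem(list(type = "nosuch", extent = 100), 10), "unknown")
})

test_that("SLIP sampling honours its noise specification", {
  tr <- scilly_like_truth()
  # noise-free points lie exactly on the truth curve
  s0 <- sample_slips(tr, 50, age_sd = 0, elev_sd = 0,
                     limiting_fraction = 0, seed = 2)
  expect_equal(s0$S_m, tr$rsl_truth(s0$age_ka), tolerance = 1e-12)
  expect_true(all(s0$kind == "precise"))
  # large-n elevation scatter matches the requested sd
  s1 <- sample_slips(tr, 1000, age_sd = 0, elev_sd = 0.3, seed = 4)
  resid <- s1$S_m - tr$rsl_truth(attr(s1, "true_age_ka"))
  expect_gt(sd(resid), 0.27)
  expect_lt(sd(resid), 0.33)
  # limiting points sit on the correct side of the truth curve
  s2 <- sample_slips(tr, 400, age_sd = 0, elev_sd = 0,
                     limiting_fraction = 0.5, seed = 5)
  truth_at <- tr$rsl_truth(attr(s2, "true_age_ka"))
  mar <- s2$kind == "marine_limiting"
  ter <- s2$kind == "terrestrial_limiting"
  expect_gt(sum(mar), 0); expect_gt(sum(ter), 0)
  expect_true(all(s2$S_m[mar] <= truth_at[mar]))
  expect_true(all(s2$S_m[ter] >= truth_at[ter]))
  # an all-limiting dataset is unusable downstream
  s3 <- sample_slips(tr, 30, limiting_fraction = 1, seed = 6)
  expect_error(score_chi2(data.frame(time_ka = c(0, 10),
                                     rsl_m = c(0, -10)), s3),
               "precise")
})

test_that("radiocarbon sampling follows the population curve", {
  # point-mass population on a zero-error linear curve: exact 14C ages
  cc0 <- make_calcurve(span = c(0, 8000), step = 5, curve_sd = 0)
  pop <- function(t) rep(1, length(t))
  d0 <- sample_radiocarbon(pop, cc0, n = 20, err = 0, seed = 1,
                           support = c(5, 5))
  expect_true(all(d0$c14_age == 5000))
  # uniform population: drawn calendar ages pass a KS test at alpha 0.01
  cc <- make_calcurve(span = c(0, 8000), step = 5, curve_sd = 8)
  d1 <- sample_radiocarbon(function(t) rep(1 / 3, length(t)), cc,
                           n = 5000, err = 25, seed = 2, support = c(3, 6))
  ks <- suppressWarnings(
    stats::ks.test(attr(d1, "true_cal_bp"), "punif", 3000, 6000))
  expect_gt(ks$p.value, 0.01)
  # support outside the curve span is rejected
  expect_error(sample_radiocarbon(pop, cc, n = 5, support = c(1, 20)),
               "span")
})

test_that("monument sampling respects mix and unknown flags", {
  pw <- data.frame(start_bp = c(5000, 3000), end_bp = c(4000, 2000))
  m <- sample_monuments(10000, pw, mix = c(0.5, 0.5),
                        unknown_fraction = 0, seed = 1)
  n1 <- sum(m$start_bp == 5000)
  expect_lt(abs(n1 - 5000), 3 * sqrt(10000 * 0.25))
  mu <- sample_monuments(50, pw, unknown_fraction = 1, seed = 2)
  expect_true(all(!mu$known))
  expect_equal(attr(aoristic_sum(mu), "n_known"), 0)
  expect_error(sample_monuments(5, data.frame(start_bp = 1, end_bp = 2)),
               "malformed")
})

test_that("pollen sampling counts exactly the land-pollen stopping total", {
  pol <- sample_pollen(seq(0, 1, length.out = 20), taxa = 6,
                       counts_per_sample = 300, halophyte_cluster = TRUE,
                       seed = 3)
  taxa <- attr(pol, "taxon_names")
  expect_true(all(rowSums(pol[taxa]) == 300))
  expect_true(any(pol$is_halophyte_truth))
  halo <- pol[pol$is_halophyte_truth, "Halophyte"]
  expect_true(all(halo / 300 > 0.5))       # halophyte-dominated block
  expect_true(all(pol$Halophyte[!pol$is_halophyte_truth] == 0))
})

test_that("file interchange round-trips", {
  dir <- withr::local_tempdir()
  dem <- make_dem(default_island_shape(4000), 200, seed = 1)
  dem$z[3, 4] <- NA
  f <- file.path(dir, "dem.asc")
  write_ascii_grid(dem, f)
  back <- read_ascii_grid(f)
  expect_equal(back$z, dem$z, tolerance = 1e-6)
  expect_equal(back$cell_size, dem$cell_size)

  s <- sample_slips(scilly_like_truth(), 12, seed = 1)
  fs <- file.path(dir, "slips.csv")
  write_slips(s, fs)
  expect_equal(read_slips(fs)$S_m, s$S_m)
  expect_s3_class(read_slips(fs), "slip_table")

  cc <- make_calcurve(span = c(0, 1000), step = 10, wiggle_amp = 10)
  fc <- file.path(dir, "cc.csv")
  write_calcurve(cc, fc)
  expect_equal(read_calcurve(fc)$c14_bp, cc$c14_bp)

  expect_error(read_slips(fc), "missing column")
})
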