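lincurve <- function(span = c(0, 9000), step = 5, sd = 0)
  make_calcurve(span = span, step = step, curve_sd = sd)

test_that("calibration matches the closed form on a linear curve", {
  cc <- lincurve()
  d <- calibrate(list(c14_age = 5000, c14_error = 50), cc)
  expect_lt(max(abs(d$density - dnorm(cc$cal_bp, 5000, 50))), 1e-6)
  # normalization
  dn <- calibrate(list(c14_age = 5000, c14_error = 50), cc,
                  normalized = TRUE)
  expect_equal(sum(dn$density), 1, tolerance = 1e-9)
  # round trip: density median maps back near the 14C age
  med <- dn$cal_bp[which.min(abs(cumsum(dn$density) - 0.5))]
  expect_lt(abs(med - 5000), 50)
  # guards
  expect_error(calibrate(list(c14_age = 20000, c14_error = 30), cc),
               "outside")
  expect_error(calibrate(list(c14_age = 5000, c14_error = 0), cc),
               "zero combined sigma")
})

test_that("a wiggle in the curve produces multimodal densities", {
  # constructed curve crossing 14C age 3000 three times
  grid <- seq(2000, 4000, by = 1)
  mu <- grid + 80 * sin(2 * pi * (grid - 2000) / 1000)
  cc <- calibration_curve(grid, mu, rep(0, length(grid)))
  d <- calibrate(list(c14_age = 3000, c14_error = 15), cc)
  crossings <- grid[which(diff(sign(mu - 3000)) != 0)]
  # every crossing hosts a local maximum of the calibrated density
  for (cr in crossings) {
    win <- abs(d$cal_bp - cr) < 30
    expect_gt(max(d$density[win]), 0.5 * max(d$density))
  }
  expect_gt(length(crossings), 1)
})

test_that("site binning follows the greedy 50-year rule", {
  d <- data.frame(site_id = c("s1", "s1", "s1", "s2"),
                  c14_age = c(4000, 4030, 4070, 4000))
  # anchored at 4000: 4030 joins, 4070 is 70 > 50 away -> new bin
  b <- bin_dates(d, bin_width = 50)
  expect_equal(b[1], b[2])
  expect_false(b[2] == b[3])
  # identical ages at different sites never share a bin
  expect_false(b[1] == b[4])
  # order independence
  d2 <- d[c(3, 1, 4, 2), ]
  b2 <- bin_dates(d2, 50)
  expect_equal(b2[2], b2[4])     # 4000 and 4030 of s1 still together
  # single date, single bin
  expect_equal(length(unique(bin_dates(d[1, , drop = FALSE]))), 1)
})

test_that("SPD aggregation averages within bins and sums across", {
  cc <- lincurve(sd = 8)
  one <- data.frame(lab_id = "a", site_id = "s1", region = "r",
                    c14_age = 4000, c14_error = 30)
  s1 <- spd(one, cc)
  d1 <- calibrate(one, cc)
  expect_equal(s1$density, d1$density)
  expect_equal(attr(s1, "n_bins"), 1)
  # duplicate date, same site: same bin, so the SPD is unchanged
  twin <- rbind(one, transform(one, lab_id = "b"))
  expect_equal(spd(twin, cc)$density, d1$density)
  # duplicate date, different site: doubles
  twin2 <- rbind(one, transform(one, lab_id = "b", site_id = "s2"))
  expect_equal(spd(twin2, cc)$density, 2 * d1$density)
  # mass invariance under date order and site relabeling
  set.seed(2)
  many <- data.frame(lab_id = letters[1:10],
                     site_id = rep(c("x", "y"), 5),
                     region = "r",
                     c14_age = runif(10, 3000, 6000), c14_error = 30)
  ref <- spd(many, cc)$density
  expect_equal(spd(many[sample(10), ], cc)$density, ref)
  relab <- transform(many, site_id = ifelse(site_id == "x", "q", "y"))
  expect_equal(spd(relab, cc)$density, ref)
})

test_that("permutation test flags a constructed regional contrast", {
  cc <- lincurve(span = c(0, 9000), step = 20, sd = 8)
  set.seed(5)
  early <- data.frame(lab_id = sprintf("e%02d", 1:60),
                      site_id = sprintf("se%d", rep(1:12, 5)),
                      region = "A",
                      c14_age = runif(60, 5000, 6000), c14_error = 30)
  late <- data.frame(lab_id = sprintf("l%02d", 1:60),
                     site_id = sprintf("sl%d", rep(1:12, 5)),
                     region = "B",
                     c14_age = runif(60, 2000, 3000), c14_error = 30)
  env <- permutation_test(rbind(early, late), cc, n_perm = 200, seed = 1,
                          smooth_halfwidth = 60)
  a <- env$A; b <- env$B
  win_a <- a$cal_bp > 5150 & a$cal_bp < 5850
  win_b <- a$cal_bp > 2150 & a$cal_bp < 2850
  # region A: positive departure in its own window, negative in B's
  expect_gt(mean(a$flag[win_a] == "+"), 0.5)
  expect_gt(mean(a$flag[win_b] == "-"), 0.5)
  expect_gt(mean(b$flag[win_b] == "+"), 0.5)
  expect_gt(mean(b$flag[win_a] == "-"), 0.5)
  # determinism
  env2 <- permutation_test(rbind(early, late), cc, n_perm = 200, seed = 1,
                           smooth_halfwidth = 60)
  expect_identical(env, env2)
  # guards
  expect_error(permutation_test(early, cc), "2 regions")
  expect_error(permutation_test(rbind(early, late), cc, n_perm = 50),
               "unstable")
})

test_that("envelope flags are nested across significance levels", {
  cc <- lincurve(span = c(0, 9000), step = 40, sd = 8)
  set.seed(9)
  d <- data.frame(lab_id = sprintf("d%02d", 1:60),
                  site_id = sprintf("s%d", rep(1:10, 6)),
                  region = rep(c("A", "B"), 30),
                  c14_age = runif(60, 2000, 7000), c14_error = 30)
  e10 <- permutation_test(d, cc, n_perm = 200, alpha = 0.10, seed = 2)
  e01 <- permutation_test(d, cc, n_perm = 200, alpha = 0.01, seed = 2)
  # flags at the stricter level are a subset of the looser level's
  expect_true(all(which(e01$A$flag != "") %in% which(e10$A$flag != "")))
})

test_that("aoristic sums spread unit mass over period windows", {
  # window exactly one bin
  m1 <- data.frame(start_bp = 4000, end_bp = 3800, known = TRUE)
  a1 <- aoristic_sum(m1, 200)
  expect_equal(sum(a1$mass), 1)
  expect_equal(max(a1$mass), 1)
  # window spanning four bins: 0.25 each
  m4 <- data.frame(start_bp = 4000, end_bp = 3200, known = TRUE)
  a4 <- aoristic_sum(m4, 200)
  expect_equal(sort(unique(round(a4$mass[a4$mass > 0], 10))), 0.25)
  expect_equal(sum(a4$mass > 0), 4)
  # conservation on an arbitrary inventory to 1e-9
  pw <- data.frame(start_bp = c(6000, 4400, 3500, 1500),
                   end_bp = c(4400, 3500, 2800, 1000))
  mm <- sample_monuments(500, pw, unknown_fraction = 0.2, seed = 3)
  aa <- aoristic_sum(mm, 200)
  expect_equal(sum(aa$mass), sum(mm$known), tolerance = 1e-9)
  expect_equal(attr(aa, "n_known"), sum(mm$known))
  # zero-length window: point mass in its containing bin
  mp <- data.frame(start_bp = 3890, end_bp = 3890, known = TRUE)
  ap <- aoristic_sum(mp, 200, span = c(3000, 4200))
  expect_equal(sum(ap$mass), 1)
  expect_equal(ap$mass[ap$bin_end_bp == 3800], 1)
  # bin-origin shift conserves mass and moves it at most one bin
  sh <- aoristic_sum(m4, 200, span = c(3100, 4100))
  expect_equal(sum(sh$mass), 1, tolerance = 1e-9)
  expect_error(aoristic_sum(data.frame(start_bp = 1, end_bp = 5,
                                       known = TRUE)), "malformed")
})
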