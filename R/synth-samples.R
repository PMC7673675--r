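#' Sample synthetic sea-level index points
#'
#' Draws dated sea-level observations from a known relative sea-level
#' history.  True calendar ages are uniform over `support`; observed ages
#' and elevations carry independent Gaussian errors.  A fraction of
#' points are converted to limiting observations: their elevations are
#' displaced by a half-normal draw below (marine-limiting) or above
#' (terrestrial-limiting) the truth curve, so they constrain sea level
#' from one side only.
#'
#' @param truth a [synthetic_truth()] object.
#' @param n number of points (>= 1).
#' @param age_sd 1-sigma age error, ka (>= 0).
#' @param elev_sd 1-sigma elevation error, m (>= 0).
#' @param limiting_fraction proportion of points made limiting, in [0, 1]
#'   (split evenly between marine- and terrestrial-limiting).
#' @param seed integer master seed.
#' @param support length-2 age span (ka BP) to draw from.
#' @param limiting_sd scale (m) of the half-normal limiting displacement.
#' @return a `data.frame` of class `slip_table` with columns `id`,
#'   `age_ka`, `age_2sigma_ka`, `H_m`, `I_m`, `S_m`, `S_2sigma_m`,
#'   `kind` (one of `precise`, `marine_limiting`, `terrestrial_limiting`).
#' @export
sample_slips <- function(truth, n, age_sd = 0.1, elev_sd = 0.3,
                         limiting_fraction = 0, seed = 1,
                         support = c(0.5, 8), limiting_sd = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (n < 1) stop("n must be >= 1")
  if (age_sd < 0 || elev_sd < 0) stop("error sds must be >= 0")
  if (limiting_fraction < 0 || limiting_fraction > 1)
    stop("limiting_fraction must be in [0, 1]")
  if (diff(support) <= 0) stop("empty age support")

  with_substream(seed, "slips", {
    true_age <- sort(runif(n, support[1], support[2]), decreasing = TRUE)
    true_rsl <- truth$rsl_truth(true_age)
    obs_age <- true_age + rnorm(n, 0, age_sd)
    S <- true_rsl + rnorm(n, 0, elev_sd)
    kind <- rep("precise", n)
    n_lim <- round(limiting_fraction * n)
    if (n_lim > 0) {
      idx <- sample.int(n, n_lim)
      marine <- rbinom(n_lim, 1, 0.5) == 1
      kind[idx[marine]] <- "marine_limiting"
      kind[idx[!marine]] <- "terrestrial_limiting"
      disp <- abs(rnorm(n_lim, 0, limiting_sd))
      S[idx] <- true_rsl[idx] + ifelse(marine, -disp, disp)
    }
    structure(data.frame(id = sprintf("SYN-%03d", seq_len(n)),
                         age_ka = obs_age,
                         age_2sigma_ka = rep(2 * age_sd, n),
                         H_m = S, I_m = rep(0, n), S_m = S,
                         S_2sigma_m = rep(2 * elev_sd, n),
                         kind = kind,
                         stringsAsFactors = FALSE),
              class = c("slip_table", "data.frame"),
              true_age_ka = true_age, true_rsl_m = true_rsl)
  })
}

#' Calibration curve container and synthetic curves
#'
#' IntCal-style curve: a strictly increasing calendar grid with the
#' radiocarbon-age mean and 1-sigma of the curve at each node.
#'
#' @param cal_bp calendar ages, yr BP, strictly increasing.
#' @param c14_bp radiocarbon ages of the curve at `cal_bp`.
#' @param sigma curve 1-sigma, yr (>= 0).
#' @return object of class `calcurve` (a data.frame).
#' @export
calibration_curve <- function(cal_bp, c14_bp, sigma) {
  if (is.unsorted(cal_bp, strictly = TRUE))
    stop("cal_bp grid must be strictly increasing")
  if (any(sigma < 0)) stop("curve sigma must be >= 0")
  structure(data.frame(cal_bp = cal_bp, c14_bp = c14_bp, sigma = sigma),
            class = c("calcurve", "data.frame"))
}

#' @rdname calibration_curve
#' @param span calendar span (yr BP) of the synthetic curve.
#' @param step grid step, yr.
#' @param wiggle_amp,wiggle_period amplitude (14C yr) and period (cal yr)
#'   of a sinusoidal departure from the 1:1 line; 0 amplitude gives a
#'   linear curve.
#' @param curve_sd constant curve 1-sigma, yr.
#' @export
make_calcurve <- function(span = c(0, 12000), step = 5, wiggle_amp = 0,
                          wiggle_period = 500, curve_sd = 10) {
  grid <- seq(span[1], span[2], by = step)
  mu <- grid + wiggle_amp * sin(2 * pi * grid / wiggle_period)
  calibration_curve(grid, mu, rep(curve_sd, length(grid)))
}

#' Sample synthetic radiocarbon dates from a population curve
#'
#' Calendar ages are drawn from the population density by inverse-CDF
#' sampling on a fine grid; each is pushed through the calibration curve
#' and perturbed with Gaussian noise of sd `sqrt(err^2 + curve_sd^2)`.
#'
#' @param pop function `age_ka -> density`, the regional population curve.
#' @param calcurve a [calibration_curve()].
#' @param n number of dates (>= 1).
#' @param err laboratory 1-sigma, 14C yr.
#' @param sites number of site labels, assigned uniformly.
#' @param seed integer master seed.
#' @param region region label attached to every date.
#' @param support length-2 calendar-age support (ka BP) of `pop`; must lie
#'   within the calibration-curve span.
#' @return a `data.frame` with columns `lab_id`, `site_id`, `region`,
#'   `c14_age`, `c14_error`, plus attribute `true_cal_bp`.
#' @export
sample_radiocarbon <- function(pop, calcurve, n, err = 30, sites = 10,
                               seed = 1, region = "region",
                               support = c(1, 10)) {
  stopifnot(inherits(calcurve, "calcurve"))
  if (n < 1) stop("n must be >= 1")
  sup_bp <- sort(support * 1000)
  if (sup_bp[1] < min(calcurve$cal_bp) || sup_bp[2] > max(calcurve$cal_bp))
    stop("population support lies outside the calibration curve span")
  with_substream(seed, paste0("c14-", region), {
    if (diff(support) == 0) {
      theta_ka <- rep(support[1], n)       # point-mass population
    } else {
      fine <- seq(support[1], support[2], length.out = 4000L)
      dens <- pmax(pop(fine), 0)
      if (all(dens == 0)) stop("population curve is zero on its support")
      cdf <- cumsum(dens); cdf <- cdf / cdf[length(cdf)]
      keep <- !duplicated(cdf)
      theta_ka <- approx(cdf[keep], fine[keep], runif(n), rule = 2)$y
    }
    theta_bp <- theta_ka * 1000
    mu <- approx(calcurve$cal_bp, calcurve$c14_bp, theta_bp)$y
    csd <- approx(calcurve$cal_bp, calcurve$sigma, theta_bp)$y
    c14 <- mu + rnorm(n, 0, sqrt(err^2 + csd^2))
    structure(data.frame(lab_id = sprintf("%s-%04d", region, seq_len(n)),
                         site_id = sprintf("%s_site%02d", region,
                                           sample.int(sites, n, replace = TRUE)),
                         region = region,
                         c14_age = c14, c14_error = rep(err, n),
                         stringsAsFactors = FALSE),
              true_cal_bp = theta_bp)
  })
}

#' Sample a synthetic monument inventory
#'
#' Each monument is assigned one of the supplied archaeological period
#' windows (probabilities `mix`) or flagged as being of unknown age with
#' probability `unknown_fraction`.
#'
#' @param n inventory size.
#' @param period_windows data.frame with columns `start_bp`, `end_bp`
#'   (BP convention: `start_bp > end_bp`) and optionally `period`.
#' @param mix period mixing proportions (sum to 1).
#' @param unknown_fraction probability a record has no usable age.
#' @param seed integer master seed.
#' @return a `data.frame` with columns `monument_id`, `period`,
#'   `start_bp`, `end_bp`, `known` (logical).
#' @export
sample_monuments <- function(n, period_windows, mix = NULL,
                             unknown_fraction = 0, seed = 1) {
  pw <- as.data.frame(period_windows)
  if (!all(c("start_bp", "end_bp") %in% names(pw)))
    stop("period_windows needs columns start_bp, end_bp")
  if (any(pw$start_bp <= pw$end_bp))
    stop("malformed window: start_bp must exceed end_bp (BP convention)")
  if (is.null(mix)) mix <- rep(1 / nrow(pw), nrow(pw))
  if (abs(sum(mix) - 1) > 1e-8) stop("mix proportions must sum to 1")
  if (is.null(pw$period)) pw$period <- sprintf("period%d", seq_len(nrow(pw)))
  with_substream(seed, "monuments", {
    unknown <- runif(n) < unknown_fraction
    wi <- sample.int(nrow(pw), n, replace = TRUE, prob = mix)
    out <- data.frame(monument_id = sprintf("MON-%05d", seq_len(n)),
                      period = pw$period[wi],
                      start_bp = pw$start_bp[wi],
                      end_bp = pw$end_bp[wi],
                      known = !unknown,
                      stringsAsFactors = FALSE)
    out$period[unknown] <- "unknown"
    out$start_bp[unknown] <- NA_real_
    out$end_bp[unknown] <- NA_real_
    out
  })
}

#' Sample synthetic pollen assemblages along an ecological gradient
#'
#' Expected land-taxon proportions are a linear mixture of two endmember
#' compositions, `(1 - g) * E0 + g * E1`, where `g` is the min-max scaled
#' gradient score, `E0` is a geometric composition with a 9:1
#' first-to-last taxon ratio and `E1` is its reverse; counts are
#' multinomial with exactly `counts_per_sample` land-derived grains per
#' sample (the counting convention of stopping at a fixed land-pollen
#' total).  With `halophyte_cluster = TRUE` an extra block of samples
#' dominated (75%) by a `Halophyte` taxon is appended, emulating
#' salt-marsh assemblages that downstream screening should remove.
#' Paired charcoal counts (two size fractions) are drawn Poisson with a
#' rate that increases along the gradient.
#'
#' @param gradient numeric per-sample scores (any scale; only ranks and
#'   relative spacing matter).
#' @param taxa number of land taxa (>= 2), excluding the halophyte.
#' @param counts_per_sample land-derived grains counted per sample.
#' @param halophyte_cluster logical; append halophyte-dominated samples?
#' @param seed integer master seed.
#' @param ages_bp optional per-sample ages (yr BP); defaults to a linear
#'   10-1 ka span over the gradient samples.
#' @return a `data.frame` with columns `sample_id`, `age_bp`,
#'   `is_halophyte_truth`, one column per taxon, `charcoal_gt50`,
#'   `charcoal_lt50`; attribute `gradient_truth` carries the generating
#'   scores (NA for appended halophyte samples).
#' @export
sample_pollen <- function(gradient, taxa = 8, counts_per_sample = 300,
                          halophyte_cluster = FALSE, seed = 1,
                          ages_bp = NULL) {
  if (taxa < 2) stop("need at least 2 taxa")
  if (counts_per_sample < 1) stop("counts_per_sample must be >= 1")
  n <- length(gradient)
  g <- if (diff(range(gradient)) == 0) rep(0.5, n) else
    (gradient - min(gradient)) / diff(range(gradient))
  e0 <- (1 / 9)^(seq(0, 1, length.out = taxa)); e0 <- e0 / sum(e0)
  e1 <- rev(e0)
  taxon_names <- sprintf("Taxon%02d", seq_len(taxa))
  if (is.null(ages_bp)) ages_bp <- seq(10000, 1000, length.out = n)

  with_substream(seed, "pollen", {
    props <- outer(1 - g, e0) + outer(g, e1)   # n x taxa
    counts <- t(vapply(seq_len(n),
                       function(i) as.numeric(rmultinom(1, counts_per_sample,
                                                        props[i, ])),
                       numeric(taxa)))
    is_halo <- rep(FALSE, n)
    grad_truth <- gradient
    if (halophyte_cluster) {
      n_h <- max(3L, round(0.15 * n))
      # halophyte-dominated: 75% Chenopodiaceae-like, remainder ~ E1
      ph <- c(0.25 * e1, 0.75)
      ch <- t(vapply(seq_len(n_h),
                     function(i) as.numeric(rmultinom(1, counts_per_sample, ph)),
                     numeric(taxa + 1)))
      counts <- cbind(counts, 0)
      counts <- rbind(counts, ch)
      is_halo <- c(is_halo, rep(TRUE, n_h))
      ages_bp <- c(ages_bp, seq(6000, 4000, length.out = n_h))
      grad_truth <- c(grad_truth, rep(NA_real_, n_h))
      taxon_names <- c(taxon_names, "Halophyte")
    }
    m <- nrow(counts)
    lam <- 15 * exp(1.5 * c(g, rep(0.5, m - n)))
    out <- data.frame(sample_id = sprintf("P%03d", seq_len(m)),
                      age_bp = ages_bp,
                      is_halophyte_truth = is_halo,
                      stringsAsFactors = FALSE)
    out[taxon_names] <- as.data.frame(counts)
    out$charcoal_gt50 <- stats::rpois(m, lam)
    out$charcoal_lt50 <- stats::rpois(m, 3 * lam)
    structure(out, gradient_truth = grad_truth,
              taxon_names = taxon_names)
  })
}

#' Synthetic paleotidal history
#'
#' M2/S2 amplitudes per 1-ka time slice, shrinking smoothly back in time
#' (shallower shelf seas damp the tide).
#'
#' @param times_ka time slices, ka BP.
#' @param aM2_present,aS2_present present-day amplitudes, m.
#' @param shrink fractional amplitude reduction per ka into the past.
#' @return a `data.frame` with columns `time_ka`, `aM2_m`, `aS2_m`.
#' @export
make_tide_history <- function(times_ka = 0:9, aM2_present = 1.8,
                              aS2_present = 0.6, shrink = 0.03) {
  f <- pmax(1 - shrink * times_ka, 0.2)
  data.frame(time_ka = times_ka, aM2_m = aM2_present * f,
             aS2_m = aS2_present * f)
}
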