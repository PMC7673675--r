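#' Synthetic ground truth for end-to-end testing
#'
#' Bundles the quantities every downstream stage is later asked to
#' recover: a relative sea-level history and its rate, per-region
#' population curves, a per-sample ecological gradient, and the island
#' shape descriptors used by [make_dem()].
#'
#' @param rate_anchors two-column matrix or data.frame `(age_ka, rate_mm_yr)`
#'   of rate-of-rise anchor points; the rate history is linear between
#'   anchors and the level history is its exact (piecewise-quadratic)
#'   integral, pinned to RSL = 0 at age 0.
#' @param population_curves named list of functions `age_ka -> density`,
#'   each nonnegative and integrating to 1 over `pop_support`.
#' @param pop_support numeric length-2: calendar-age support (ka) of the
#'   population curves.
#' @param gradient_truth numeric vector of per-sample ecological scores
#'   driving synthetic pollen composition.
#' @param dem_params list with `peak_height_m`, `shelf_gradient` (m/m) and
#'   `extent_m` describing the synthetic island.
#'
#' @return an object of class `synthetic_truth` with elements
#'   `rsl_truth(t)` (m, RSL relative to present MSL at age `t` ka BP),
#'   `rate_truth(t)` (mm/yr of rise toward the present), plus the inputs.
#' @seealso [scilly_like_truth()] for the default study conditions.
#' @export
synthetic_truth <- function(rate_anchors,
                            population_curves = list(),
                            pop_support = c(1, 10),
                            gradient_truth = seq(0, 1, length.out = 50),
                            dem_params = list(peak_height_m = 40,
                                              shelf_gradient = 0.002,
                                              extent_m = 12000)) {
  rate_anchors <- as.data.frame(rate_anchors)
  names(rate_anchors) <- c("age_ka", "rate_mm_yr")
  stopifnot(nrow(rate_anchors) >= 2,
            !is.unsorted(rate_anchors$age_ka, strictly = TRUE))
  ta <- rate_anchors$age_ka
  ra <- rate_anchors$rate_mm_yr

  rate_truth <- approxfun(ta, ra, rule = 2)

  # Exact integral of the piecewise-linear rate: piecewise quadratic.
  # rate is mm/yr = m/ka, age axis is ka, so RSL(t) = -integral_0^t rate.
  seg_int <- c(0, cumsum(diff(ta) * (head(ra, -1) + tail(ra, -1)) / 2))
  cum_at <- function(t) {
    t <- pmin(pmax(t, ta[1]), ta[length(ta)])
    j <- findInterval(t, ta, rightmost.closed = TRUE)
    dt <- t - ta[j]
    slope <- (ra[pmin(j + 1, length(ra))] - ra[j]) /
      pmax(ta[pmin(j + 1, length(ta))] - ta[j], .Machine$double.eps)
    seg_int[j] + dt * (ra[j] + 0.5 * slope * dt)
  }
  base <- cum_at(0)
  rsl_truth <- function(t) -(cum_at(t) - base)

  structure(list(rsl_truth = rsl_truth,
                 rate_truth = rate_truth,
                 rate_anchors = rate_anchors,
                 population_curves = population_curves,
                 pop_support = pop_support,
                 gradient_truth = gradient_truth,
                 dem_params = dem_params),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic ground truth\n")
  cat(sprintf("  rate anchors: %d over %.1f-%.1f ka BP\n",
              nrow(x$rate_anchors), min(x$rate_anchors$age_ka),
              max(x$rate_anchors$age_ka)))
  cat(sprintf("  RSL at oldest anchor: %.1f m\n",
              x$rsl_truth(max(x$rate_anchors$age_ka))))
  if (length(x$population_curves))
    cat("  population regions:",
        paste(names(x$population_curves), collapse = ", "), "\n")
  invisible(x)
}

#' Default study conditions: a Scilly-like Holocene history
#'
#' Rate-of-rise anchors chosen so that the truth reproduces the headline
#' rates of the reconstructed curve: a mean of 2.8 mm/yr over 7-4.5 ka,
#' 2.8 mm/yr at 5 ka, 1.1 mm/yr at 4 ka, a mean of 0.8 mm/yr over
#' 4 ka-present, and rapid (>5 mm/yr) Early Holocene rise.  Population
#' curves emulate a western-Britain expansion from ~4.2 ka against an
#' earlier northwest-France Neolithic peak that declines after ~4.5 ka.
#'
#' @param n_gradient number of samples on the synthetic ecological
#'   gradient (default 50).
#' @return a [synthetic_truth()] object.
#' @examples
#' tr <- scilly_like_truth()
#' tr$rate_truth(c(5, 4))   # mm/yr at 5 and 4 ka BP
#' tr$rsl_truth(7)          # m below present MSL at 7 ka
#' @export
scilly_like_truth <- function(n_gradient = 50) {
  anchors <- data.frame(
    age_ka     = c(0,    3,      4,   4.5, 5,   6,   7,   9, 12),
    rate_mm_yr = c(0.55, 0.9125, 1.1, 1.6, 2.8, 3.0, 3.0, 6, 10))
  support <- c(1, 10)
  bump <- function(mu, s) function(t) exp(-0.5 * ((t - mu) / s)^2)
  mix <- function(parts, w) {
    f_raw <- function(t) {
      v <- 0
      for (i in seq_along(parts)) v <- v + w[i] * parts[[i]](t)
      v * as.numeric(t >= support[1] & t <= support[2])
    }
    z <- integrate(f_raw, support[1], support[2],
                   subdivisions = 500L)$value
    function(t) f_raw(t) / z
  }
  pops <- list(
    west_britain = mix(list(bump(6.0, 0.8), bump(3.0, 1.0)), c(0.35, 1.0)),
    nw_france    = mix(list(bump(6.3, 0.9), bump(2.5, 1.2)), c(1.0, 0.35)))
  synthetic_truth(anchors,
                  population_curves = pops,
                  pop_support = support,
                  gradient_truth = seq(0, 1, length.out = n_gradient))
}

#' Build a normalized population curve from anchor weights
#'
#' Linear interpolation between `(age, weight)` anchors, clamped to zero
#' outside the anchor span and normalized to integrate to 1.
#'
#' @param ages_ka anchor ages (ka BP), strictly increasing.
#' @param weights nonnegative relative densities at the anchors.
#' @return a function `age_ka -> density` (per ka).
#' @export
make_population_curve <- function(ages_ka, weights) {
  stopifnot(length(ages_ka) == length(weights), all(weights >= 0),
            !is.unsorted(ages_ka, strictly = TRUE), any(weights > 0))
  f_raw <- approxfun(ages_ka, weights, yleft = 0, yright = 0)
  z <- integrate(f_raw, min(ages_ka), max(ages_ka),
                 subdivisions = 500L)$value
  function(t) f_raw(t) / z
}
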