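#' Construct a sea-level index point
#'
#' A dated sample of elevation `H` (m relative to MSL) whose depositional
#' environment sat `I` metres above former sea level (the indicative
#' meaning) constrains former sea level to `S = H - I`.  The 2-sigma
#' vertical error is twice the root-sum-of-squares of the supplied
#' 1-sigma error components (surveying, sampling, transfer function, ...).
#'
#' @param H sample elevation, m relative to present MSL.
#' @param I indicative meaning, m (0 for direct sea-level markers).
#' @param errors numeric vector of independent 1-sigma error components, m.
#' @param kind `"precise"`, `"marine_limiting"` or
#'   `"terrestrial_limiting"`; limiting points carry a one-sided
#'   constraint only.
#' @param age_ka,age_2sigma_ka age and its 2-sigma error, ka BP.
#' @param id sample identifier.
#' @return one-row `data.frame` of class `slip_table` with the standard
#'   columns (`id`, `age_ka`, `age_2sigma_ka`, `H_m`, `I_m`, `S_m`,
#'   `S_2sigma_m`, `kind`).
#' @examples
#' build_slip(H = 1.2, I = 0.8, errors = c(0.03, 0.04, 0.12),
#'            age_ka = 4.2, age_2sigma_ka = 0.1)
#' @export
build_slip <- function(H, I, errors = 0, kind = "precise",
                       age_ka = NA_real_, age_2sigma_ka = NA_real_,
                       id = "slip") {
  if (!is.finite(H) || !is.finite(I)) stop("H and I must be finite")
  if (any(errors < 0)) stop("error components must be >= 0")
  kind <- match.arg(kind,
                    c("precise", "marine_limiting", "terrestrial_limiting"))
  structure(data.frame(id = id, age_ka = age_ka,
                       age_2sigma_ka = age_2sigma_ka,
                       H_m = H, I_m = I, S_m = H - I,
                       S_2sigma_m = 2 * sqrt(sum(errors^2)),
                       kind = kind, stringsAsFactors = FALSE),
            class = c("slip_table", "data.frame"))
}

#' Standardize an elevation between tidal frames
#'
#' Maps a height above local mean sea level from one tidal regime to
#' another by scaling in proportion to the spring tidal range (the
#' standardized-water-level-index convention), as when a transfer
#' function trained in one estuary is applied to a site with a different
#' tidal range.
#'
#' @param elevation height above MSL, m, in the source frame.
#' @param source_tides,target_tides tidal epochs: lists or one-row
#'   data.frames with `aM2_m` and `aS2_m` (m); spring range is
#'   `2 * (aM2 + aS2)`.
#' @return the elevation expressed in the target frame, m above MSL.
#' @examples
#' tidal_standardize(2, list(aM2_m = 1.5, aS2_m = 0.5),
#'                   list(aM2_m = 0.75, aS2_m = 0.25))  # 1 m
#' @export
tidal_standardize <- function(elevation, source_tides, target_tides) {
  rs <- spring_range(source_tides)
  rt <- spring_range(target_tides)
  if (rs <= 0 || rt <= 0) stop("spring range must be positive in both frames")
  elevation * rt / rs
}

spring_range <- function(tides) {
  2 * (as.numeric(tides$aM2_m) + as.numeric(tides$aS2_m))
}
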