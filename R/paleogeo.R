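#' Spring tidal levels from M2 and S2 constituent amplitudes
#'
#' Mean high water springs is approximated as the sum of the M2 and S2
#' amplitudes about contemporaneous mean sea level, and mean low water
#' springs as its negative.  The combination rule is a configuration
#' point: supply `combine` to use a different functional of the
#' amplitudes.
#'
#' @param tides a tidal epoch: list or one-row data.frame with `aM2_m`
#'   and `aS2_m` (>= 0).
#' @param combine function of `(aM2, aS2)` returning the spring high
#'   water level; default `aM2 + aS2`.
#' @return named numeric `c(MHWS, MLWS)` in m relative to MSL.
#' @examples
#' water_levels(list(aM2_m = 1.8, aS2_m = 0.6))  # +2.4 / -2.4
#' @export
water_levels <- function(tides, combine = function(aM2, aS2) aM2 + aS2) {
  aM2 <- as.numeric(tides$aM2_m); aS2 <- as.numeric(tides$aS2_m)
  if (aM2 < 0 || aS2 < 0) stop("tidal amplitudes must be >= 0")
  hw <- combine(aM2, aS2)
  c(MHWS = hw, MLWS = -hw)
}

#' Reconstruct a paleogeography for one epoch
#'
#' Cells are classified against the contemporaneous tidal frame: land
#' where `elevation - rsl > MHWS`, intertidal where
#' `MLWS < elevation - rsl <= MHWS` (cells exactly at MHWS are
#' intertidal), subtidal below.  Nodata cells are excluded from every
#' class and every area.
#'
#' @param dem an [elevation_grid()] (m relative to present MSL).
#' @param rsl relative sea level at the epoch, m (negative = below
#'   present).
#' @param tides tidal epoch (see [water_levels()]).
#' @param time_ka epoch age label, ka BP.
#' @param min_island_cells connected components smaller than this many
#'   cells are not counted as islands (default 1 = count all).
#' @return object of class `paleogeography`: masks (`land`,
#'   `intertidal`, logical matrices with NA at nodata), areas in km2,
#'   `island_count`, the tidal levels and cell bookkeeping.
#' @export
reconstruct <- function(dem, rsl, tides, time_ka = NA_real_,
                        min_island_cells = 1L) {
  stopifnot(inherits(dem, "elevation_grid"))
  if (!is.finite(rsl)) stop("rsl must be finite")
  if (all(is.na(dem$z))) stop("all-nodata grid")
  wl <- water_levels(tides)
  rel <- dem$z - rsl
  land <- rel > wl["MHWS"]
  inter <- rel > wl["MLWS"] & rel <= wl["MHWS"]
  cell_km2 <- (dem$cell_size / 1000)^2
  n_land <- sum(land, na.rm = TRUE)
  n_inter <- sum(inter, na.rm = TRUE)
  n_nodata <- sum(is.na(dem$z))
  n_sub <- length(dem$z) - n_land - n_inter - n_nodata
  structure(list(time_ka = time_ka, rsl_m = rsl,
                 mhws_m = unname(wl["MHWS"]), mlws_m = unname(wl["MLWS"]),
                 land = land, intertidal = inter,
                 land_area_km2 = n_land * cell_km2,
                 intertidal_area_km2 = n_inter * cell_km2,
                 island_count = island_count(land,
                                             min_cells = min_island_cells),
                 n_land = n_land, n_intertidal = n_inter,
                 n_subtidal = n_sub, n_nodata = n_nodata,
                 dem = dem),
            class = "paleogeography")
}

#' @export
print.paleogeography <- function(x, ...) {
  cat(sprintf("Paleogeography at %s ka BP (RSL %.2f m, MHWS %+.2f m):\n",
              format(x$time_ka), x$rsl_m, x$mhws_m))
  cat(sprintf("  land %.3f km2 (%d islands), intertidal %.3f km2\n",
              x$land_area_km2, x$island_count, x$intertidal_area_km2))
  invisible(x)
}

#' Count islands in a land mask
#'
#' Connected-component labelling of the land mask, 8-connectivity by
#' default (diagonally touching land is one island), via a cell-adjacency
#' graph.
#'
#' @param mask logical matrix (NA treated as sea).
#' @param connectivity 8 (default) or 4.
#' @param min_cells minimum component size counted (default 1).
#' @return integer number of islands.
#' @export
island_count <- function(mask, connectivity = 8, min_cells = 1L) {
  stopifnot(connectivity %in% c(4, 8))
  m <- mask
  m[is.na(m)] <- FALSE
  idx <- which(m)
  if (length(idx) == 0L) return(0L)
  nr <- nrow(m)
  id <- matrix(NA_integer_, nrow(m), ncol(m))
  id[idx] <- seq_along(idx)
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  edges <- integer(0)
  for (o in offs) {
    r <- arrayInd(idx, dim(m))
    r2 <- cbind(r[, 1] + o[1], r[, 2] + o[2])
    ok <- r2[, 1] >= 1 & r2[, 1] <= nrow(m) &
      r2[, 2] >= 1 & r2[, 2] <= ncol(m)
    j <- id[cbind(r2[ok, 1], r2[ok, 2])]
    i <- id[idx[ok]]
    keep <- !is.na(j)
    edges <- c(edges, rbind(i[keep], j[keep]))
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)
  sum(comp$csize >= min_cells)
}

#' Land- and intertidal-area series through time
#'
#' Applies [reconstruct()] at every epoch of the sea-level history, with
#' tidal amplitudes linearly interpolated to those epochs, and derives
#' the ratio and percentage columns used to describe landscape change:
#' the land/intertidal ratio and the intertidal area as a percentage of
#' the total area above mean low water springs.
#'
#' @param dem an [elevation_grid()].
#' @param rsl_history data.frame `time_ka`, `rsl_m`.
#' @param tide_history data.frame `time_ka`, `aM2_m`, `aS2_m`; must span
#'   the sea-level epochs.
#' @param min_island_cells passed to [reconstruct()].
#' @param keep_geographies keep the per-epoch mask objects? (default
#'   FALSE; the series table is always returned).
#' @return object of class `landscape_series`: a data.frame with one row
#'   per epoch (`time_ka`, `rsl_m`, `land_km2`, `intertidal_km2`,
#'   `island_count`, `land_intertidal_ratio`, `intertidal_pct_above_mlws`,
#'   conservation counts), with the geography list as an attribute when
#'   requested.
#' @export
area_series <- function(dem, rsl_history, tide_history,
                        min_island_cells = 1L, keep_geographies = FALSE) {
  rh <- as.data.frame(rsl_history)
  th <- as.data.frame(tide_history)
  if (min(rh$time_ka) < min(th$time_ka) - 1e-9 ||
      max(rh$time_ka) > max(th$time_ka) + 1e-9)
    stop("tide history does not span the sea-level epochs; cannot interpolate")
  ord <- order(rh$time_ka)
  rh <- rh[ord, , drop = FALSE]
  aM2 <- approx(th$time_ka, th$aM2_m, rh$time_ka, rule = 2)$y
  aS2 <- approx(th$time_ka, th$aS2_m, rh$time_ka, rule = 2)$y
  geos <- vector("list", nrow(rh))
  rows <- vector("list", nrow(rh))
  for (i in seq_len(nrow(rh))) {
    g <- reconstruct(dem, rh$rsl_m[i],
                     list(aM2_m = aM2[i], aS2_m = aS2[i]),
                     time_ka = rh$time_ka[i],
                     min_island_cells = min_island_cells)
    above_mlws <- g$land_area_km2 + g$intertidal_area_km2
    rows[[i]] <- data.frame(
      time_ka = g$time_ka, rsl_m = g$rsl_m,
      land_km2 = g$land_area_km2, intertidal_km2 = g$intertidal_area_km2,
      island_count = g$island_count,
      land_intertidal_ratio = if (g$intertidal_area_km2 > 0)
        g$land_area_km2 / g$intertidal_area_km2 else NA_real_,
      intertidal_pct_above_mlws = if (above_mlws > 0)
        100 * g$intertidal_area_km2 / above_mlws else NA_real_,
      n_land = g$n_land, n_intertidal = g$n_intertidal,
      n_subtidal = g$n_subtidal, n_nodata = g$n_nodata)
    g$dem <- NULL
    geos[[i]] <- g
  }
  out <- do.call(rbind, rows)
  class(out) <- c("landscape_series", "data.frame")
  if (keep_geographies) attr(out, "geographies") <- geos
  out
}

#' Human-timescale landscape change metrics
#'
#' Rescales each between-epoch change of the series linearly to a chosen
#' window (a lifespan, a decade, ...), reporting absolute change in m2
#' and the proportional change relative to the start-of-interval area.
#'
#' @param series a [area_series()] result (or any data.frame with
#'   `time_ka`, `land_km2`, `intertidal_km2`).
#' @param window_years window length, yr (> 0).
#' @return data.frame with one row per between-epoch interval:
#'   `from_ka`, `to_ka`, `land_change_m2`, `land_change_pct`,
#'   `intertidal_change_m2`, `intertidal_change_pct` (all per window;
#'   negative = loss; percentages of start-of-interval area).
#' @examples
#' s <- data.frame(time_ka = c(5, 4), land_km2 = c(27.8, 17.8),
#'                 intertidal_km2 = c(7.8, 12.8))
#' change_metrics(s, 70)    # a 70-year lifespan
#' change_metrics(s, 10)    # a decade
#' @export
change_metrics <- function(series, window_years) {
  s <- as.data.frame(series)
  if (window_years <= 0) stop("window_years must be positive")
  if (nrow(s) < 2) stop("need at least 2 epochs")
  s <- s[order(s$time_ka, decreasing = TRUE), , drop = FALSE]  # old -> young
  span_yr <- (max(s$time_ka) - min(s$time_ka)) * 1000
  if (window_years > span_yr)
    stop("window (", window_years, " yr) exceeds the series span (",
         span_yr, " yr)")
  i <- seq_len(nrow(s) - 1L)
  dt_yr <- (s$time_ka[i] - s$time_ka[i + 1L]) * 1000
  dl_km2 <- s$land_km2[i + 1L] - s$land_km2[i]
  di_km2 <- s$intertidal_km2[i + 1L] - s$intertidal_km2[i]
  f <- window_years / dt_yr
  data.frame(from_ka = s$time_ka[i], to_ka = s$time_ka[i + 1L],
             land_change_m2 = dl_km2 * 1e6 * f,
             land_change_pct = 100 * dl_km2 * f / s$land_km2[i],
             intertidal_change_m2 = di_km2 * 1e6 * f,
             intertidal_change_pct = 100 * di_km2 * f / s$intertidal_km2[i])
}

#' Lateral shoreline displacement rate along a transect
#'
#' Locates the land/sea boundary (the MHWS shoreline) along a transect
#' at two epochs by linear interpolation of `elevation - rsl - MHWS`
#' along the transect arc, and divides the displacement by the elapsed
#' time.
#'
#' @param geo_t1,geo_t2 [reconstruct()] results for two different epochs
#'   (both must retain their `dem`).
#' @param transect two-column matrix/data.frame of grid indices
#'   `(row, col)` ordered along the line, starting on land.
#' @return lateral inundation rate, m/yr (>= 0).
#' @export
lateral_rate <- function(geo_t1, geo_t2, transect) {
  stopifnot(inherits(geo_t1, "paleogeography"),
            inherits(geo_t2, "paleogeography"))
  if (isTRUE(all.equal(geo_t1$time_ka, geo_t2$time_ka)))
    stop("epochs must differ")
  if (is.null(geo_t1$dem) || is.null(geo_t2$dem))
    stop("paleogeographies must retain their dem for transect work")
  tr <- as.matrix(transect)
  dem <- geo_t1$dem
  arc <- c(0, cumsum(sqrt(rowSums(diff(tr)^2)))) * dem$cell_size
  pos <- function(geo) {
    f <- dem$z[tr] - geo$rsl_m - geo$mhws_m   # >0 on land
    if (all(f > 0) || all(f <= 0) || f[1] <= 0)
      stop("transect does not cross the shoreline at epoch ",
           format(geo$time_ka), " ka")
    k <- which(f[-length(f)] > 0 & f[-1] <= 0)[1]
    if (f[k] == f[k + 1]) return(arc[k])
    arc[k] + (arc[k + 1] - arc[k]) * f[k] / (f[k] - f[k + 1])
  }
  disp <- abs(pos(geo_t2) - pos(geo_t1))
  years <- abs(geo_t1$time_ka - geo_t2$time_ka) * 1000
  disp / years
}
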