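#' Score a candidate relative sea-level history against precise SLIPs
#'
#' Reduced chi-square misfit between a candidate (e.g. GIA-modelled)
#' relative sea-level curve and the precise index points:
#' \deqn{\chi^2 = \frac{1}{N-1} \sum_{i=1}^{N}
#'       \left(\frac{RSL^p_i - RSL^{obs}_i}{\sigma_i}\right)^2}
#' where `N` is the number of precise SLIPs, the prediction is the
#' candidate linearly interpolated at each SLIP age, and `sigma_i` is the
#' 2-sigma vertical error of the observation.  Limiting points are
#' excluded.
#'
#' @param candidate a data.frame with columns `time_ka` and `rsl_m` (and
#'   optionally a `label` attribute), or a `gia_candidate` from
#'   [gia_candidate()].
#' @param slips a `slip_table`.
#' @return the chi-square value (single number).
#' @examples
#' s <- build_slip(H = -2, I = 0, errors = 0.25, age_ka = 4)
#' s <- rbind(s, build_slip(H = -5, I = 0, errors = 0.25, age_ka = 6))
#' cand <- data.frame(time_ka = c(0, 10), rsl_m = c(0, -10))
#' score_chi2(cand, s)
#' @export
score_chi2 <- function(candidate, slips) {
  sl <- as.data.frame(slips)
  sl <- sl[sl$kind == "precise", , drop = FALSE]
  N <- nrow(sl)
  if (N < 2) stop("need at least 2 precise SLIPs for a chi-square score")
  if (any(sl$S_2sigma_m <= 0))
    stop("zero vertical error on a precise SLIP; chi-square undefined")
  cd <- as.data.frame(candidate)
  if (min(sl$age_ka) < min(cd$time_ka) || max(sl$age_ka) > max(cd$time_ka))
    stop("candidate curve does not cover the SLIP epoch")
  pred <- approx(cd$time_ka, cd$rsl_m, sl$age_ka)$y
  sum(((pred - sl$S_m) / sl$S_2sigma_m)^2) / (N - 1)
}

#' @rdname score_chi2
#' @param label model label (ice history + Earth-model tag).
#' @param time_ka,rsl_m candidate curve nodes.
#' @export
gia_candidate <- function(label, time_ka, rsl_m) {
  structure(data.frame(time_ka = time_ka, rsl_m = rsl_m),
            label = label, class = c("gia_candidate", "data.frame"))
}

#' Rank candidate GIA histories by chi-square misfit
#'
#' @param candidates a (possibly named) list of candidate curves; names
#'   or `label` attributes supply the model labels.
#' @param slips a `slip_table`.
#' @return data.frame with columns `label` and `chi2`, sorted ascending
#'   by `chi2` with ties broken by label (lexicographic).
#' @export
select_gia <- function(candidates, slips) {
  if (length(candidates) == 0) stop("empty candidate list")
  labels <- names(candidates)
  if (is.null(labels)) labels <- rep(NA_character_, length(candidates))
  for (i in seq_along(candidates)) {
    al <- attr(candidates[[i]], "label")
    if (is.na(labels[i]) || labels[i] == "")
      labels[i] <- if (!is.null(al)) al else sprintf("model%02d", i)
  }
  chi2 <- vapply(candidates, score_chi2, numeric(1), slips = slips)
  out <- data.frame(label = labels, chi2 = unname(chi2),
                    stringsAsFactors = FALSE)
  out[order(out$chi2, out$label), , drop = FALSE]
}
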