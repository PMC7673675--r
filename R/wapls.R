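#' Weighted-averaging partial least squares transfer function
#'
#' Fits a WA-PLS transfer function relating foraminiferal (or other
#' microfossil) count assemblages to an environmental variable — here the
#' elevation of the sample within the tidal frame.  Components are
#' extracted by iterated weighted averaging of regression residuals;
#' the final weighted regression of the observed variable on the
#' component scores is the inverse-deshrinking step, which corrects the
#' shrinkage toward the mean inherent in weighted averaging.  With one
#' component the model reduces to classical weighted averaging with
#' inverse deshrinking.
#'
#' Training samples must have more than `min_count` individuals counted
#' (default 50, the usual screening rule for statistically usable
#' assemblages); offending samples abort the fit with their identifiers.
#'
#' @param counts numeric matrix or data.frame of taxon counts, samples in
#'   rows, taxa in (named) columns.
#' @param elevation numeric vector of training elevations (m), one per row.
#' @param n_components number of WA-PLS components (default 2).
#' @param n_boot bootstrap cycles for the RMSEP (default 100; 0 skips).
#' @param min_count count-total screening threshold (exclusive).
#' @param seed seed for the bootstrap.
#' @return an object of class `wapls` with elements `species_scores`
#'   (per-component taxon scores), `deshrink` (regression intercept and
#'   per-component slopes), `rmsep` (bootstrap), `rmse` (apparent),
#'   `null_rmse` (predicting the weighted-mean elevation), `fitted`,
#'   `n_components`, `taxa`.
#' @examples
#' cnt <- rbind(matrix(rep(c(100, 0), 5), 5, 2, byrow = TRUE),
#'              matrix(rep(c(0, 100), 5), 5, 2, byrow = TRUE))
#' colnames(cnt) <- c("A", "B")
#' m <- fit_wapls(cnt, rep(c(1, 2), each = 5), n_components = 1, n_boot = 0)
#' predict(m, c(A = 100, B = 0))
#' @export
fit_wapls <- function(counts, elevation, n_components = 2, n_boot = 100,
                      min_count = 50, seed = 1) {
  Y <- as.matrix(counts)
  if (is.null(colnames(Y))) colnames(Y) <- sprintf("taxon%d", seq_len(ncol(Y)))
  x <- as.numeric(elevation)
  if (nrow(Y) != length(x)) stop("counts and elevation lengths differ")
  if (n_components < 1) stop("n_components must be >= 1")
  if (nrow(Y) < 10) stop("need at least 10 training samples")
  if (nrow(Y) < n_components + 2)
    stop("need at least n_components + 2 training samples")
  tot <- rowSums(Y)
  if (any(tot <= min_count)) {
    bad <- rownames(Y)[tot <= min_count]
    if (is.null(bad)) bad <- which(tot <= min_count)
    stop("count screen failed (total <= ", min_count, " tests): sample(s) ",
         paste(bad, collapse = ", "))
  }
  drop_taxa <- colSums(Y) == 0
  Y <- Y[, !drop_taxa, drop = FALSE]

  core <- wapls_core(Y, x, n_components)
  fitted <- core$fitted
  rmse <- sqrt(mean((fitted - x)^2))
  xbar_w <- weighted.mean(x, tot)
  null_rmse <- sqrt(mean((xbar_w - x)^2))

  rmsep <- NA_real_
  if (n_boot > 0) {
    rmsep <- with_substream(seed, "wapls-boot", {
      errs <- numeric(0)
      n <- nrow(Y)
      for (b in seq_len(n_boot)) {
        idx <- sample.int(n, n, replace = TRUE)
        oob <- setdiff(seq_len(n), unique(idx))
        if (length(oob) == 0) next
        fb <- tryCatch(wapls_core(Y[idx, , drop = FALSE], x[idx],
                                  n_components), error = function(e) NULL)
        if (is.null(fb)) next
        pb <- wapls_predict_core(fb, Y[oob, , drop = FALSE])
        errs <- c(errs, pb - x[oob])
      }
      sqrt(mean(errs^2))
    })
  }

  structure(c(core,
              list(rmse = rmse, null_rmse = null_rmse, rmsep = rmsep,
                   n_boot = n_boot, min_count = min_count,
                   elevation = x)),
            class = "wapls")
}

# WA-PLS component extraction (counts Y, environment x).  Returns the
# linear recursion scalars needed to score new samples.
wapls_core <- function(Y, x, A) {
  n <- nrow(Y); m <- ncol(Y)
  rsum <- rowSums(Y); csum <- colSums(Y)
  R <- rsum / sum(Y)                      # sample weights
  xbar <- sum(R * x)
  e <- x - xbar                           # current regression residual
  P <- matrix(0, n, A)                    # standardized component scores
  U <- matrix(0, m, A, dimnames = list(colnames(Y), NULL))
  mu_a <- numeric(A); s_a <- numeric(A)
  gam <- matrix(0, A, A)                  # projections on earlier comps
  for (a in seq_len(A)) {
    u <- as.numeric(crossprod(Y, e)) / csum      # species scores
    p <- as.numeric(Y %*% u) / rsum              # raw sample scores
    mu_a[a] <- sum(R * p)
    p <- p - mu_a[a]
    if (a > 1) for (c in seq_len(a - 1)) {
      gam[a, c] <- sum(R * p * P[, c])
      p <- p - gam[a, c] * P[, c]
    }
    s_a[a] <- sqrt(sum(R * p^2))
    if (s_a[a] < 1e-12) {                 # degenerate (e.g. constant x)
      s_a[a] <- 1
      p <- rep(0, n)
    } else p <- p / s_a[a]
    P[, a] <- p
    U[, a] <- u
    b <- as.numeric(crossprod(P[, seq_len(a), drop = FALSE], R * x))
    fitted <- xbar + P[, seq_len(a), drop = FALSE] %*% b
    e <- x - as.numeric(fitted)
  }
  list(species_scores = U,
       deshrink = list(intercept = xbar, slopes = b),
       comp_mean = mu_a, comp_scale = s_a, comp_proj = gam,
       fitted = as.numeric(fitted), n_components = A,
       taxa = colnames(Y))
}

wapls_predict_core <- function(core, Ynew) {
  Ynew <- matrix(Ynew, ncol = length(core$taxa))
  A <- core$n_components
  tot <- rowSums(Ynew)
  Pn <- matrix(0, nrow(Ynew), A)
  for (a in seq_len(A)) {
    p <- as.numeric(Ynew %*% core$species_scores[, a]) / tot
    p <- p - core$comp_mean[a]
    if (a > 1) for (c in seq_len(a - 1))
      p <- p - core$comp_proj[a, c] * Pn[, c]
    Pn[, a] <- p / core$comp_scale[a]
  }
  as.numeric(core$deshrink$intercept + Pn %*% core$deshrink$slopes)
}

#' @export
print.wapls <- function(x, ...) {
  cat(sprintf("WA-PLS transfer function: %d component(s), %d taxa\n",
              x$n_components, length(x$taxa)))
  cat(sprintf("  apparent RMSE %.4g m | null RMSE %.4g m | bootstrap RMSEP %.4g m\n",
              x$rmse, x$null_rmse, x$rmsep))
  invisible(x)
}

#' @export
summary.wapls <- function(object, ...) {
  print(object)
  cat("  deshrinking: intercept", format(object$deshrink$intercept, digits = 4),
      "slopes", paste(format(object$deshrink$slopes, digits = 4),
                      collapse = ", "), "\n")
  invisible(object)
}

#' Predict paleomarsh surface elevation from a fossil assemblage
#'
#' @param object a fitted [fit_wapls()] model.
#' @param newdata named numeric vector of counts, or a matrix/data.frame
#'   with taxa in columns; taxa absent from the training set are dropped
#'   with a warning, and a fossil sharing no taxa with the training set
#'   is a no-analogue error.
#' @param min_count count screen applied to fossils (default: the
#'   model's).
#' @param ... unused.
#' @return data.frame with columns `pms_m` (paleomarsh surface elevation)
#'   and `rmsep_m`.
#' @export
predict.wapls <- function(object, newdata, min_count = object$min_count,
                          ...) {
  if (is.null(dim(newdata))) newdata <- t(as.matrix(newdata))
  newdata <- as.matrix(newdata)
  if (is.null(colnames(newdata)))
    stop("fossil counts must carry taxon names")
  extra <- setdiff(colnames(newdata), object$taxa)
  if (length(extra))
    warning("fossil taxa absent from training set ignored: ",
            paste(extra, collapse = ", "))
  common <- intersect(colnames(newdata), object$taxa)
  if (length(common) == 0)
    stop("no-analogue fossil: no taxa shared with the training set")
  tot <- rowSums(newdata)
  if (any(tot <= min_count))
    stop("fossil count screen failed (total <= ", min_count, " tests)")
  Y <- matrix(0, nrow(newdata), length(object$taxa),
              dimnames = list(rownames(newdata), object$taxa))
  Y[, common] <- newdata[, common]
  data.frame(pms_m = wapls_predict_core(object, Y),
             rmsep_m = object$rmsep)
}

#' @rdname predict.wapls
#' @param model a fitted [fit_wapls()] model.
#' @param fossil fossil counts (named vector).
#' @export
predict_pms <- function(model, fossil) {
  out <- predict(model, fossil)
  c(pms_m = out$pms_m[1], rmsep_m = out$rmsep_m[1])
}
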