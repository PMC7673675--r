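#' Fit an errors-in-variables integrated Gaussian process sea-level model
#'
#' The rate of sea-level change is modelled as a latent Gaussian process
#' (squared-exponential covariance) on a knot grid; relative sea level is
#' its exact integral, so level and rate posteriors are jointly
#' consistent by construction.  Each index point enters with its own
#' vertical and temporal uncertainty: elevations are Gaussian about the
#' level curve evaluated at a latent true age, and latent ages are given
#' Gaussian priors centred on the observed ages (the errors-in-variables
#' construction).  Limiting points are excluded from the default
#' likelihood.
#'
#' The sampler alternates elliptical slice sampling of the whitened rate
#' vector, a conjugate update of the level offset, Metropolis updates of
#' the latent ages, and Metropolis updates of the GP amplitude and
#' length-scale (half-normal priors).  All draws are reproducible for a
#' fixed `seed`.  A split-chain R-hat on the offset and mean rate above
#' `rhat_limit` triggers a warning — non-convergence is reported, never
#' swallowed.
#'
#' Vertical and temporal input errors are the 2-sigma columns of the SLIP
#' table, converted to 1-sigma internally; vertical sigmas are floored at
#' 0.01 m so that noise-free synthetic data remain usable.
#'
#' @param slips a `slip_table` (see [build_slip()], [sample_slips()]);
#'   only `kind == "precise"` rows enter the likelihood (>= 5 required).
#' @param time_grid output ages, ka BP.  Grid points outside the data
#'   span are flagged in the output (`extrapolated`) with a warning, not
#'   silently returned.
#' @param n_knots rate-process knots spanning the data (default 25).
#' @param n_iter,burn,thin chain length, burn-in, thinning.
#' @param amp_scale,len_scale half-normal prior scales for the GP
#'   amplitude (mm/yr) and length-scale (ka); `len_scale` defaults to
#'   half the data span.
#' @param seed integer master seed.
#' @param rhat_limit convergence warning threshold (default 1.15).
#' @return an object of class `rsl_igp`: `curve` (data.frame with
#'   `time_ka`, `level_mean`, `level_sd`, `level_lo95`, `level_hi95`,
#'   `rate_mean`, `rate_sd`, `rate_lo95`, `rate_hi95`, `extrapolated`),
#'   plus knots, kept draws, diagnostics and the call.  Rates are mm/yr
#'   of rise toward the present (positive = sea level rising).
#' @seealso [mean_rate()] for posterior interval-averaged rates.
#' @export
fit_eiv_igp <- function(slips, time_grid = NULL, n_knots = 25,
                        n_iter = 3000, burn = 1000, thin = 2,
                        amp_scale = 5, len_scale = NULL, seed = 1,
                        rhat_limit = 1.15) {
  n_iter <- as.integer(round(n_iter)); burn <- as.integer(round(burn))
  thin <- max(1L, as.integer(round(thin)))
  if (burn >= n_iter) stop("burn must be smaller than n_iter")
  sl <- as.data.frame(slips)
  sl <- sl[sl$kind == "precise", , drop = FALSE]
  if (nrow(sl) < 5) stop("need at least 5 precise SLIPs")
  if (any(!is.finite(sl$S_2sigma_m)) || any(!is.finite(sl$age_2sigma_ka)))
    stop("non-finite uncertainties in SLIP table")
  t_obs <- sl$age_ka
  y <- sl$S_m
  sy <- pmax(sl$S_2sigma_m / 2, 0.01)
  st <- sl$age_2sigma_ka / 2
  span <- range(t_obs)
  if (is.null(time_grid))
    time_grid <- seq(span[1], span[2], length.out = 100)
  extrap <- time_grid < span[1] | time_grid > span[2]
  if (any(extrap))
    warning(sum(extrap), " grid point(s) outside the data span are ",
            "extrapolations; flagged in the output")
  if (is.null(len_scale)) len_scale <- diff(span) / 2

  pad <- 0.02 * diff(span)
  knots <- seq(min(span[1], min(time_grid)) - pad,
               max(span[2], max(time_grid)) + pad, length.out = n_knots)
  dk <- diff(knots)
  len_min <- diff(range(knots)) / (n_knots - 1) # avoid sub-grid lengths
  D2 <- outer(knots, knots, function(a, b) (a - b)^2)

  # cumulative integral of piecewise-linear rate r over the knots
  cumint <- function(r) c(0, cumsum(dk * (r[-n_knots] + r[-1]) / 2))
  int_at <- function(r, ci, t) {
    j <- findInterval(t, knots, rightmost.closed = TRUE)
    j <- pmin(pmax(j, 1L), n_knots - 1L)
    dt <- t - knots[j]
    sl_ <- (r[j + 1L] - r[j]) / dk[j]
    ci[j] + dt * (r[j] + 0.5 * sl_ * dt)
  }
  chol_k <- function(amp, len)
    t(chol(amp^2 * exp(-D2 / (2 * len^2)) + diag(1e-8, n_knots)))

  loglik <- function(r, beta0, x) {
    lev <- beta0 - int_at(r, cumint(r), x)
    sum(dnorm(y, lev, sy, log = TRUE))
  }
  # The rate field is m_r + GP(0, K): a scalar mean rate plus a
  # zero-mean fluctuation, so the overall trend is not shrunk by the GP
  # prior.  For the slice sampler both linear nuisance parameters (level
  # offset beta0, mean rate m_r; independent N(0, s0^2) / N(0, sm^2)
  # priors) are marginalized out of the likelihood by Woodbury on
  # diag(sy^2) + U P U', U = [1, -(x - t0)].
  s0 <- 100; sm <- 10
  w_inv <- 1 / sy^2
  t0 <- knots[1]
  P_pr <- c(s0^2, sm^2)
  loglik_marg <- function(r, x) {
    z <- y + int_at(r, cumint(r), x)     # z ~ beta0 - m_r (x - t0) + eps
    U <- cbind(1, -(x - t0))
    UD <- U * w_inv
    A <- crossprod(U, UD) + diag(1 / P_pr)
    bvec <- crossprod(UD, z)
    -0.5 * (sum(z^2 * w_inv) - sum(bvec * solve(A, bvec))) -
      0.5 * (determinant(A)$modulus + sum(log(P_pr)))
  }
  # conjugate joint draw of (beta0, m_r) given the GP fluctuation
  draw_linear <- function(r, x) {
    z <- y + int_at(r, cumint(r), x)
    U <- cbind(1, -(x - t0))
    UD <- U * w_inv
    A <- crossprod(U, UD) + diag(1 / P_pr)
    mu <- solve(A, crossprod(UD, z))
    R_ <- chol(A)
    as.numeric(mu + backsolve(R_, rnorm(2)))
  }

  with_substream(seed, "eiv-igp", {
    amp <- amp_scale / 2
    len <- max(len_scale / 2, len_min)
    L <- chol_k(amp, len)
    v <- rnorm(n_knots) * 0.1
    r <- as.numeric(L %*% v)          # GP fluctuation at the knots
    x <- t_obs
    beta0 <- y[which.min(abs(x - knots[1]))]
    m_r <- 0

    keep <- seq(burn + 1L, n_iter, by = thin)
    R <- length(keep)
    rate_draws <- matrix(0, R, n_knots)
    beta0_draws <- numeric(R)
    hyper_draws <- matrix(0, R, 2, dimnames = list(NULL, c("amp", "len")))
    ki <- 0L

    for (it in seq_len(n_iter)) {
      ## 1. elliptical slice sample the whitened rate vector (offset
      ##    marginalized out)
      nu <- rnorm(n_knots)
      logy <- loglik_marg(as.numeric(L %*% v), x) + log(runif(1))
      th <- runif(1, 0, 2 * pi)
      lo <- th - 2 * pi; hi <- th
      repeat {
        v_prop <- v * cos(th) + nu * sin(th)
        r_prop <- as.numeric(L %*% v_prop)
        if (loglik_marg(r_prop, x) > logy) { v <- v_prop; r <- r_prop; break }
        if (th < 0) lo <- th else hi <- th
        th <- runif(1, lo, hi)
      }
      ## 2. conjugate joint draw of level offset and mean rate
      lin <- draw_linear(r, x)
      beta0 <- lin[1]; m_r <- lin[2]
      ## 3. latent true ages (errors-in-variables)
      mv <- st > 0
      if (any(mv)) {
        xp <- x
        xp[mv] <- x[mv] + rnorm(sum(mv), 0, st[mv])
        ci <- cumint(r)
        lev_old <- beta0 - m_r * (x - t0) - int_at(r, ci, x)
        lev_new <- beta0 - m_r * (xp - t0) - int_at(r, ci, xp)
        lr <- dnorm(y, lev_new, sy, log = TRUE) -
          dnorm(y, lev_old, sy, log = TRUE) +
          dnorm(xp, t_obs, pmax(st, 1e-12), log = TRUE) -
          dnorm(x, t_obs, pmax(st, 1e-12), log = TRUE)
        acc <- mv & log(runif(length(x))) < lr
        x[acc] <- xp[acc]
      }
      ## 4. GP hyperparameters (whitened, so r moves with them);
      ##    several sweeps per iteration to decorrelate the length-scale
      for (hs in 1:3) {
        ap <- amp * exp(rnorm(1, 0, 0.25))
        lp <- max(len * exp(rnorm(1, 0, 0.25)), len_min)
        Lp <- chol_k(ap, lp)
        lr <- loglik_marg(as.numeric(Lp %*% v), x) -
          loglik_marg(as.numeric(L %*% v), x) +
          dnorm(ap, 0, amp_scale, log = TRUE) - dnorm(amp, 0, amp_scale, log = TRUE) +
          dnorm(lp, 0, len_scale, log = TRUE) - dnorm(len, 0, len_scale, log = TRUE) +
          log(ap) - log(amp) + log(lp) - log(len)   # log-scale Jacobian
        if (log(runif(1)) < lr) {
          amp <- ap; len <- lp; L <- Lp
          r <- as.numeric(L %*% v)
        }
      }
      if (it %in% keep) {
        ki <- ki + 1L
        rate_draws[ki, ] <- m_r + r
        beta0_draws[ki] <- beta0
        hyper_draws[ki, ] <- c(amp, len)
      }
    }

    ## posterior summaries on the output grid
    lev_draws <- matrix(0, R, length(time_grid))
    rate_grid <- matrix(0, R, length(time_grid))
    for (i in seq_len(R)) {
      ri <- rate_draws[i, ]
      ci <- cumint(ri)
      lev_draws[i, ] <- beta0_draws[i] - int_at(ri, ci, time_grid)
      rate_grid[i, ] <- approx(knots, ri, time_grid, rule = 2)$y
    }
    q <- function(m, p) apply(m, 2, quantile, probs = p)
    curve <- data.frame(time_ka = time_grid,
                        level_mean = colMeans(lev_draws),
                        level_sd = apply(lev_draws, 2, sd),
                        level_lo95 = q(lev_draws, 0.025),
                        level_hi95 = q(lev_draws, 0.975),
                        rate_mean = colMeans(rate_grid),
                        rate_sd = apply(rate_grid, 2, sd),
                        rate_lo95 = q(rate_grid, 0.025),
                        rate_hi95 = q(rate_grid, 0.975),
                        extrapolated = extrap)

    rhat <- c(beta0 = split_rhat(beta0_draws),
              mean_rate = split_rhat(rowMeans(rate_draws)))
    if (any(rhat > rhat_limit, na.rm = TRUE))
      warning("possible non-convergence: split-chain R-hat ",
              paste(sprintf("%s=%.3f", names(rhat), rhat), collapse = ", "),
              " exceeds ", rhat_limit)

    structure(list(curve = curve, knots = knots, rate_draws = rate_draws,
                   beta0_draws = beta0_draws, hyper_draws = hyper_draws,
                   rhat = rhat, n_precise = nrow(sl), span = span,
                   call = match.call()),
              class = "rsl_igp")
  })
}

split_rhat <- function(x) {
  n <- floor(length(x) / 2)
  if (n < 4) return(NA_real_)
  a <- x[seq_len(n)]; b <- x[n + seq_len(n)]
  W <- (var(a) + var(b)) / 2
  B <- n * (mean(a) - mean(b))^2 / 2
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Posterior mean rate of sea-level rise over an age interval (or at a point)
#'
#' Interval averages are computed per posterior draw as the exact mean of
#' the piecewise-linear rate process over the interval, then summarized.
#'
#' @param fit an [fit_eiv_igp()] object.
#' @param interval length-2 ages (ka BP), or a single age for the
#'   pointwise rate.
#' @return named numeric: `mean`, `sd`, `lo95`, `hi95` (mm/yr of rise).
#' @export
mean_rate <- function(fit, interval) {
  stopifnot(inherits(fit, "rsl_igp"))
  knots <- fit$knots
  dk <- diff(knots); nk <- length(knots)
  int_at <- function(r, ci, t) {
    j <- findInterval(t, knots, rightmost.closed = TRUE)
    j <- pmin(pmax(j, 1L), nk - 1L)
    dt <- t - knots[j]
    sl_ <- (r[j + 1L] - r[j]) / dk[j]
    ci[j] + dt * (r[j] + 0.5 * sl_ * dt)
  }
  vals <- apply(fit$rate_draws, 1, function(r) {
    if (length(interval) == 1)
      return(approx(knots, r, interval, rule = 2)$y)
    ci <- c(0, cumsum(dk * (r[-nk] + r[-1]) / 2))
    a <- min(interval); b <- max(interval)
    (int_at(r, ci, b) - int_at(r, ci, a)) / (b - a)
  })
  c(mean = mean(vals), sd = sd(vals),
    lo95 = unname(quantile(vals, 0.025)),
    hi95 = unname(quantile(vals, 0.975)))
}

#' @export
print.rsl_igp <- function(x, ...) {
  cat(sprintf("EIV-IGP sea-level fit: %d precise SLIPs, %.2f-%.2f ka BP\n",
              x$n_precise, x$span[1], x$span[2]))
  cat(sprintf("  %d posterior draws; split R-hat: beta0 %.3f, mean rate %.3f\n",
              nrow(x$rate_draws), x$rhat["beta0"], x$rhat["mean_rate"]))
  cat(sprintf("  level at youngest grid age: %.2f m; rate range %.2f to %.2f mm/yr\n",
              x$curve$level_mean[which.min(x$curve$time_ka)],
              min(x$curve$rate_mean), max(x$curve$rate_mean)))
  invisible(x)
}

#' @export
summary.rsl_igp <- function(object, ...) {
  print(object)
  cat("\nPosterior curve (head):\n")
  print(head(object$curve[, c("time_ka", "level_mean", "level_sd",
                              "rate_mean", "rate_sd")]), digits = 3)
  invisible(object)
}

#' @export
predict.rsl_igp <- function(object, times, ...) {
  cv <- object$curve
  data.frame(time_ka = times,
             level_mean = approx(cv$time_ka, cv$level_mean, times, rule = 2)$y,
             level_sd = approx(cv$time_ka, cv$level_sd, times, rule = 2)$y,
             rate_mean = approx(cv$time_ka, cv$rate_mean, times, rule = 2)$y,
             rate_sd = approx(cv$time_ka, cv$rate_sd, times, rule = 2)$y)
}

#' @export
plot.rsl_igp <- function(x, what = c("level", "rate"), ...) {
  what <- match.arg(what)
  cv <- x$curve[order(x$curve$time_ka), ]
  if (what == "level") {
    plot(cv$time_ka, cv$level_mean, type = "n",
         xlim = rev(range(cv$time_ka)),
         xlab = "Age (ka BP)", ylab = "RSL (m)", ...)
    polygon(c(cv$time_ka, rev(cv$time_ka)),
            c(cv$level_lo95, rev(cv$level_hi95)),
            col = gray(0.85), border = NA)
    lines(cv$time_ka, cv$level_mean, lwd = 2)
  } else {
    plot(cv$time_ka, cv$rate_mean, type = "n",
         xlim = rev(range(cv$time_ka)),
         xlab = "Age (ka BP)", ylab = "Rate of rise (mm/yr)", ...)
    polygon(c(cv$time_ka, rev(cv$time_ka)),
            c(cv$rate_lo95, rev(cv$rate_hi95)),
            col = gray(0.85), border = NA)
    lines(cv$time_ka, cv$rate_mean, lwd = 2)
    abline(h = 0, lty = 3)
  }
  invisible(x)
}
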