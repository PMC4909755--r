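# Simulation-based inference of the fragmentation bias exponent mu.
#
# The dispersion sigma(ln v) of leaf volumes at a fixed region count n_pu
# decreases, on average, with the bias mu. Simulating the fragmentation
# process over a grid of mu values gives, at each grid point, the sampling
# distribution of sigma; its empirical quantile band is an acceptance
# envelope, and the set of mu at which an observed sigma falls inside the
# band is a simulation-based confidence interval for mu.

#' Quantile envelope of sigma(ln v) over a mu grid
#'
#' For each value on `mu_grid`, runs `n_sims` independent fragmentations to
#' `n_pu` regions and records the within-run standard deviation of
#' log leaf volume; the envelope consists of the `q_low`, median and
#' `q_high` empirical quantiles per grid point (defaults give a 90 percent
#' band).
#'
#' @param n_pu number of regions per simulated brain (>= 3).
#' @param mu_grid ascending numeric grid of bias exponents.
#' @param n_sims simulations per grid point (>= 100; the default mirrors the
#'   1000-simulation band used for the species intervals).
#' @param noise_sd multiplicative split noise (default 0.10).
#' @param q_low,q_high quantile levels of the band.
#' @param seed optional integer seed.
#' @param keep_draws keep the full matrix of simulated sigmas (one column
#'   per grid point) in the result.
#' @return object of class `sigma_envelope` with fields `mu_grid`, `n_pu`,
#'   `n_sims`, `noise_sd`, `q_low`, `q_high`, `lower_band`, `median_band`,
#'   `upper_band` and optionally `draws`.
#' @export
sigma_envelope <- function(n_pu, mu_grid = seq(-0.8, 0.8, by = 0.02),
                           n_sims = 1000L, noise_sd = 0.1,
                           q_low = 0.05, q_high = 0.95, seed = NULL,
                           keep_draws = FALSE) {
  stopifnot(n_pu >= 3, n_sims >= 100)
  stopifnot(is.numeric(mu_grid), length(mu_grid) >= 1L,
            !is.unsorted(mu_grid, strictly = TRUE))
  stopifnot(q_low >= 0, q_high <= 1, q_low < q_high)
  if (!is.null(seed)) set.seed(seed)
  sig <- vapply(mu_grid, function(mu) {
    cpp_sigma_ensemble(as.integer(n_pu), mu, noise_sd, as.integer(n_sims), 1)
  }, numeric(n_sims))
  sig <- matrix(sig, nrow = n_sims)
  structure(
    list(mu_grid = mu_grid, n_pu = as.integer(n_pu),
         n_sims = as.integer(n_sims), noise_sd = noise_sd,
         q_low = q_low, q_high = q_high,
         lower_band = apply(sig, 2L, quantile, probs = q_low, names = FALSE),
         median_band = apply(sig, 2L, median),
         upper_band = apply(sig, 2L, quantile, probs = q_high, names = FALSE),
         draws = if (keep_draws) sig else NULL),
    class = "sigma_envelope")
}

#' @export
print.sigma_envelope <- function(x, ...) {
  cat(sprintf(
    "sigma(ln v) envelope: n_pu = %d, %d sims/point, %d mu values in [%g, %g]\n",
    x$n_pu, x$n_sims, length(x$mu_grid), min(x$mu_grid), max(x$mu_grid)))
  cat(sprintf("  band: %.0f%%-%.0f%% quantiles, split noise sd = %g\n",
              100 * x$q_low, 100 * x$q_high, x$noise_sd))
  invisible(x)
}

#' @export
as.data.frame.sigma_envelope <- function(x, ...) {
  data.frame(mu = x$mu_grid, lower = x$lower_band, median = x$median_band,
             upper = x$upper_band)
}

#' @export
plot.sigma_envelope <- function(x, sigma_obs = NULL, ...) {
  plot(x$mu_grid, x$median_band, type = "n",
       ylim = range(x$lower_band, x$upper_band, sigma_obs),
       xlab = expression(mu), ylab = expression(sigma(ln ~ v)), ...)
  polygon(c(x$mu_grid, rev(x$mu_grid)),
          c(x$lower_band, rev(x$upper_band)),
          col = adjustcolor("steelblue", 0.3), border = NA)
  lines(x$mu_grid, x$median_band, lwd = 2, col = "steelblue4")
  if (!is.null(sigma_obs)) abline(h = sigma_obs, lty = 2)
  invisible(x)
}

# linearly interpolated crossing of a band with level s between grid
# points i and i+1
.band_cross <- function(mu, band, i, s) {
  if (band[i + 1L] == band[i]) return(mu[i + 1L])
  mu[i] + (s - band[i]) / (band[i + 1L] - band[i]) * (mu[i + 1L] - mu[i])
}

#' Invert a sigma envelope into a confidence interval for mu
#'
#' Returns the smallest and largest mu at which `sigma_obs` lies inside the
#' envelope's quantile band, interpolating linearly between grid points on
#' whichever band is crossed. The scan considers every grid cell, so a
#' non-monotone (noisy) band cannot silently truncate the interval. `NA`
#' endpoints flag an observed sigma outside the band over the whole grid.
#'
#' @param sigma_obs observed standard deviation of log region volumes
#'   (natural-log units, positive).
#' @param envelope a [sigma_envelope()] result.
#' @return object of class `mu_interval` with fields `mu_low`, `mu_high`,
#'   `sigma_obs`, `n_pu`.
#' @export
infer_mu_interval <- function(sigma_obs, envelope) {
  stopifnot(inherits(envelope, "sigma_envelope"))
  if (!is.numeric(sigma_obs) || length(sigma_obs) != 1L ||
      is.na(sigma_obs) || sigma_obs <= 0) {
    stop("'sigma_obs' must be a single positive number")
  }
  mu <- envelope$mu_grid
  lo <- envelope$lower_band
  hi <- envelope$upper_band
  inside <- lo <= sigma_obs & sigma_obs <= hi
  if (!any(inside)) {
    out <- list(mu_low = NA_real_, mu_high = NA_real_,
                sigma_obs = sigma_obs, n_pu = envelope$n_pu)
    class(out) <- "mu_interval"
    return(out)
  }
  first <- which(inside)[1L]
  last <- which(inside)[length(which(inside))]
  mu_low <- mu[first]
  if (first > 1L) {
    i <- first - 1L
    band <- if (sigma_obs < lo[i]) lo else hi
    mu_low <- .band_cross(mu, band, i, sigma_obs)
  }
  mu_high <- mu[last]
  if (last < length(mu)) {
    # crossing out of the band between last and last+1
    band <- if (sigma_obs < lo[last + 1L]) lo else hi
    mu_high <- .band_cross(mu, band, last, sigma_obs)
  }
  structure(list(mu_low = mu_low, mu_high = mu_high,
                 sigma_obs = sigma_obs, n_pu = envelope$n_pu),
            class = "mu_interval")
}

#' @export
print.mu_interval <- function(x, ...) {
  if (is.na(x$mu_low)) {
    cat(sprintf(
      "No mu on the grid is consistent with sigma_obs = %.3f (n_pu = %d)\n",
      x$sigma_obs, x$n_pu))
  } else {
    cat(sprintf("mu consistent with sigma_obs = %.3f at n_pu = %d:\n",
                x$sigma_obs, x$n_pu))
    cat(sprintf("  %.3f <= mu <= %.3f\n", x$mu_low, x$mu_high))
  }
  invisible(x)
}

#' Fit the fragmentation bias exponent to observed region volumes
#'
#' The top-level estimator: given either a vector of region volumes or a
#' pre-computed dispersion `sigma_obs` with its region count `n_pu`, builds
#' (or reuses) a [sigma_envelope()] and inverts it with
#' [infer_mu_interval()]. The point estimate is the mu at which the median
#' simulated sigma equals the observed one (linear interpolation); the
#' confidence interval is the envelope inversion.
#'
#' @param volumes positive numeric vector of leaf-region volumes; overrides
#'   `sigma_obs`/`n_pu` when given.
#' @param sigma_obs observed sd of log volumes (natural-log units).
#' @param n_pu number of regions behind `sigma_obs`.
#' @param envelope optional pre-computed [sigma_envelope()] for this `n_pu`
#'   (re-used as-is; its `n_pu` must match).
#' @inheritParams sigma_envelope
#' @return object of class `mu_fit`; see [coef.mu_fit()], [confint.mu_fit()],
#'   [plot.mu_fit()].
#' @examples
#' \donttest{
#' fit <- estimate_mu(sigma_obs = 1.24, n_pu = 91, n_sims = 200, seed = 1)
#' fit
#' confint(fit)
#' }
#' @export
estimate_mu <- function(volumes = NULL, sigma_obs = NULL, n_pu = NULL,
                        mu_grid = seq(-0.8, 0.8, by = 0.02),
                        n_sims = 1000L, noise_sd = 0.1,
                        q_low = 0.05, q_high = 0.95, seed = NULL,
                        envelope = NULL) {
  cl <- match.call()
  if (!is.null(volumes)) {
    fit <- fit_log_gaussian(volumes)
    sigma_obs <- fit$sigma
    n_pu <- fit$n
  }
  if (is.null(sigma_obs) || is.null(n_pu)) {
    stop("supply either 'volumes' or both 'sigma_obs' and 'n_pu'")
  }
  if (is.null(envelope)) {
    envelope <- sigma_envelope(n_pu, mu_grid = mu_grid, n_sims = n_sims,
                               noise_sd = noise_sd, q_low = q_low,
                               q_high = q_high, seed = seed)
  } else {
    stopifnot(inherits(envelope, "sigma_envelope"))
    if (envelope$n_pu != n_pu) {
      stop("supplied envelope was built for n_pu = ", envelope$n_pu,
           ", not ", n_pu)
    }
  }
  interval <- infer_mu_interval(sigma_obs, envelope)
  # point estimate: median band crossing
  med <- envelope$median_band
  mu <- envelope$mu_grid
  mu_hat <- NA_real_
  sgn <- sign(med - sigma_obs)
  hit <- which(sgn == 0)
  if (length(hit)) {
    mu_hat <- mu[hit[1L]]
  } else {
    cross <- which(sgn[-1L] * sgn[-length(sgn)] < 0)
    if (length(cross)) mu_hat <- .band_cross(mu, med, cross[1L], sigma_obs)
  }
  structure(list(call = cl, sigma_obs = sigma_obs, n_pu = as.integer(n_pu),
                 mu_hat = mu_hat, interval = interval, envelope = envelope),
            class = "mu_fit")
}

#' @export
print.mu_fit <- function(x, ...) {
  cat("Fragmentation bias exponent fit\n")
  cat(sprintf("  observed sigma(ln v) = %.4f over %d regions\n",
              x$sigma_obs, x$n_pu))
  cat(sprintf("  mu point estimate (median-band crossing): %s\n",
              if (is.na(x$mu_hat)) "outside grid" else
                sprintf("%.3f", x$mu_hat)))
  print(x$interval)
  invisible(x)
}

#' @rdname estimate_mu
#' @param object,x a `mu_fit`.
#' @param ... unused.
#' @export
summary.mu_fit <- function(object, ...) {
  env <- object$envelope
  cat("Fragmentation bias exponent fit\n")
  cat(sprintf("  envelope: n_pu = %d, %d sims/point, grid [%g, %g] (%d pts)\n",
              env$n_pu, env$n_sims, min(env$mu_grid), max(env$mu_grid),
              length(env$mu_grid)))
  cat(sprintf("  band %g-%g quantiles, split noise sd %g\n",
              env$q_low, env$q_high, env$noise_sd))
  print.mu_fit(object)
  invisible(object)
}

#' @rdname estimate_mu
#' @export
coef.mu_fit <- function(object, ...) c(mu = object$mu_hat)

#' @rdname estimate_mu
#' @param parm,level ignored; the interval level is fixed by the envelope's
#'   quantile band.
#' @export
confint.mu_fit <- function(object, parm, level, ...) {
  env <- object$envelope
  out <- matrix(c(object$interval$mu_low, object$interval$mu_high), 1L,
                dimnames = list("mu", sprintf("%g %%", 100 * c(env$q_low,
                                                               env$q_high))))
  out
}

#' @rdname estimate_mu
#' @export
plot.mu_fit <- function(x, ...) {
  plot(x$envelope, sigma_obs = x$sigma_obs, ...)
  iv <- x$interval
  if (!is.na(iv$mu_low)) abline(v = c(iv$mu_low, iv$mu_high), lty = 3)
  invisible(x)
}
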