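# Lognormality diagnostics for region-volume samples.
#
# Region volumes across species look lognormal: the histogram of ln(volume)
# is well fit by a Gaussian. These helpers fit that Gaussian, test the fit
# (one-sample KS), and produce Q-Q data. All logarithms are natural logs, so
# the reported sigma is in natural-log units.

check_volumes <- function(volumes) {
  if (!is.numeric(volumes) || length(volumes) < 2L) {
    stop("'volumes' must be a numeric vector with at least 2 values")
  }
  if (anyNA(volumes) || any(volumes <= 0)) {
    stop("all volumes must be positive (drop zero-volume records first, ",
         "see filter_volumes())")
  }
  invisible(volumes)
}

#' Gaussian fit to log volumes
#'
#' Sample mean and standard deviation (n - 1 denominator) of `log(volumes)`.
#'
#' @param volumes positive numeric vector of region volumes.
#' @return an object of class `lognormal_fit` with fields `log_mean`,
#'   `sigma` and `n`.
#' @examples
#' fit_log_gaussian(c(exp(1), exp(3)))  # log_mean 2, sigma sqrt(2)
#' @export
fit_log_gaussian <- function(volumes) {
  check_volumes(volumes)
  lv <- log(volumes)
  structure(list(log_mean = mean(lv), sigma = sd(lv), n = length(lv)),
            class = "lognormal_fit")
}

#' @export
print.lognormal_fit <- function(x, ...) {
  cat("Gaussian fit to log volumes (natural-log units)\n")
  cat(sprintf("  n = %d, mean(ln v) = %.4f, sigma(ln v) = %.4f\n",
              x$n, x$log_mean, x$sigma))
  invisible(x)
}

#' Kolmogorov-Smirnov test of lognormality
#'
#' One-sample KS test of `log(volumes)` against a normal distribution with
#' mean and sd fitted from the same sample. The default p-value is the
#' classical KS p-value; because the reference parameters are estimated from
#' the data it is anti-conservative (the Lilliefors situation), so a
#' Monte-Carlo Lilliefors p-value is available via `lilliefors = TRUE`.
#'
#' @inheritParams fit_log_gaussian
#' @param lilliefors if `TRUE`, replace the classical p-value by a
#'   parametric-bootstrap p-value (re-fitting on each resample).
#' @param n_boot bootstrap resamples for the Lilliefors p-value.
#' @param seed optional seed for the bootstrap.
#' @return an object of class `ks_lognormality` with fields `statistic`
#'   (KS D), `p_value`, `method` and the underlying `fit`.
#' @export
ks_lognormality <- function(volumes, lilliefors = FALSE, n_boot = 1000L,
                            seed = NULL) {
  fit <- fit_log_gaussian(volumes)
  lv <- log(volumes)
  kt <- suppressWarnings(
    ks.test(lv, "pnorm", mean = fit$log_mean, sd = fit$sigma))
  d <- unname(kt$statistic)
  p <- unname(kt$p.value)
  method <- "classical"
  if (lilliefors) {
    if (!is.null(seed)) set.seed(seed)
    n <- fit$n
    d_boot <- vapply(seq_len(n_boot), function(i) {
      x <- rnorm(n)
      unname(suppressWarnings(
        ks.test(x, "pnorm", mean = mean(x), sd = sd(x)))$statistic)
    }, numeric(1))
    p <- (sum(d_boot >= d) + 1) / (n_boot + 1)
    method <- "lilliefors"
  }
  structure(list(statistic = d, p_value = p, method = method, fit = fit),
            class = "ks_lognormality")
}

#' @export
print.ks_lognormality <- function(x, ...) {
  cat(sprintf("KS test of lognormality (%s p-value)\n", x$method))
  cat(sprintf("  D = %.4f, p = %.4g  (n = %d, sigma = %.3f)\n",
              x$statistic, x$p_value, x$fit$n, x$fit$sigma))
  invisible(x)
}

#' Q-Q data for the lognormal fit
#'
#' Pairs of theoretical normal quantiles (at plotting positions
#' `(i - 0.5)/n` under the fitted normal) and ordered observed log volumes.
#'
#' @inheritParams fit_log_gaussian
#' @return data frame with columns `theoretical` and `observed`.
#' @export
qq_points <- function(volumes) {
  fit <- fit_log_gaussian(volumes)
  n <- fit$n
  obs <- sort(log(volumes))
  theo <- qnorm((seq_len(n) - 0.5) / n, mean = fit$log_mean, sd = fit$sigma)
  data.frame(theoretical = theo, observed = obs)
}

#' Extract positive leaf volumes from a region table
#'
#' Atlas hierarchy tables contain internal (branch-point) rows and leaves
#' recorded with zero volume; only leaves with positive volume enter the
#' size-distribution analysis. Accepts a `parc_tree` or a data frame with a
#' `volume` column (and optionally `is_leaf`; if absent, leaf status is
#' derived from `id`/`parent_id`, else all rows count as leaves).
#'
#' @param x a `parc_tree` or data frame of region records.
#' @return numeric vector of positive leaf volumes; a message reports how
#'   many records were dropped, and an empty result triggers a warning.
#' @export
filter_volumes <- function(x) {
  if (is_parc_tree(x)) x <- as.data.frame(x)
  if (!is.data.frame(x) || is.null(x$volume)) {
    stop("'x' must be a parc_tree or a data frame with a 'volume' column")
  }
  leaf <- if (!is.null(x$is_leaf)) {
    as.logical(x$is_leaf)
  } else if (!is.null(x$id) && !is.null(x$parent_id)) {
    !(x$id %in% x$parent_id[!is.na(x$parent_id)])
  } else {
    rep(TRUE, nrow(x))
  }
  keep <- leaf & !is.na(x$volume) & x$volume > 0
  dropped <- sum(leaf) - sum(keep)   # leaves lost to zero/missing volume
  if (dropped > 0L) {
    message(dropped, " leaf record(s) dropped (non-positive volume)")
  }
  out <- as.numeric(x$volume[keep])
  if (length(out) == 0L) warning("no positive leaf volumes in input")
  out
}
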