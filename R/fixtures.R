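# Synthetic fixtures: lognormal volume sets, atlas-style hierarchy tables
# and power-law FLN matrices with planted exponents. Everything downstream
# can be exercised on these generators alone; they are seeded and
# bit-reproducible.

#' Lognormal region-volume sample
#'
#' @param n number of regions.
#' @param log_mean mean of log volume.
#' @param sigma standard deviation of log volume (natural-log units); the
#'   species-scale dispersions are around 1.2-1.5.
#' @param seed optional integer seed.
#' @return positive numeric vector of length `n`.
#' @export
make_lognormal_volumes <- function(n, log_mean = 0, sigma = 1.24,
                                   seed = NULL) {
  stopifnot(n >= 1, sigma >= 0)
  if (!is.null(seed)) set.seed(seed)
  rlnorm(n, meanlog = log_mean, sdlog = sigma)
}

#' Atlas-style hierarchy table with zero-volume leaves
#'
#' Runs a uniform fragmentation to `n_leaves` regions and returns the flat
#' parent-child table (id, parent_id, name, volume, birth_step, is_leaf),
#' with `floor(zero_fraction * n_leaves)` randomly chosen leaves set to
#' volume 0 — mimicking atlas tables in which some delineated leaves carry
#' no volume annotation and must be filtered before analysis.
#'
#' @param n_leaves number of leaf regions (>= 2).
#' @param zero_fraction fraction of leaves zeroed out, in `[0, 1)`.
#' @param mu bias exponent of the generating fragmentation.
#' @param seed optional integer seed.
#' @return data frame of region records.
#' @export
make_hierarchy_fixture <- function(n_leaves, zero_fraction = 0, mu = 0,
                                   seed = NULL) {
  stopifnot(n_leaves >= 2, zero_fraction >= 0, zero_fraction < 1)
  if (!is.null(seed)) set.seed(seed)
  tree <- run_fragmentation(mu = mu, n_target = n_leaves)
  tab <- as.data.frame(tree)
  n_zero <- floor(zero_fraction * n_leaves)
  if (n_zero > 0L) {
    leaf_rows <- which(tab$is_leaf)
    tab$volume[sample(leaf_rows, n_zero)] <- 0
  }
  tab
}

#' FLN matrix with a planted power-law exponent
#'
#' Builds a square target-by-source matrix whose row entries are
#' `v_j^exponent` times lognormal multiplicative noise, zeroes a random
#' `zero_fraction` of off-diagonal entries (missing-at-random, as in sparse
#' tracer data), sets the diagonal to zero, and row-normalizes to FLN. With
#' `noise_sigma = 0` the planted exponent is recovered exactly by
#' [fit_power_law()] on any row.
#'
#' @param volumes positive source/target volumes (square matrix,
#'   `length(volumes)` regions).
#' @param exponent planted scaling exponent of strength vs source volume.
#' @param noise_sigma sd of the lognormal scatter on log strengths.
#' @param zero_fraction fraction of off-diagonal entries zeroed, `[0, 1)`.
#' @param seed optional integer seed.
#' @return an FLN `connectome`.
#' @export
make_power_law_fln <- function(volumes, exponent, noise_sigma = 0,
                               zero_fraction = 0, seed = NULL) {
  if (!is.numeric(volumes) || anyNA(volumes) || any(volumes <= 0)) {
    stop("all volumes must be positive")
  }
  stopifnot(noise_sigma >= 0, zero_fraction >= 0, zero_fraction < 1)
  if (!is.null(seed)) set.seed(seed)
  n <- length(volumes)
  base <- matrix(rep(volumes^exponent, each = n), n)   # row i: v_j^exponent
  noise <- matrix(rlnorm(n * n, 0, noise_sigma), n)
  M <- base * noise
  diag(M) <- 0
  if (zero_fraction > 0) {
    off <- which(row(M) != col(M))
    n_zero <- floor(zero_fraction * length(off))
    if (n_zero > 0L) M[sample(off, n_zero)] <- 0
  }
  labels <- paste0("area_", seq_len(n))
  normalize_fln(connectome(M, target_labels = labels,
                           source_labels = labels))
}

#' Noise level giving a target r-squared for a planted power law
#'
#' For log strengths `exponent * log(v) + noise`, the expected log-log fit
#' r-squared is `s2 / (s2 + noise_sigma^2)` with
#' `s2 = exponent^2 * var(log v)`; inverting gives the noise sd that lands
#' the fit at a chosen `r_squared` (used to emulate the observed scatter of
#' tracer data, e.g. the r-squared ~ 0.62 regime).
#'
#' @param volumes positive volumes the fixture will use.
#' @param exponent planted exponent.
#' @param r_squared target fraction of log-strength variance explained.
#' @return noise sd on the log scale.
#' @export
noise_for_r_squared <- function(volumes, exponent, r_squared) {
  stopifnot(r_squared > 0, r_squared < 1)
  s2 <- exponent^2 * var(log(volumes))
  sqrt(s2 * (1 - r_squared) / r_squared)
}
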