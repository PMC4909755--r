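# Outer-product macroconnectome and power-law exponent fits.
#
# If every pair of neurons is connected with probability f at the tabula
# rasa stage and parcellation merely partitions neurons into regions of
# volume v_i (constant neuron density rho), the number of connections
# between regions i and j is C_ij = f * rho^2 * v_i * v_j / 2: a rank-one
# (outer-product) matrix. Row-normalizing C to the fraction of labeled
# neurons (FLN) makes each row proportional to the source volume alone, so
# the model's baseline prediction for the incoming scaling exponent is
# eta = 1. Empirical exponents are estimated by OLS of log strength on log
# source volume over the non-zero connections.

#' Connectivity matrices
#'
#' A `connectome` is a non-negative numeric matrix with rows = target
#' regions and columns = source regions, plus a flag recording whether rows
#' have been normalized to FLN (fraction of labeled neurons).
#'
#' @param values non-negative numeric matrix (targets x sources).
#' @param target_labels,source_labels optional dimension labels.
#' @param normalized whether rows are FLN-normalized.
#' @return object of class `connectome` (a matrix with attributes).
#' @export
connectome <- function(values, target_labels = NULL, source_labels = NULL,
                       normalized = FALSE) {
  values <- as.matrix(values)
  if (any(values < 0)) stop("connectivity entries must be non-negative")
  if (!is.null(target_labels)) rownames(values) <- target_labels
  if (!is.null(source_labels)) colnames(values) <- source_labels
  structure(values, normalized = isTRUE(normalized),
            class = c("connectome", class(values)))
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("%s connectivity matrix: %d targets x %d sources\n",
              if (attr(x, "normalized")) "FLN-normalized" else "Raw",
              nrow(x), ncol(x)))
  cat(sprintf("  non-zero entries: %d / %d\n", sum(x > 0), length(x)))
  invisible(x)
}

#' @rdname connectome
#' @param x object to test.
#' @export
is_fln <- function(x) inherits(x, "connectome") && isTRUE(attr(x, "normalized"))

#' Outer-product connectome predicted by the parcellation model
#'
#' Builds `C[i, j] = f * rho^2 * v_i * v_j / 2`. By default the diagonal
#' (within-region connections) is set to zero, matching how tracer-derived
#' region-to-region matrices report extrinsic connections only;
#' `include_diagonal = TRUE` keeps the self blocks so that, with neuron
#' counts `n_i = rho * v_i`, the total count sums to `f * N^2 / 2`.
#'
#' @param volumes positive region volumes.
#' @param f pairwise connection probability at the tabula rasa stage,
#'   in `[0, 1]`.
#' @param rho neuron number density (neurons per unit volume), constant
#'   across regions.
#' @param include_diagonal keep within-region (diagonal) counts.
#' @param labels optional region labels.
#' @return a raw `connectome`.
#' @examples
#' outer_product_connectome(c(1, 1), f = 1, rho = 1)  # off-diagonal 0.5
#' @export
outer_product_connectome <- function(volumes, f = 1, rho = 1,
                                     include_diagonal = FALSE,
                                     labels = NULL) {
  if (!is.numeric(volumes) || length(volumes) < 1L || anyNA(volumes) ||
      any(volumes <= 0)) {
    stop("all volumes must be positive")
  }
  if (!is.numeric(f) || length(f) != 1L || is.na(f) || f < 0 || f > 1) {
    stop("'f' must be in [0, 1]")
  }
  stopifnot(rho > 0)
  C <- f * rho^2 * outer(volumes, volumes) / 2
  if (!include_diagonal) diag(C) <- 0
  if (is.null(labels)) labels <- paste0("area_", seq_along(volumes))
  connectome(C, target_labels = labels, source_labels = labels,
             normalized = FALSE)
}

#' Row-normalize a connectome to FLN
#'
#' Divides each row by its sum, giving the fraction of labeled neurons: the
#' share of a target's inputs contributed by each source. Rows that are
#' entirely zero are left as zero and reported with a warning.
#'
#' @param C a raw `connectome` (or plain non-negative matrix).
#' @return an FLN `connectome` whose non-zero rows sum to 1.
#' @export
normalize_fln <- function(C) {
  if (is_fln(C)) stop("'C' is already FLN-normalized")
  M <- unclass(C)
  attr(M, "normalized") <- NULL
  if (any(M < 0)) stop("connectivity entries must be non-negative")
  rs <- rowSums(M)
  zero <- rs == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero row(s) left unnormalized")
    rs[zero] <- 1
  }
  connectome(M / rs, target_labels = rownames(M), source_labels = colnames(M),
             normalized = TRUE)
}

#' Log-log power-law fit of connection strength against volume
#'
#' Ordinary least squares of `log(strength)` on `log(volume)`, restricted to
#' strictly positive strengths (zero connections carry no information about
#' the scaling and are never floored). The slope is the scaling exponent
#' (eta for incoming FLN vs source volume, kappa for outgoing counts vs
#' source volume).
#'
#' @param strengths non-negative connection strengths.
#' @param volumes positive volumes aligned with `strengths`.
#' @return object of class `powerlaw_fit` with fields `exponent`,
#'   `intercept` (natural-log intercept), `r`, `r_squared`, `n_points`.
#' @examples
#' v <- exp(seq(0, 3, length.out = 20))
#' fit_power_law(v^2.33, v)  # exponent 2.33, r^2 = 1
#' @export
fit_power_law <- function(strengths, volumes) {
  stopifnot(length(strengths) == length(volumes))
  if (anyNA(volumes) || any(volumes <= 0)) stop("all volumes must be positive")
  if (anyNA(strengths) || any(strengths < 0)) {
    stop("strengths must be non-negative")
  }
  use <- strengths > 0
  if (sum(use) < 3L) {
    stop("insufficient data: need at least 3 non-zero strengths")
  }
  s <- strengths[use]
  v <- volumes[use]
  if (max(v) / min(v) < 1.001) {
    stop("degenerate fit: volume spread (max/min) below 1.001")
  }
  x <- log(v)
  y <- log(s)
  fit <- lm(y ~ x)
  r <- cor(x, y)
  structure(list(exponent = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 r = r, r_squared = r^2, n_points = sum(use)),
            class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf(
    "Power-law fit: exponent = %.4f, intercept = %.4f (natural log)\n",
    x$exponent, x$intercept))
  cat(sprintf("  r = %.3f, r^2 = %.3f, n = %d non-zero points\n",
              x$r, x$r_squared, x$n_points))
  invisible(x)
}

#' @export
coef.powerlaw_fit <- function(object, ...) {
  c(exponent = object$exponent, intercept = object$intercept)
}

resolve_ids <- function(ids, labels, n, what) {
  if (is.null(ids)) return(seq_len(n))
  if (is.character(ids)) {
    pos <- match(ids, labels)
    if (anyNA(pos)) stop("unknown ", what, ": ",
                         paste(ids[is.na(pos)], collapse = ", "))
    return(pos)
  }
  ids <- as.integer(ids)
  if (any(ids < 1L | ids > n)) stop(what, " index out of range")
  ids
}

#' Incoming-connection scaling exponents (eta)
#'
#' For each selected target row of an FLN matrix, fits the row's non-zero
#' strengths against the source volumes with [fit_power_law()]. In pooled
#' mode the selected rows' points are stacked into one regression, each
#' point weighted equally.
#'
#' @param C_fln FLN-normalized `connectome`.
#' @param volumes source-region volumes aligned with the columns.
#' @param targets target rows (indices or labels); default all.
#' @param pooled stack all selected rows into a single fit.
#' @return a `powerlaw_fit` (pooled) or a named list of `powerlaw_fit`.
#' @export
fit_incoming <- function(C_fln, volumes, targets = NULL, pooled = FALSE) {
  if (!is_fln(C_fln)) stop("'C_fln' must be an FLN-normalized connectome")
  stopifnot(length(volumes) == ncol(C_fln))
  rows <- resolve_ids(targets, rownames(C_fln), nrow(C_fln), "target")
  if (pooled) {
    s <- as.vector(t(unclass(C_fln)[rows, , drop = FALSE]))
    v <- rep(volumes, times = length(rows))
    return(fit_power_law(s, v))
  }
  out <- lapply(rows, function(i) fit_power_law(unclass(C_fln)[i, ], volumes))
  names(out) <- if (!is.null(rownames(C_fln))) rownames(C_fln)[rows] else rows
  if (length(out) == 1L) out[[1L]] else out
}

#' Outgoing-connection scaling exponents (kappa)
#'
#' For each selected source column, fits the column's non-zero entries
#' against the target volumes: the outgoing analogue `C[i, j]` proportional
#' to `v_i^kappa`.
#'
#' @param C a `connectome` (raw or FLN).
#' @param volumes target-region volumes aligned with the rows.
#' @param sources source columns (indices or labels); default all.
#' @return a `powerlaw_fit` or a named list of them.
#' @export
fit_outgoing <- function(C, volumes, sources = NULL) {
  stopifnot(inherits(C, "connectome") || is.matrix(C))
  stopifnot(length(volumes) == nrow(C))
  cols <- resolve_ids(sources, colnames(C), ncol(C), "source")
  out <- lapply(cols, function(j) fit_power_law(unclass(C)[, j], volumes))
  names(out) <- if (!is.null(colnames(C))) colnames(C)[cols] else cols
  if (length(out) == 1L) out[[1L]] else out
}
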