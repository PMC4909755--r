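# Multiplicative Hebbian plasticity and its power-law fixed point.
#
# Connection strengths evolve under
#   dC_ij/dt = eps1 * f_i^alpha * C_ij^beta * f_j^gamma - eps2 * C_ij,
# where f_i is the activity level of area i. With activity proportional to
# area volume (f_i = v_i by default), the non-trivial equilibrium is
#   C*_ij = (eps1/eps2)^(1/(1-beta)) * f_i^(alpha/(1-beta)) * f_j^(gamma/(1-beta)),
# an outer-product power law with incoming exponent eta = gamma/(1-beta)
# and outgoing exponent kappa = alpha/(1-beta). For beta < 1 this branch is
# attracting from positive initial conditions and C = 0 is itself a
# solution (beta > 0), so zero connections stay zero.

#' Hebbian rule parameters
#'
#' @param alpha,beta,gamma exponents of the plasticity rule; `beta` is the
#'   self-reinforcement exponent and must differ from 1 for the closed-form
#'   equilibrium.
#' @param eps1,eps2 positive growth and decay coefficients.
#' @return object of class `hebbian_params`.
#' @export
hebbian_params <- function(alpha, beta, gamma, eps1 = 1, eps2 = 1) {
  stopifnot(is.numeric(alpha), is.numeric(beta), is.numeric(gamma),
            length(alpha) == 1L, length(beta) == 1L, length(gamma) == 1L,
            is.finite(alpha), is.finite(beta), is.finite(gamma))
  if (!(eps1 > 0) || !(eps2 > 0)) stop("eps1 and eps2 must be positive")
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 eps1 = eps1, eps2 = eps2),
            class = "hebbian_params")
}

#' @export
print.hebbian_params <- function(x, ...) {
  cat(sprintf(
    "Hebbian rule: dC/dt = %g f_i^%g C^%g f_j^%g - %g C\n",
    x$eps1, x$alpha, x$beta, x$gamma, x$eps2))
  invisible(x)
}

check_activity <- function(f) {
  if (!is.numeric(f) || length(f) < 1L || anyNA(f) || any(f <= 0)) {
    stop("activity levels must be positive")
  }
  invisible(f)
}

#' Right-hand side of the Hebbian rule
#'
#' @param C non-negative matrix of connection strengths (targets x sources).
#' @param f positive activity vector aligned with both dimensions.
#' @param params a [hebbian_params()].
#' @return matrix dC/dt of the same shape.
#' @export
hebbian_rhs <- function(C, f, params) {
  stopifnot(inherits(params, "hebbian_params"))
  check_activity(f)
  C <- as.matrix(C)
  stopifnot(nrow(C) == length(f), ncol(C) == length(f))
  if (any(C < 0)) stop("connection strengths must be non-negative")
  A <- outer(f^params$alpha, f^params$gamma)
  params$eps1 * A * C^params$beta - params$eps2 * C
}

#' Closed-form equilibrium of the Hebbian rule
#'
#' The non-trivial fixed point
#' `C* = (eps1/eps2)^(1/(1-beta)) * outer(f^(alpha/(1-beta)), f^(gamma/(1-beta)))`.
#' Only `beta < 1` is supported: there the positive branch is the attractor;
#' for `beta >= 1` it is not, and the function refuses rather than return a
#' repelling state.
#'
#' @inheritParams hebbian_rhs
#' @return the equilibrium matrix.
#' @export
hebbian_fixed_point <- function(f, params) {
  stopifnot(inherits(params, "hebbian_params"))
  check_activity(f)
  if (params$beta >= 1) {
    stop("unsupported regime: the closed-form equilibrium requires beta < 1")
  }
  om <- 1 - params$beta
  (params$eps1 / params$eps2)^(1 / om) *
    outer(f^(params$alpha / om), f^(params$gamma / om))
}

#' Integrate the Hebbian rule to equilibrium
#'
#' Forward-integrates the rule (adaptive lsoda) until the scaled residual
#' `max |dC/dt| / max C` drops below `tol`, and errors with the residual if
#' that does not happen by `max_time`. Entries of `C0` that are exactly
#' zero are held at zero (zero is a solution of the rule for `beta > 0`).
#'
#' @param C0 non-negative initial matrix; positive entries converge to the
#'   closed-form equilibrium.
#' @inheritParams hebbian_rhs
#' @param tol convergence tolerance on the scaled residual.
#' @param max_time maximum integration time.
#' @return the equilibrated matrix.
#' @export
integrate_to_equilibrium <- function(C0, f, params, tol = 1e-9,
                                     max_time = 1e4) {
  stopifnot(inherits(params, "hebbian_params"))
  check_activity(f)
  if (params$beta >= 1) {
    stop("unsupported regime: integration requires beta < 1")
  }
  C0 <- as.matrix(C0)
  stopifnot(nrow(C0) == length(f), ncol(C0) == length(f))
  if (any(C0 < 0)) stop("initial strengths must be non-negative")
  stopifnot(tol > 0, max_time > 0)
  zero <- C0 == 0
  A <- outer(f^params$alpha, f^params$gamma)
  deriv <- function(t, y, parms) {
    C <- matrix(pmax(y, 0), nrow(C0))
    d <- params$eps1 * A * C^params$beta - params$eps2 * C
    d[zero] <- 0
    list(as.vector(d))
  }
  resid <- function(C) {
    d <- params$eps1 * A * C^params$beta - params$eps2 * C
    d[zero] <- 0
    max(abs(d)) / max(C, .Machine$double.eps)
  }
  C <- C0
  t_now <- 0
  chunk <- 1 / params$eps2           # natural decay timescale
  while (resid(C) >= tol) {
    if (t_now >= max_time) {
      stop(sprintf(
        "no convergence by t = %g: scaled residual %.3g (tol %.3g)",
        max_time, resid(C), tol))
    }
    t_end <- min(t_now + 50 * chunk, max_time)
    sol <- deSolve::ode(y = as.vector(C), times = c(t_now, t_end),
                        func = deriv, parms = NULL, method = "lsoda",
                        rtol = tol / 100, atol = tol / 100)
    C <- matrix(pmax(sol[nrow(sol), -1L], 0), nrow(C0))
    C[zero] <- 0
    t_now <- t_end
  }
  dimnames(C) <- dimnames(C0)
  C
}

#' Macroconnectome exponents implied by the Hebbian rule
#'
#' At equilibrium the connectome is an outer-product power law in the
#' activities (hence, with f proportional to volume, in the volumes), with
#' incoming exponent `eta = gamma / (1 - beta)` and outgoing exponent
#' `kappa = alpha / (1 - beta)`.
#'
#' @param params a [hebbian_params()], or `alpha` given the three exponents
#'   directly.
#' @param alpha,beta,gamma exponents, used when `params` is missing.
#' @return named numeric vector `c(eta = , kappa = )`.
#' @examples
#' predicted_exponents(alpha = 1, beta = 0.4, gamma = 1.6)  # eta ~ 2.67
#' @export
predicted_exponents <- function(params = NULL, alpha = NULL, beta = NULL,
                                gamma = NULL) {
  if (is.null(params)) {
    params <- hebbian_params(alpha, beta, gamma)
  }
  stopifnot(inherits(params, "hebbian_params"))
  if (params$beta == 1) {
    stop("beta = 1: exponents gamma/(1-beta), alpha/(1-beta) are undefined")
  }
  c(eta = params$gamma / (1 - params$beta),
    kappa = params$alpha / (1 - params$beta))
}
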