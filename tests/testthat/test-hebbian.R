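test_that("plasticity rule right-hand side matches its definition", {
  p <- hebbian_params(alpha = 0, beta = 0.5, gamma = 0)
  # zero connectivity is a solution for beta > 0
  expect_equal(hebbian_rhs(matrix(0, 3, 3), rep(1, 3), p),
               matrix(0, 3, 3))
  # scalar arithmetic: sqrt(4) - 4 = -2
  expect_equal(hebbian_rhs(matrix(4), 1, p), matrix(-2))
  # general entrywise form on random inputs
  set.seed(1)
  f <- runif(4, 0.5, 2)
  C <- matrix(runif(16, 0, 3), 4)
  p2 <- hebbian_params(alpha = 0.7, beta = 0.3, gamma = 1.2,
                       eps1 = 1.5, eps2 = 0.8)
  expect_equal(hebbian_rhs(C, f, p2),
               1.5 * outer(f^0.7, f^1.2) * C^0.3 - 0.8 * C)
  expect_error(hebbian_rhs(matrix(-1), 1, p), "non-negative")
})

test_that("closed-form equilibrium annihilates the rule", {
  set.seed(2)
  for (i in 1:100) {
    p <- hebbian_params(alpha = runif(1, -1, 1.5), beta = runif(1, 0, 0.9),
                        gamma = runif(1, -1, 1.5),
                        eps1 = runif(1, 0.8, 1.25),
                        eps2 = runif(1, 0.8, 1.25))
    f <- runif(5, 0.8, 1.25)
    Cs <- hebbian_fixed_point(f, p)
    expect_lt(max(abs(hebbian_rhs(Cs, f, p))), 1e-10)
  }
  p_bad <- hebbian_params(alpha = 1, beta = 1.2, gamma = 1)
  expect_error(hebbian_fixed_point(c(1, 2), p_bad), "beta < 1")
})

test_that("integration reaches the closed-form equilibrium", {
  p <- hebbian_params(alpha = 0, beta = 0.5, gamma = 0)
  # scalar case: C0 = 4 decays to C* = 1
  expect_equal(integrate_to_equilibrium(matrix(4), 1, p)[1, 1], 1,
               tolerance = 1e-6)
  # starting at the fixed point returns it unchanged
  f <- make_lognormal_volumes(6, sigma = 0.8, seed = 3)
  p2 <- hebbian_params(alpha = 1, beta = 0.4, gamma = 1.6)
  Cs <- hebbian_fixed_point(f, p2)
  expect_equal(integrate_to_equilibrium(Cs, f, p2), Cs, tolerance = 1e-8)
  # random positive start on a 10-area system converges to the closed form
  f10 <- make_lognormal_volumes(10, sigma = 0.8, seed = 4)
  Cs10 <- hebbian_fixed_point(f10, p2)
  set.seed(5)
  C0 <- matrix(rlnorm(100, 0, 1), 10)
  Ceq <- integrate_to_equilibrium(C0, f10, p2)
  expect_lt(max(abs(Ceq - Cs10) / Cs10), 1e-6)
  expect_error(integrate_to_equilibrium(matrix(1), 1,
                                        hebbian_params(1, 1.5, 1)),
               "beta < 1")
})

test_that("zero connections stay zero through integration", {
  p <- hebbian_params(alpha = 0.5, beta = 0.5, gamma = 0.5)
  f <- c(0.8, 1.1, 1.4)
  C0 <- matrix(1, 3, 3)
  C0[1, 2] <- 0
  C0[3, 1] <- 0
  Ceq <- integrate_to_equilibrium(C0, f, p)
  expect_identical(Ceq[1, 2], 0)
  expect_identical(Ceq[3, 1], 0)
  Cs <- hebbian_fixed_point(f, p)
  expect_equal(Ceq[C0 > 0], Cs[C0 > 0], tolerance = 1e-6)
})

test_that("equilibrium connectivity carries the predicted exponents", {
  expect_equal(predicted_exponents(alpha = 1, beta = 0, gamma = 1),
               c(eta = 1, kappa = 1))
  ex <- predicted_exponents(alpha = 1, beta = 0.4, gamma = 1.6)
  expect_equal(ex[["eta"]], 1.6 / 0.6)
  expect_equal(predicted_exponents(alpha = 0.65, beta = 0.5,
                                   gamma = 1)[["kappa"]], 1.30)
  expect_error(predicted_exponents(alpha = 1, beta = 1, gamma = 1),
               "beta = 1")
  # eta increases with gamma and with beta
  etas_g <- vapply(c(0.5, 1, 1.5),
                   function(g) predicted_exponents(alpha = 1, beta = 0.4,
                                                   gamma = g)[["eta"]],
                   numeric(1))
  etas_b <- vapply(c(0.1, 0.4, 0.7),
                   function(b) predicted_exponents(alpha = 1, beta = b,
                                                   gamma = 1)[["eta"]],
                   numeric(1))
  expect_true(all(diff(etas_g) > 0) && all(diff(etas_b) > 0))

  # end to end: integrate, then fit a target row against activity
  f <- make_lognormal_volumes(10, sigma = 0.7, seed = 6)
  p <- hebbian_params(alpha = 1, beta = 0.4, gamma = 1.6)
  Ceq <- integrate_to_equilibrium(matrix(1, 10, 10), f, p, tol = 1e-10)
  row_fit <- fit_power_law(Ceq[1, ], f)
  expect_lt(abs(row_fit$exponent - 1.6 / 0.6), 1e-3)
  expect_equal(row_fit$r_squared, 1, tolerance = 1e-9)
  # and a source column against activity recovers kappa = alpha/(1-beta)
  col_fit <- fit_power_law(Ceq[, 1], f)
  expect_lt(abs(col_fit$exponent - 1 / 0.6), 1e-3)
})
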