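test_that("outer-product connectome matches the tabula rasa counting", {
  C <- outer_product_connectome(c(1, 1), f = 1, rho = 1)
  expect_equal(unclass(C)[1, 2], 0.5)
  expect_equal(diag(unclass(C)), c(0, 0), ignore_attr = TRUE)
  expect_false(is_fln(C))
  # with self blocks included, total count is f * N^2 / 2 for N = rho*sum(v)
  v <- c(2, 3, 5)
  f <- 0.3
  rho <- 7
  Cd <- outer_product_connectome(v, f = f, rho = rho,
                                 include_diagonal = TRUE)
  N <- rho * sum(v)
  expect_equal(sum(Cd), f * N^2 / 2)
  # bilinearity: doubling volumes quadruples every entry
  C2 <- outer_product_connectome(2 * v, f = f, rho = rho)
  expect_equal(unclass(C2), 4 * unclass(outer_product_connectome(v, f = f,
                                                                 rho = rho)))
  expect_error(outer_product_connectome(c(1, -1)), "positive")
  expect_error(outer_product_connectome(c(1, 2), f = 1.5), "\\[0, 1\\]")
})

test_that("FLN normalization makes non-zero rows sum to one", {
  C <- connectome(matrix(c(2, 2, 0, 0), 2, byrow = TRUE))
  expect_warning(F <- normalize_fln(C), "all-zero row")
  expect_equal(unclass(F)[1, ], c(0.5, 0.5), ignore_attr = TRUE)
  expect_equal(unclass(F)[2, ], c(0, 0), ignore_attr = TRUE)
  expect_true(is_fln(F))
  expect_error(normalize_fln(F), "already")

  set.seed(5)
  v <- rlnorm(30, 0, 1.2)
  Ffull <- normalize_fln(outer_product_connectome(v, include_diagonal = TRUE))
  expect_lt(max(abs(rowSums(Ffull) - 1)), 1e-9)
  # every FLN row is v_j / sum(v): source volume alone sets the column
  spread <- apply(unclass(Ffull), 2, function(col) diff(range(col)))
  expect_lt(max(spread / colMeans(unclass(Ffull))), 1e-9)
})

test_that("log-log fits recover exact power laws and refuse degenerate input", {
  v <- exp(seq(0, 3, length.out = 25))
  fit <- fit_power_law(v^2.33, v)
  expect_equal(fit$exponent, 2.33)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$n_points, 25L)
  expect_equal(fit$r_squared, fit$r^2, tolerance = 1e-12)
  expect_error(fit_power_law(c(1, 2, 0), c(1, 2, 3)), "at least 3")
  expect_error(fit_power_law(rep(1, 5), rep(2, 5)), "degenerate")
  # invariances: strength rescaling shifts the intercept only; volume
  # rescaling leaves the slope unchanged
  set.seed(6)
  s <- v^1.7 * rlnorm(25, 0, 0.3)
  f0 <- fit_power_law(s, v)
  f1 <- fit_power_law(10 * s, v)
  expect_equal(f1$exponent, f0$exponent)
  expect_equal(f1$intercept, f0$intercept + log(10))
  f2 <- fit_power_law(s, 5 * v)
  expect_equal(f2$exponent, f0$exponent)
})

test_that("pure outer-product FLN yields incoming exponent eta = 1", {
  set.seed(7)
  v <- make_lognormal_volumes(60, sigma = 1.24, seed = 7)
  F <- normalize_fln(outer_product_connectome(v, include_diagonal = TRUE))
  one <- fit_incoming(F, v, targets = 1)
  expect_lt(abs(one$exponent - 1), 1e-9)
  pooled <- fit_incoming(F, v, pooled = TRUE)
  expect_lt(abs(pooled$exponent - 1), 1e-9)
})

test_that("planted incoming exponents are recovered under realistic noise", {
  v <- make_lognormal_volumes(90, sigma = 1.24, seed = 11)
  ns <- noise_for_r_squared(v, 2.67, 0.62)
  set.seed(12)
  rec <- replicate(100, {
    F <- make_power_law_fln(v, exponent = 2.67, noise_sigma = ns)
    fit_incoming(F, v, targets = 1)
  }, simplify = FALSE)
  exps <- vapply(rec, `[[`, numeric(1), "exponent")
  r2 <- vapply(rec, `[[`, numeric(1), "r_squared")
  expect_lt(abs(mean(exps) - 2.67), 0.25)
  expect_gt(mean(r2), 0.45)
  expect_lt(mean(r2), 0.8)
})

test_that("pooled fits over targets with different planted slopes interpolate", {
  v <- make_lognormal_volumes(91, sigma = 1.24, seed = 13)
  planted <- c(2.67, 2.85, 1.79)
  set.seed(14)
  rows <- lapply(planted, function(e) {
    v^e * rlnorm(length(v), 0, noise_for_r_squared(v, e, 0.6))
  })
  M <- do.call(rbind, rows)
  F <- normalize_fln(connectome(M))
  pooled <- fit_incoming(F, v, pooled = TRUE)
  expect_gt(pooled$exponent, min(planted) - 0.3)
  expect_lt(pooled$exponent, max(planted) + 0.3)
  # pooling identical rows reproduces the single-row exponent
  Fsame <- normalize_fln(connectome(rbind(rows[[1]], rows[[1]])))
  expect_equal(fit_incoming(Fsame, v, pooled = TRUE)$exponent,
               fit_incoming(Fsame, v, targets = 1)$exponent)
})

test_that("outgoing exponents are recovered per source column", {
  v_t <- make_lognormal_volumes(295, sigma = 1.24, seed = 15)
  ns <- noise_for_r_squared(v_t, 1.30, 0.6)
  set.seed(16)
  exps <- replicate(100, {
    col <- v_t^1.30 * rlnorm(295, 0, ns)
    M <- connectome(cbind(col, col * 0.5))
    fit_outgoing(M, v_t, sources = 1)$exponent
  })
  expect_lt(abs(mean(exps) - 1.30), 0.15)
  # exact column, and zero entries never enter the regression
  col <- v_t^1.30
  col[1:50] <- 0
  f <- fit_outgoing(connectome(cbind(col)), v_t, sources = 1)
  expect_equal(f$exponent, 1.30)
  expect_equal(f$n_points, 245L)
  expect_error(fit_outgoing(connectome(cbind(rep(2, 5))), rep(1, 5)),
               "degenerate")
})
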