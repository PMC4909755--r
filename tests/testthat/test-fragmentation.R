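test_that("split probabilities normalize and follow volume^mu", {
  expect_equal(split_probabilities(c(1, 1), mu = 5), c(0.5, 0.5))
  expect_equal(split_probabilities(c(2, 1), mu = 0), c(0.5, 0.5))
  expect_equal(split_probabilities(c(2, 1), mu = 1), c(2 / 3, 1 / 3))
  # general proportionality on random volumes
  set.seed(42)
  for (mu in c(-1.3, 0.7, 2)) {
    v <- exp(rnorm(20))
    p <- split_probabilities(v, mu)
    expect_equal(sum(p), 1)
    expect_true(all(p >= 0))
    expect_equal(p, v^mu / sum(v^mu))
  }
  # log-space computation survives extreme mu * log(v)
  p <- split_probabilities(c(1e-12, 1e12), mu = 40)
  expect_true(all(is.finite(p)))
  expect_equal(sum(p), 1)
  expect_error(split_probabilities(c(1, -1), 0), "positive")
  expect_error(split_probabilities(numeric(0), 0), "non-empty")
})

test_that("splitting a leaf conserves volume and applies 10% noise", {
  tr <- run_fragmentation(mu = 0, n_target = 1)
  out <- split_leaf(tr, leaf_id = 0L, noise_sd = 0)
  expect_equal(n_leaves(out), 2L)
  expect_equal(leaf_volumes(out), c(0.5, 0.5))

  set.seed(7)
  ratios <- replicate(1e4, {
    tr2 <- split_leaf(tr, 0L, noise_sd = 0.1)
    v <- leaf_volumes(tr2)
    expect_equal(sum(v), 1, tolerance = 1e-14)  # children sum to parent
    v[1L]
  })
  # child1/parent = r/2 with r ~ Normal(1, 0.1): sd of the ratio ~ 0.05
  expect_equal(sd(ratios), 0.05, tolerance = 0.05)
  expect_equal(mean(ratios), 0.5, tolerance = 0.01)

  expect_error(split_leaf(out, leaf_id = 0L), "not a current leaf")
})

test_that("fragmentation runs hit the target leaf count and conserve volume", {
  tr <- run_fragmentation(mu = 0, n_target = 1, root_volume = 3.5)
  expect_equal(n_leaves(tr), 1L)
  expect_equal(leaf_volumes(tr), 3.5)

  set.seed(99)
  cases <- data.frame(mu = c(-0.5, 0, 0.4, 1.2),
                      n = c(17L, 64L, 200L, 33L),
                      noise = c(0, 0.1, 0.1, 0.3),
                      root = c(1, 1, 2.7, 1e-4))
  for (i in seq_len(nrow(cases))) {
    tr <- run_fragmentation(cases$mu[i], cases$n[i], cases$noise[i],
                            cases$root[i])
    expect_equal(n_leaves(tr), cases$n[i])
    expect_lt(abs(sum(leaf_volumes(tr)) - cases$root[i]) / cases$root[i],
              1e-9)
    expect_silent(brainparc:::validate_parc_tree(tr))
    # binary history: leaves = internal nodes + 1
    expect_equal(length(tr$id), 2L * cases$n[i] - 1L)
  }
})

test_that("identical seeds reproduce identical trees and ensembles", {
  a <- run_fragmentation(0.3, 150, seed = 123)
  b <- run_fragmentation(0.3, 150, seed = 123)
  expect_identical(a, b)
  sa <- simulate_sigma_ensemble(80, 0.2, n_sims = 50, seed = 5)
  sb <- simulate_sigma_ensemble(80, 0.2, n_sims = 50, seed = 5)
  expect_identical(sa, sb)
})

test_that("uniform noiseless model is the Yule process", {
  set.seed(314)
  # volumes are exact powers of 1/2
  tr <- run_fragmentation(mu = 0, n_target = 40, noise_sd = 0)
  d <- leaf_depths(tr)
  expect_equal(leaf_volumes(tr), 2^-d)
  # depth distribution matches an independent pick-a-uniform-leaf oracle
  n <- 30L
  sim_depths <- unlist(replicate(500, {
    leaf_depths(run_fragmentation(0, n, noise_sd = 0))
  }, simplify = FALSE))
  ora_depths <- unlist(replicate(500, yule_depths_oracle(n),
                                 simplify = FALSE))
  ks <- suppressWarnings(ks.test(sim_depths, ora_depths))
  expect_gt(ks$p.value, 0.01)
})

test_that("compiled sigma kernel agrees with the R tree simulator", {
  set.seed(2024)
  s_tree <- replicate(200, sd(log(leaf_volumes(
    run_fragmentation(mu = 0.3, n_target = 100)))))
  s_kernel <- simulate_sigma_ensemble(100, mu = 0.3, n_sims = 200)
  ks <- suppressWarnings(ks.test(s_tree, s_kernel))
  expect_gt(ks$p.value, 0.01)
})

test_that("log-volume variance grows diffusively (like ln t) at mu = 0", {
  n_grid <- c(50L, 100L, 200L, 400L, 800L)
  set.seed(8)
  mean_var <- vapply(n_grid, function(n) {
    mean(simulate_sigma_ensemble(n, mu = 0, n_sims = 100)^2)
  }, numeric(1))
  expect_true(all(diff(mean_var) > 0))
  fit <- summary(lm(mean_var ~ log(n_grid)))
  expect_gt(fit$r.squared, 0.95)
})

test_that("stronger bias toward splitting large regions homogenizes sizes", {
  set.seed(9)
  mean_sigma <- vapply(c(-0.5, 0, 0.5, 1), function(mu) {
    mean(simulate_sigma_ensemble(200, mu = mu, n_sims = 300))
  }, numeric(1))
  expect_true(all(diff(mean_sigma) < 0))
})
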