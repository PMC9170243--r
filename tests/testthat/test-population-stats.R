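test_that("noise correlations hit their independence and identity anchors", {
  set.seed(2)
  rs <- vapply(1:100, function(r) {
    x <- matrix(rpois(40 * 8, 5), 40, 8)
    noise_correlations(trial_matrix(x, theta = rep(0.5, 40)))$mean_rsc
  }, numeric(1))
  expect_lt(abs(mean(rs)), 3 * sd(rs) / sqrt(length(rs)))

  x <- matrix(rpois(60, 8), 30, 2)
  dup <- trial_matrix(cbind(x, x[, 1]), theta = rep(0.1, 30))
  nc <- noise_correlations(dup)
  pair13 <- nc$r_noise[nc$pairs[, 1] == 1 & nc$pairs[, 2] == 3]
  expect_equal(pair13, 1.0)
})

test_that("zero-variance units are excluded and reported", {
  x <- cbind(matrix(rpois(60, 6), 30, 2), 3)
  nc <- noise_correlations(trial_matrix(x, theta = rep(0, 30)))
  expect_identical(nc$excluded_units, 3L)
  expect_false(any(nc$pairs == 3))
  expect_error(noise_correlations(
    trial_matrix(matrix(1:4, 2, 2), theta = c(0, 0))), "3 trials")
})

test_that("mean r_SC of the rank-1 gain model matches its closed form", {
  p <- ring_params(n_units = 20, radial_sd = 0.2, private_sd = 1.2)
  tm <- gen_ring_responses(p, 0.4, 2500, seed = 6)
  emp <- noise_correlations(tm)$mean_rsc
  theo <- ring_expected_rsc(p, 0.4)
  expect_lt(abs(emp - theo) / theo, 0.15)
})

test_that("noise and signal correlations are positively related under
          shared gain, and attention weakens the relationship", {
  # moderate-correlation regime (mean r_SC ~ 0.15-0.2, as in cortex)
  th <- theta_grid(8)
  both <- vapply(1:6, function(r) {
    p0 <- ring_params(n_units = 20, radial_sd = 0.12, private_sd = 2,
                      attention = 0)
    p1 <- ring_params(n_units = 20, radial_sd = 0.12, private_sd = 2,
                      attention = 1)
    c(signal_vs_noise(gen_ring_responses(p0, th, 60,
                                         seed = r))$noise_vs_signal_r,
      signal_vs_noise(gen_ring_responses(p1, th, 60,
                                         seed = r))$noise_vs_signal_r)
  }, numeric(2))
  expect_true(all(both[1, ] > 0))
  expect_gt(mean(both[1, ] - both[2, ]), 0)
  expect_gt(mean(both[1, ] > both[2, ]), 0.5)
  # private noise only: no relationship
  pp <- tiny_ring(n_units = 20, radial_sd = 0)
  sp <- signal_vs_noise(gen_ring_responses(pp, th, 120, seed = 8))
  expect_lt(abs(sp$noise_vs_signal_r), 0.12)
})

test_that("signal_vs_noise guards its preconditions", {
  p <- tiny_ring(n_units = 6)
  few <- gen_ring_responses(p, c(0.1, 0.4, 0.8), 10, seed = 9)
  expect_error(signal_vs_noise(few), "5 orientations")
})

test_that("factor analysis recovers a planted one-factor model", {
  set.seed(14)
  n <- 2000; p <- 20
  L <- matrix(seq(0.5, 2, length.out = p), p, 1)
  x <- matrix(rnorm(n * p), n, p) + matrix(rnorm(n), n, 1) %*% t(L)
  ff <- factor_fit(x, n_factors = 5, seed = 2)
  expect_true(ff$converged)
  expect_lt(abs(ff$shared_eigenvalues[1] - sum(L^2)) / sum(L^2), 0.1)
  expect_identical(length(ff$shared_eigenvalues), 5L)
  # ordering and nonnegativity
  expect_true(all(diff(ff$shared_eigenvalues) <= 1e-9))
  expect_true(all(ff$shared_eigenvalues >= 0))
  expect_true(all(ff$private_variances > 0))
})

test_that("independent noise yields a near-zero leading shared eigenvalue", {
  set.seed(15)
  x <- matrix(rnorm(20000 * 6), 20000, 6)
  ff <- factor_fit(x, n_factors = 3, seed = 3)
  expect_lt(ff$shared_eigenvalues[1], 0.05 * mean(ff$private_variances))
})

test_that("EM log-likelihood is nondecreasing across iterations", {
  set.seed(16)
  x <- matrix(rnorm(400 * 10), 400, 10) +
    matrix(rnorm(400), 400, 1) %*% t(runif(10, 0.5, 1.5))
  ff <- factor_fit(x, n_factors = 3, seed = 4)
  expect_true(all(diff(ff$loglik_trace) > -1e-6 * abs(ff$loglik)))
})

test_that("factor_fit validates dimensions and warns on few trials", {
  x <- matrix(rnorm(200), 10, 20)
  expect_error(factor_fit(x, n_factors = 20), "smaller than")
  expect_warning(factor_fit(x, n_factors = 2, max_iter = 50,
                            n_restarts = 0), "unstable")
})
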