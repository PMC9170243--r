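test_that("noiseless ring responses equal the tuning curve exactly", {
  p <- ring_params(n_units = 10, radial_sd = 0, private_sd = 0,
                   heterogeneity = 0)
  tm <- gen_ring_responses(p, thetas = c(0.1, 0.6), trials_per_theta = 3,
                           seed = 1)
  f <- ring_tuning(p, c(0.1, 0.6))
  expect_equal(tm$counts[1:3, ], matrix(f[1, ], 3, 10, byrow = TRUE),
               ignore_attr = TRUE)
  expect_equal(tm$counts[4:6, ], matrix(f[2, ], 3, 10, byrow = TRUE),
               ignore_attr = TRUE)
})

test_that("generators are bit-reproducible given seed and reject bad input", {
  p <- tiny_ring()
  a <- gen_ring_responses(p, 0.5, 20, seed = 7)
  b <- gen_ring_responses(p, 0.5, 20, seed = 7)
  expect_identical(a$counts, b$counts)
  expect_error(ring_params(n_units = 1), ">= 2")
  expect_error(ring_params(radial_sd = -1), "nonnegative")
  expect_error(ring_params(attention = 2), "\\[0, 1\\]")
  expect_error(ring_params(amplitude = NaN), "non-finite|amplitude")
  expect_error(ring_params(n_units = 4, preferred = c(0, .1, .2, .3)),
               "cover the ring")
  expect_error(gen_ring_responses(p, 0.5, 1, seed = 1), ">= 2")
})

test_that("shared gain induces positive correlations that grow with its SD
          and match the analytic rank-1 prediction", {
  rsc <- vapply(c(0.05, 0.15, 0.3), function(sg) {
    p <- ring_params(n_units = 25, radial_sd = sg, private_sd = 1.5)
    tm <- gen_ring_responses(p, 0.5, 1500, seed = 11)
    noise_correlations(tm)$mean_rsc
  }, numeric(1))
  expect_true(all(rsc > 0))
  expect_true(all(diff(rsc) > 0))
  p <- ring_params(n_units = 25, radial_sd = 0.2, private_sd = 1.5)
  emp <- noise_correlations(gen_ring_responses(p, 0.5, 3000,
                                               seed = 13))$mean_rsc
  expect_lt(abs(emp - ring_expected_rsc(p, 0.5)) / ring_expected_rsc(p, 0.5),
            0.15)
})

test_that("attention scales down the shared fluctuation and mean r_SC", {
  p0 <- tiny_ring(attention = 0)
  p1 <- tiny_ring(attention = 1)
  r0 <- noise_correlations(gen_ring_responses(p0, 0.5, 800,
                                              seed = 3))$mean_rsc
  r1 <- noise_correlations(gen_ring_responses(p1, 0.5, 800,
                                              seed = 3))$mean_rsc
  expect_lt(r1, r0)
})

test_that("empirical correlation matrix approaches the rank-1 prediction", {
  p <- ring_params(n_units = 12, radial_sd = 0.25, private_sd = 1,
                   heterogeneity = 0)
  tm <- gen_ring_responses(p, 0.3, 6000, seed = 5)
  emp <- cov(tm$counts)
  theo <- ring_covariance(p, 0.3)
  expect_lt(norm(emp - theo, "F") / norm(theo, "F"), 0.1)
})

test_that("gaussian population generator matches its stated moments", {
  S <- matrix(c(2, 0.6, 0.6, 1), 2)
  tm <- gen_gaussian_population(c(5, 3), c(4, 2), S, 4000, seed = 9)
  hi <- tm$counts[tm$theta == max(tm$theta), ]
  expect_equal(colMeans(hi), c(5, 3), tolerance = 0.05, ignore_attr = TRUE)
  expect_equal(cov(hi), S, tolerance = 0.1, ignore_attr = TRUE)
  bad <- matrix(c(1, 2, 2, 1), 2)
  expect_error(gen_gaussian_population(c(0, 0), c(0, 0), bad, 10, 1),
               "positive definite")
  expect_error(
    gen_gaussian_population(c(0, 0), c(0, 0), matrix(c(1, .5, .2, 1), 2),
                            10, 1), "symmetric")
})

test_that("zero mean separation gives a Fisher estimate centered on zero", {
  S <- diag(2)
  vals <- vapply(1:60, function(r) {
    tm <- gen_gaussian_population(c(1, 1), c(1, 1), S, 100, seed = r)
    fisher_info_bc(tm, dtheta = 0.1)$value
  }, numeric(1))
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals)), 3 * se + 1e-9)
})

test_that("trial shuffling preserves marginals and removes correlations", {
  p <- tiny_ring(n_units = 15, radial_sd = 0.3)
  tm <- gen_ring_responses(p, c(0.2, 0.7), 400, seed = 21)
  sh <- shuffle_trials(tm, seed = 22)
  for (t0 in c(0.2, 0.7)) {
    i <- tm$theta == t0
    expect_identical(apply(sh$counts[i, ], 2, sort),
                     apply(tm$counts[i, ], 2, sort))
  }
  rs <- vapply(1:40, function(r) {
    sh_r <- shuffle_trials(tm, seed = 100 + r)
    noise_correlations(subset_trials(sh_r, sh_r$theta == 0.2))$mean_rsc
  }, numeric(1))
  expect_lt(abs(mean(rs)), 3 * sd(rs) / sqrt(length(rs)) + 1e-3)
})
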