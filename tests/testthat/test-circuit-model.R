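test_that("attention parameterization interpolates the printed endpoints", {
  expect_equal(attention_params(0), list(gamma = 20, mu_i = 0))
  expect_equal(attention_params(1), list(gamma = 23, mu_i = 0.5))
  expect_equal(attention_params(0.5), list(gamma = 21.5, mu_i = 0.25))
  lv <- seq(0, 1, 0.1)
  g <- vapply(lv, function(l) attention_params(l)$gamma, numeric(1))
  m <- vapply(lv, function(l) attention_params(l)$mu_i, numeric(1))
  expect_true(all(diff(g) >= 0) && all(diff(m) >= 0))
  expect_error(attention_params(1.2), "\\[0, 1\\]")
})

test_that("orientation map covers [0,1), is seed-deterministic, and its
          dominant spatial frequency is the inverse column spacing", {
  m1 <- make_orientation_map(0.2, grid_side = 32, seed = 9)
  m2 <- make_orientation_map(0.2, grid_side = 32, seed = 9)
  expect_identical(m1$orientation, m2$orientation)
  expect_true(all(m1$orientation >= 0 & m1$orientation < 1))
  pk <- map_dominant_frequency(m1)
  expect_lte(abs(pk$peak - 1 / 0.2), pk$bin_width)
  m3 <- make_orientation_map(0.1, grid_side = 40, seed = 2)
  expect_lte(abs(map_dominant_frequency(m3)$peak - 10), 1)
  expect_error(make_orientation_map(1.5), "smaller than the domain")
})

test_that("OU noise has the analytic stationary variance and exponential
          autocorrelation", {
  tau <- 40; sn <- 3.5
  expect_equal(ou_stationary_sd(tau, sn), sn / sqrt(2 * tau))
  set.seed(3)
  dt <- 2
  n_steps <- 5000  # 10 s trace
  eta <- numeric(n_steps)
  eta[1] <- ou_init(1, tau, sn)
  for (t in 2:n_steps) eta[t] <- ou_step(eta[t - 1], dt, tau, sn)
  expect_lt(abs(sd(eta) - ou_stationary_sd(tau, sn)) /
              ou_stationary_sd(tau, sn), 0.1)
  ac <- acf(eta, lag.max = 40, plot = FALSE)$acf[, 1, 1]
  lags_ms <- (0:40) * dt
  expect_lt(max(abs(ac[1:20] - exp(-lags_ms[1:20] / tau))), 0.1)
})

test_that("zero OU amplitude leaves the image exactly static", {
  img <- gabor_patch(0.3)
  eta <- ou_init(625, sigma_n = 0)
  expect_true(all(eta == 0))
  expect_identical(ou_step(eta, 1, sigma_n = 0), eta)
})

test_that("layer-4 front end calibrates to 10 Hz ON and 5 Hz OFF", {
  map <- make_orientation_map(0.2, grid_side = 16, seed = 5)
  fb <- calibrate_filterbank(make_filterbank(map), seed = 7)
  sim <- simulate_l4(fb, stim_protocol(total_ms = 6000),
                     orientation_sequence = theta_grid(12), seed = 3)
  expect_lt(abs(sim$on_rate_hz - 10), 1)
  expect_lt(abs(sim$off_rate_hz - 5), 0.5)
  expect_true(all(sim$on_counts$counts >= 0))
})

test_that("zero-contrast stimulation leaves only rectified noise, and no
          noise at all silences the ON response", {
  map <- make_orientation_map(0.2, grid_side = 12, seed = 5)
  fb <- calibrate_filterbank(make_filterbank(map), seed = 7)
  prot <- stim_protocol(total_ms = 3000)
  silent <- simulate_l4(fb, prot, 0.5, seed = 3, contrast = 0, sigma_n = 0)
  expect_equal(silent$on_rate_hz, 0)
  noisy <- simulate_l4(fb, prot, 0.5, seed = 3, contrast = 0)
  expect_gt(noisy$on_rate_hz, 0)
  expect_lt(noisy$on_rate_hz, 10)
})

test_that("rate series rejects a too-coarse noise step", {
  map <- make_orientation_map(0.2, grid_side = 12, seed = 5)
  fb <- make_filterbank(map)
  expect_error(
    l4_rate_series(fb, stim_protocol(rate_dt_ms = 10), 0.5, tau_n = 40),
    "tau_n / 10")
})

test_that("network simulation is reproducible and respects the protocol", {
  cfg <- network_config(l4_grid = 10, v1e_grid = 10, v1i_grid = 5,
                        v4e_grid = 10, v4i_grid = 5, k_ffwd = 20,
                        k_from_e = 15, k_from_i = 5, dt = 0.1,
                        protocol = stim_protocol(total_ms = 2000))
  map <- make_orientation_map(0.2, grid_side = 10, seed = 5)
  fb <- calibrate_filterbank(make_filterbank(map), seed = 7)
  conn <- build_connectivity(cfg, seed = 2)
  s1 <- suppressWarnings(
    build_and_simulate(cfg, fb, conn, 0.5, 0.3, seed = 4))
  s2 <- suppressWarnings(
    build_and_simulate(cfg, fb, conn, 0.5, 0.3, seed = 4))
  expect_identical(s1$v4e$counts, s2$v4e$counts)
  # 2000 ms / 500 ms cycles = 4 ON intervals, first dropped
  expect_identical(n_trials(s1$v4e), 3L)
  expect_identical(s1$gamma, 21.5)
  expect_identical(s1$mu_i, 0.25)
  # membrane potentials bounded by the floor and threshold
  expect_gte(s1$v_range[1], cfg$v_floor)
  expect_lte(s1$v_range[2], cfg$Vth)
})

test_that("paper parameter file records the printed constants", {
  path <- tempfile(fileext = ".json")
  write_paper_config(path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(x$stimulus$column_spacing, 0.2)
  expect_equal(x$stimulus$sigma, 0.2)
  expect_equal(x$stimulus$lambda, 0.6)
  expect_equal(x$stimulus$tau_n, 40)
  expect_equal(x$stimulus$sigma_n, 3.5)
  expect_equal(x$alpha_ffwd_v4, 0.05)
  expect_equal(x$attention$gamma_range, c(20, 23))
  expect_equal(x$attention$mu_i_range, c(0, 0.5))
  expect_equal(x$protocol$off_ms, 300)
  expect_equal(x$protocol$on_ms, 200)
  expect_equal(x$protocol$r_x, 5)
  expect_equal(x$dt, 0.01)
  unlink(path)
})
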