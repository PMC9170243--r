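test_that("specific decoder weights satisfy the closed form", {
  # isotropic covariance: weights proportional to f' with w'f' = 1
  fp <- c(2, -1, 0.5)
  dth <- 0.01
  w <- specific_weights(dth * fp, -dth * fp, diag(3), dtheta = dth)
  expect_equal(coef(w), fp / sum(fp^2), tolerance = 1e-12)
  expect_equal(sum(coef(w) * fp), 1, tolerance = 1e-12)
  expect_equal(w$info, sum(fp^2), tolerance = 1e-12)
})

test_that("estimator variance equals the inverse information on random
          positive definite covariances", {
  set.seed(4)
  for (rep in 1:10) {
    n <- 6
    A <- matrix(rnorm(n * n), n)
    S <- crossprod(A) + diag(n) * 0.1
    fp <- rnorm(n)
    w <- specific_weights(0.01 * fp, -0.01 * fp, S)
    expect_equal(w$variance, 1 / w$info, tolerance = 1e-10)
    expect_equal(w$info, drop(crossprod(fp, solve(S, fp))),
                 tolerance = 1e-8)
  }
})

test_that("specific decoder predictions are locally unbiased on means", {
  p <- ring_params(n_units = 20, heterogeneity = 0)
  dth <- 0.01
  f_p <- drop(ring_tuning(p, 0.5 + dth))
  f_m <- drop(ring_tuning(p, 0.5 - dth))
  S <- ring_covariance(p, 0.5)
  w <- specific_weights(f_p, f_m, S, dtheta = dth)
  expect_equal(predict(w, rbind(f_p, f_m)), c(0.5 + dth, 0.5 - dth),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("singular covariance falls back to a flagged pseudo-inverse", {
  S <- matrix(1, 3, 3)  # rank 1
  expect_warning(
    w <- specific_weights(c(0.01, 0.01, 0.01), c(-0.01, -0.01, -0.01), S),
    "pseudo-inverse")
  expect_true(w$pseudo_inverse)
  expect_true(all(is.finite(coef(w))))
})

test_that("bias-corrected Fisher estimator is centered on the analytic
          value and below the naive plug-in", {
  S <- matrix(c(1, 0.5, 0.5, 1), 2)
  fp <- c(1, 1)
  target <- drop(crossprod(fp, solve(S, fp)))  # 4/3
  expect_equal(target, 4 / 3)
  vals <- t(vapply(1:150, function(r) {
    tm <- gaussian_pair(fp, S, ntr = 200, dtheta = 0.1, seed = r)
    c(bc = fisher_info_bc(tm, dtheta = 0.1)$value,
      naive = fisher_info_bc(tm, dtheta = 0.1, corrected = FALSE)$value)
  }, numeric(2)))
  se <- sd(vals[, "bc"]) / sqrt(nrow(vals))
  expect_lt(abs(mean(vals[, "bc"]) - target), 3 * se)
  expect_gt(mean(vals[, "naive"]), mean(vals[, "bc"]))
  expect_gt(mean(vals[, "naive"]), target)
})

test_that("fisher_info_bc enforces its validity bound and balanced trials", {
  tm <- gaussian_pair(rep(1, 30), diag(30), ntr = 16, dtheta = 0.1,
                      seed = 1)
  expect_error(fisher_info_bc(tm), "2\\*Ntr > N \\+ 3")
  tm2 <- gaussian_pair(c(1, 1), diag(2), ntr = 50, dtheta = 0.1, seed = 1)
  tm2$theta[1] <- tm2$theta[2]  # unbalance
  expect_error(fisher_info_bc(subset_trials(tm2, -1)), "equal trial")
})

test_that("general decoder reproduces the hand-computed two-unit cases", {
  th <- theta_grid(50)
  f <- cbind(cos(2 * pi * th), sin(2 * pi * th))
  # noiseless: w = (1, i), exact decode
  tm <- trial_matrix(rbind(f, f), theta = c(th, th))
  g <- general_weights(tm)
  expect_equal(g$weights, c(1 + 0i, 0 + 1i), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(predict(g, tm), c(th, th), tolerance = 1e-10)
  expect_equal(g$expected_mse, 0, tolerance = 1e-10)
  # isotropic noise variance 1/2: w = (1/2, i/2) from exact moments
  g2 <- general_weights(moments = list(
    M = diag(2) / 2 + diag(2) / 2,
    b = c(0.5 + 0i, 0 + 0.5i)))
  expect_equal(g2$weights, c(0.5 + 0i, 0 + 0.5i), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(g2$expected_mse, 0.5, tolerance = 1e-12)
})

test_that("closed-form general weights attain the minimum mean squared
          error among random perturbations", {
  p <- tiny_ring(n_units = 10)
  tm <- gen_ring_responses(p, theta_grid(20), 25, seed = 31)
  g <- general_weights(tm)
  z <- ring_phase(tm$theta)
  mse <- function(w) mean(Mod(drop(tm$counts %*% w) - z)^2)
  base <- mse(g$weights)
  set.seed(8)
  for (k in 1:200) {
    delta <- complex(real = rnorm(10, 0, 0.02), imaginary = rnorm(10, 0, 0.02))
    expect_gte(mse(g$weights + delta * mean(Mod(g$weights))), base)
  }
})

test_that("moment-based general weights equal the raw least-squares
          solution", {
  p <- tiny_ring(n_units = 8)
  tm <- gen_ring_responses(p, theta_grid(16), 12, seed = 41)
  g <- general_weights(tm)
  # independent route: complex least squares via the stacked real system
  X <- tm$counts
  z <- ring_phase(tm$theta)
  w_ls <- qr.solve(rbind(cbind(X, 0 * X), cbind(0 * X, X)),
                   c(Re(z), Im(z)))
  w_ls <- complex(real = w_ls[1:8], imaginary = w_ls[9:16])
  expect_equal(g$weights, w_ls, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("general information uses wrapped residuals, applies the bias
          factor, and guards the degenerate case", {
  th <- theta_grid(40)
  f <- cbind(cos(2 * pi * th), sin(2 * pi * th))
  tm <- trial_matrix(rbind(f, f), theta = c(th, th))
  g <- general_weights(tm)
  gi <- general_info(tm, g)
  expect_true(gi$unbounded)
  expect_identical(gi$value, Inf)
  # bias factor applied as printed
  p <- tiny_ring(n_units = 10)
  noisy <- gen_ring_responses(p, th, 10, seed = 51)
  gd <- general_weights(noisy)
  gi2 <- general_info(noisy, gd)
  expect_equal(gi2$value,
               (1 / gi2$residual_var) *
                 (n_trials(noisy) - 10 - 2) / (n_trials(noisy) - 1))
  small <- subset_trials(noisy, 1:11)
  expect_error(general_info(small, gd), "Ntr > N \\+ 2")
})

test_that("general information agrees with a hold-out variance oracle", {
  p <- tiny_ring(n_units = 15, radial_sd = 0.15)
  th <- theta_grid(30)
  fit_data <- gen_ring_responses(p, th, 25, seed = 61)
  big <- gen_ring_responses(p, th, 250, seed = 62)
  gd <- general_weights(fit_data)
  in_sample <- general_info(fit_data, gd)$value
  hold_out <- general_info(big, gd, corrected = FALSE)$value
  expect_lt(abs(in_sample - hold_out) / hold_out, 0.1)
})

test_that("pairwise discrimination is at chance for identical conditions
          and perfect for separable ones", {
  p <- tiny_ring(n_units = 10)
  tm <- gen_ring_responses(p, theta_grid(10), 60, seed = 71)
  acc_null <- pair_discrimination(tm, 0.5, 0.5, mode = "specific", seed = 3)
  se <- sqrt(0.25 / 60)
  expect_lt(abs(acc_null - 0.5), 3 * se)
  x <- rbind(matrix(rnorm(100, 0), 50, 2), matrix(rnorm(100, 10), 50, 2))
  sep <- trial_matrix(x, theta = rep(c(0.3, 0.7), each = 50))
  expect_equal(pair_discrimination(sep, 0.3, 0.7, seed = 5), 1.0)
})

test_that("general-mode discrimination classifies in the projected plane", {
  p <- tiny_ring(n_units = 20, radial_sd = 0.15, private_sd = 1)
  tm <- gen_ring_responses(p, theta_grid(25), 40, seed = 81)
  acc <- pair_discrimination(tm, 0.2, 0.24, mode = "general", seed = 5)
  expect_gt(acc, 0.6)
  expect_lte(acc, 1.0)
})

test_that("leave-one-out linear classification hits its separable and
          chance anchors", {
  x <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(60, 8), 30, 2))
  y <- rep(c(0, 1), each = 30)
  expect_equal(as.numeric(loocv_linear_performance(x, y)), 1.0)
  set.seed(12)
  y_rand <- rbinom(60, 1, 0.5)
  perf <- as.numeric(loocv_linear_performance(matrix(rnorm(600), 60, 10),
                                              y_rand))
  expect_lt(abs(perf - 0.5), 0.25)
  expect_error(loocv_linear_performance(x, rep(0, 60)), "both classes")
})

test_that("classifier variants agree on separable data and ties go to the
          first class", {
  x <- rbind(matrix(rnorm(40, 0, 0.1), 20, 2), matrix(rnorm(40, 5, 0.1), 20, 2))
  y <- rep(c(0, 1), each = 20)
  for (cl in c("lda", "logistic", "svm")) {
    expect_equal(as.numeric(loocv_linear_performance(x, y, classifier = cl)),
                 1.0, info = cl)
  }
})

test_that("choice-trained scoring (train on choice, evaluate on stimulus)
          sits between chance and the stimulus-trained decoder", {
  set.seed(33)
  above <- 0L; below <- 0L
  for (r in 1:20) {
    n <- 60
    x <- rbind(matrix(rnorm(2 * n, 0), n, 2), matrix(rnorm(2 * n, 2), n, 2))
    stim <- rep(c(0, 1), each = n)
    # noisy choices generated from a planted readout of x
    dv <- x[, 1] + rnorm(2 * n, 0, 2)
    choice <- as.integer(dv > 1)
    if (length(unique(choice)) < 2) next
    p_stim <- as.numeric(loocv_linear_performance(x, stim))
    p_choice <- as.numeric(loocv_linear_performance(x, choice,
                                                    eval_labels = stim))
    above <- above + (p_choice > 0.5)
    below <- below + (p_choice <= p_stim)
  }
  expect_gt(above, 15)
  expect_gt(below, 15)
})

test_that("decoders serialize to JSON with real/imaginary weight pairs", {
  p <- tiny_ring(n_units = 6)
  tm <- gen_ring_responses(p, theta_grid(12), 10, seed = 91)
  g <- general_weights(tm)
  path <- tempfile(fileext = ".json")
  write_decoder_json(g, path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(x$type, "general")
  expect_equal(complex(real = x$weights_re, imaginary = x$weights_im),
               g$weights, ignore_attr = TRUE)
  unlink(path)
})
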