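test_that("unit inclusion applies the rate and signed-rank criteria", {
  set.seed(21)
  n <- 60
  # unit 1: driven at 25 Hz vs 5 Hz baseline -> included
  # unit 2: 5 Hz stimulus rate -> excluded (below 10 Hz)
  # unit 3: stimulus identical to baseline -> excluded (not significant)
  stim <- cbind(rpois(n, 5) / 0.2, rpois(n, 1) / 0.2, rpois(n, 4) / 0.2)
  base <- cbind(rpois(n, 0.5) / 0.1, rpois(n, 0.1) / 0.1, stim[, 3])
  mask <- include_units(stim, base)
  expect_identical(as.vector(mask), c(TRUE, FALSE, FALSE))
  st <- attr(mask, "stats")
  expect_match(st$reason[2], "below threshold")
  expect_match(st$reason[3], "not significant")
  # fewer than 6 paired trials: excluded with reason
  m2 <- include_units(stim[1:4, , drop = FALSE], base[1:4, , drop = FALSE])
  expect_false(any(m2))
  expect_true(all(attr(m2, "stats")$reason == "insufficient trials"))
})

test_that("planted responsiveness fractions are recovered", {
  set.seed(22)
  hits <- vapply(1:20, function(r) {
    nu <- 40; n <- 80
    responsive <- rep(c(TRUE, FALSE), c(28, 12))  # 70%
    stim <- sapply(seq_len(nu), function(j)
      rpois(n, if (responsive[j]) 6 else 0.4) / 0.2)
    base <- sapply(seq_len(nu), function(j) rpois(n, 0.4) / 0.1)
    mean(include_units(stim, base))
  }, numeric(1))
  expect_lt(abs(mean(hits) - 0.7), 0.05)
})

test_that("Williams' test is symmetric, antisymmetric, and guarded", {
  w0 <- williams_test(0.4, 0.4, 0.3, 50)
  expect_equal(w0$t, 0)
  expect_equal(w0$p, 1)
  wa <- williams_test(0.6, 0.2, 0.3, 50)
  wb <- williams_test(0.2, 0.6, 0.3, 50)
  expect_equal(wa$t, -wb$t)
  expect_equal(wa$p, wb$p)
  expect_identical(wa$df, 47)
  expect_error(williams_test(0.9, -0.9, 0.9, 50), "positive definite")
  expect_error(williams_test(1, 0.5, 0.3, 50), "\\|r\\| < 1")
  expect_error(williams_test(0.1, 0.2, 0.3, 3), ">= 4")
})

test_that("Williams' test maintains its type-I error rate under a
          trivariate-normal null", {
  set.seed(23)
  n <- 86
  rho <- 0.4; rkh <- 0.3
  # common-factor construction giving cor(j,k) = cor(j,h) = rho,
  # cor(k,h) = rkh
  S <- matrix(c(1, rho, rho, rho, 1, rkh, rho, rkh, 1), 3)
  L <- chol(S)
  rej <- 0L
  n_draws <- 10000
  for (r in seq_len(n_draws)) {
    x <- matrix(rnorm(n * 3), n, 3) %*% L
    cm <- cor(x)
    wt <- williams_test(cm[1, 2], cm[1, 3], cm[2, 3], n)
    if (wt$p < 0.05) rej <- rej + 1L
  }
  expect_gte(rej / n_draws, 0.04)
  expect_lte(rej / n_draws, 0.06)
})

test_that("Tukey fence excludes the textbook outlier, both variants are
          reported, and degenerate inputs are flagged", {
  rsc <- c(0.05, 0.06, 0.07, 0.08, 0.50)
  fence <- popdecode:::tukey_upper_fence(rsc)
  expect_true(0.50 > fence)
  expect_true(all(rsc[1:4] <= fence))
  df <- data.frame(
    day = rep(1:5, 2), condition = "cued",
    decoder = rep(c("monkey", "specific"), each = 5),
    performance = c(0.9, 0.85, 0.8, 0.75, 0.4, rep(0.9, 5)),
    mean_rsc = rep(rsc, 2))
  rep_ <- performance_vs_rsc(df)
  expect_identical(rep_$by_decoder$monkey$excluded, 5L)
  expect_identical(rep_$by_decoder$monkey$n, 4L)
  expect_false(is.na(rep_$by_decoder$monkey$filtered$r))
  # constant performance -> undefined correlation, reported as such
  expect_true(is.na(rep_$by_decoder$specific$filtered$r))
  expect_match(rep_$by_decoder$specific$filtered$note, "undefined")
})

test_that("shuffling day labels centers the performance correlation on 0", {
  set.seed(24)
  n <- 30
  rsc <- runif(n, 0.05, 0.3)
  perf <- 0.9 - rsc + rnorm(n, 0, 0.05)
  rs <- vapply(1:500, function(r) cor(sample(perf), rsc), numeric(1))
  expect_lt(abs(mean(rs)), 3 * sd(rs) / sqrt(length(rs)))
})

test_that("session decoders run per condition with evoked-response
          ranking and skip starved conditions", {
  s <- gen_session(tiny_session_config(cued_per_amount = 10), seed = 31)
  out <- specific_and_monkeys_decoders(s, "cued", pop_sizes = c(1, 5, 15))
  expect_identical(nrow(out), 6L)
  expect_true(all(out$status == "ok"))
  expect_true(all(out$performance >= 0 & out$performance <= 1))
  # pop_size = 1 must use the single most responsive unit
  sel <- popdecode:::median_change_rows(s, "cued")
  top <- popdecode:::evoked_ranking(s, sel$rows)[1]
  x1 <- s$decode$counts[sel$rows, top, drop = FALSE]
  p1 <- as.numeric(loocv_linear_performance(x1, sel$stim))
  expect_equal(out$performance[out$pop_size == 1 &
                                 out$decoder == "specific"], p1)
  # starved condition: no uncued trials at all
  cfg0 <- tiny_session_config(cued_per_amount = 4)
  cfg0$uncued_median <- 0; cfg0$uncued_largest <- 0
  s0 <- gen_session(cfg0, seed = 32)
  out0 <- specific_and_monkeys_decoders(s0, "uncued")
  expect_true(all(out0$status == "skipped"))
  expect_true(all(is.na(out0$performance)))
})

test_that("generality ladder enumerates the right subset counts and
          reports statuses", {
  s <- gen_session(tiny_session_config(cued_per_amount = 8), seed = 33)
  lad <- generality_ladder(s)
  perf <- lad$performance
  # k=1: 4 decoders x 4 evals; k=2: 6 x 4; k=3: 4 x 4; k=4: 1 x 4
  counts <- table(perf$level[perf$status == "ok"])
  expect_identical(as.vector(counts), c(16L, 24L, 16L, 4L))
  expect_identical(length(unique(perf$subset[perf$level == 2])), 6L)
  expect_identical(length(unique(perf$subset[perf$level == 4])), 1L)
  expect_true(all(perf$performance[perf$status == "ok"] >= 0))
  expect_identical(nrow(lad$choice_prediction), 15L)
})

test_that("monkey's decoder axis aligns with the planted readout when
          choices are strongly stimulus- and noise-driven", {
  cos_v <- vapply(1:12, function(d) {
    cfg <- tiny_session_config(n_units = 20, radial_sd = 0.2,
                               private_sd = 2, cued_per_amount = 20)
    monkeys_axis(gen_session(cfg, seed = 40 + d), "cued")$cosine
  }, numeric(1))
  expect_gt(median(cos_v), 0.7)
})
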