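test_that("model sweep on the ring backend emits both information ratios
          and reproduces byte-identical outputs under one seed", {
  out1 <- file.path(tempdir(), "sweep1")
  out2 <- file.path(tempdir(), "sweep2")
  cfg <- experiment_config(backend = "ring", n_units = 18, n_thetas = 20,
                           trials_per_theta = 25, fisher_trials = 80,
                           dtheta = 0.05, n_pairs = 2, seed = 5,
                           out_dir = out1)
  b1 <- run_model_experiment(cfg)
  expect_identical(b1$status, "complete")
  expect_true(is.finite(b1$ratios$specific))
  expect_true(is.finite(b1$ratios$general))
  expect_true(file.exists(file.path(out1, "levels.csv")))
  expect_true(file.exists(file.path(out1, "manifest.json")))
  cfg$out_dir <- out2
  b2 <- run_model_experiment(cfg)
  expect_identical(readLines(file.path(out1, "levels.csv")),
                   readLines(file.path(out2, "levels.csv")))
  # per-level battery is complete
  lvl <- b1$per_level[[1]]
  expect_true(all(c("mean_rate", "mean_rsc", "fa_eigenvalues", "fisher",
                    "general", "pair_accuracy") %in% names(lvl)))
  expect_identical(length(lvl$fa_eigenvalues), 5L)
  expect_identical(nrow(lvl$pair_accuracy), 2L)
  unlink(c(out1, out2), recursive = TRUE)
})

test_that("session experiment assembles cross-day summaries at toy scale", {
  cfg <- experiment_config(
    n_days = 5, seed = 11,
    session = tiny_session_config(n_units = 12, cued_per_amount = 8))
  b <- run_session_experiment(cfg)
  expect_s3_class(b, "experiment_bundle")
  expect_true(nrow(b$day_results) >= 16)
  expect_true(all(c("perf_vs_rsc", "williams", "ladder", "axis_cosines")
                  %in% names(b)))
  expect_true(is.finite(b$williams$t))
  expect_identical(length(b$ladder$trend$levels), 4L)
  expect_true(length(b$ladder$trend$trend_choice_ci) == 2)
})

test_that("fisher_vs_popsize returns one mean estimate per size", {
  p <- tiny_ring(n_units = 30)
  pair <- gen_ring_responses(p, c(0.45, 0.55), 150, seed = 3)
  fv <- fisher_vs_popsize(pair, sizes = c(5, 10, 20), dtheta = 0.05,
                          seed = 4)
  expect_identical(fv$n_units, c(5, 10, 20))
  expect_true(all(is.finite(fv$info)))
})

test_that("experiment configs hash deterministically", {
  c1 <- experiment_config(seed = 3)
  c2 <- experiment_config(seed = 3)
  c3 <- experiment_config(seed = 4)
  expect_identical(popdecode:::config_hash(c1), popdecode:::config_hash(c2))
  expect_false(identical(popdecode:::config_hash(c1),
                         popdecode:::config_hash(c3)))
})
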