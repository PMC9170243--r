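test_that("session blocks honor the cued/uncued composition", {
  cfg <- tiny_session_config(cued_per_amount = 20)
  cfg$uncued_median <- 20; cfg$uncued_largest <- 5
  s <- gen_session(cfg, seed = 2)
  m <- s$meta
  chg <- m[m$change_idx > 0, ]
  for (b in unique(chg$block)) {
    blk <- chg[chg$block == b, ]
    expect_identical(nrow(blk), 125L)
    expect_identical(sum(blk$cued == "cued"), 100L)   # 80%
    un <- blk[blk$cued == "uncued", ]
    expect_identical(sum(un$change_idx == 3L), 20L)
    expect_identical(sum(un$change_idx == 5L), 5L)
    expect_true(all(un$change_idx %in% c(3L, 5L)))
    expect_identical(as.vector(table(blk$change_idx[blk$cued == "cued"])),
                     rep(20L, 5))
  }
  # first presentation of each trial flagged
  expect_true(all(m$first[m$presentation == 1]))
  expect_false(any(m$first[m$presentation > 1]))
})

test_that("sessions are reproducible and validate their configuration", {
  cfg <- tiny_session_config()
  a <- gen_session(cfg, seed = 5)
  b <- gen_session(cfg, seed = 5)
  expect_identical(a$decode$counts, b$decode$counts)
  expect_identical(a$meta$choice, b$meta$choice)
  expect_error(session_config(change_amounts = c(0.1, 0.2)), "5 change")
  expect_error(session_config(change_amounts = c(0.3, 0.2, 0.4, 0.5, 0.6)),
               "strictly increasing")
})

test_that("hit rate is monotone nondecreasing in change amount", {
  # Monte-Carlo: average psychometric curves over many small sessions
  hr <- matrix(0, 40, 5)
  for (r in 1:40) {
    s <- gen_session(tiny_session_config(cued_per_amount = 10), seed = r)
    hr[r, ] <- session_hit_rates(s)$cued
  }
  curve <- colMeans(hr)
  expect_true(all(diff(curve) > -0.02))
  expect_gt(curve[5], curve[1])
})

test_that("noise-free choices are linearly separable along the planted
          axis and recovered by a choice-trained classifier", {
  cfg <- tiny_session_config(n_units = 10, private_sd = 1.5,
                             cued_per_amount = 20)
  cfg$psychometric_noise <- 0
  s <- gen_session(cfg, seed = 9)
  sel <- popdecode:::median_change_rows(s, "cued")
  # deterministic choices are a linear threshold on the planted axis:
  # the training data are exactly separable along that axis
  proj <- drop(s$decode$counts[sel$rows, ] %*% s$planted_axis)
  gap_ok <- max(proj[sel$choice == 1]) < min(proj[sel$choice == 0]) ||
    max(proj[sel$choice == 0]) < min(proj[sel$choice == 1])
  expect_true(gap_ok)
  # and a choice-trained classifier reproduces them almost perfectly
  # (left-out presentations near the threshold bound it below 1)
  perf <- loocv_linear_performance(s$decode$counts[sel$rows, ],
                                   sel$choice, classifier = "svm")
  expect_gte(as.numeric(perf), 0.9)
  ax <- monkeys_axis(s, "cued")
  expect_gt(ax$cosine, 0.8)
})

test_that("sessions serialize to CSV with a JSON parameter sidecar", {
  s <- gen_session(tiny_session_config(cued_per_amount = 4), seed = 3)
  base <- tempfile()
  write_session(s, base)
  expect_true(file.exists(paste0(base, ".csv")))
  expect_true(file.exists(paste0(base, "_rates.csv")))
  side <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  expect_equal(side$planted_axis, s$planted_axis, tolerance = 1e-12)
  expect_equal(side$change_amounts, s$change_amounts)
  df <- read.csv(paste0(base, ".csv"))
  expect_identical(nrow(df), nrow(s$meta))
  unlink(paste0(base, c(".csv", "_rates.csv", ".json")))
})

test_that("counting-window bookkeeping is carried on the containers", {
  s <- gen_session(tiny_session_config(cued_per_amount = 4), seed = 4)
  expect_identical(s$decode$window, "60-130ms")
  expect_identical(s$rates$window, "60-260ms")
})
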