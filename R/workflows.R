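#' Experiment configuration
#'
#' Bundles the parameters of the two canonical experiments — the model-side
#' attention sweep and the synthetic-session analysis — with explicit seeds
#' and a scale factor so desk-scale runs and larger runs share one code
#' path.
#'
#' @param name Experiment name.
#' @param backend `"ring"` (parametric ring-model surrogate, fast) or
#'   `"network"` (spiking circuit model).
#' @param attention_levels Attention levels to sweep (default `c(0, 1)`).
#' @param n_units Units decoded per level (ring backend) (default 100).
#' @param n_thetas Orientations on the ring (default 50).
#' @param trials_per_theta Ring-surrogate trials per orientation (default
#'   60).
#' @param fisher_trials Trials per condition for the fine-discrimination
#'   estimate (default 400).
#' @param dtheta Fine-discrimination half-offset (default 0.01).
#' @param delta_pair Orientation separation for pairwise SVM
#'   discrimination (default 0.04).
#' @param n_pairs Orientation pairs for the SVM comparison (default 10).
#' @param ring Base [ring_params()] for the surrogate backend.
#' @param network A [network_config()] for the network backend.
#' @param n_days Number of synthetic sessions ("days") for the session
#'   experiment (presets 46 and 28 mirror the two recorded subjects).
#' @param session Base [session_config()] for the session experiment.
#' @param radial_sd_range Across-day range of the shared-noise SD; day-to-day
#'   variation in this SD drives the across-day spread of mean correlated
#'   variability (default `c(0.05, 0.3)`).
#' @param decode_noise_range Across-day range of the decoder-window private
#'   noise multiplier (see [session_config()]'s `decode_noise_factor`),
#'   emulating day-to-day variation in early-window count reliability
#'   (default `c(0.7, 1.8)`).
#' @param seed Base seed; all stage seeds derive from it.
#' @param scale Scale factor multiplying trial counts (default 1).
#' @param out_dir Output directory for CSV/JSON bundles, or `NULL` to skip
#'   writing.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(name = "model_sweep",
                              backend = c("ring", "network"),
                              attention_levels = c(0, 1),
                              n_units = 100,
                              n_thetas = 50,
                              trials_per_theta = 60,
                              fisher_trials = 400,
                              dtheta = 0.01,
                              delta_pair = 0.04,
                              n_pairs = 10,
                              ring = ring_params(n_units = 100),
                              network = NULL,
                              n_days = 46,
                              session = session_config(),
                              radial_sd_range = c(0.05, 0.3),
                              decode_noise_range = c(0.7, 1.8),
                              seed = 1,
                              scale = 1,
                              out_dir = NULL) {
  backend <- match.arg(backend)
  if (scale <= 0) stop("'scale' must be positive")
  cfg <- as.list(environment())
  class(cfg) <- "experiment_config"
  cfg
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  x <- lapply(unclass(config), function(v)
    if (is.list(v)) unclass(v) else v)
  x$out_dir <- NULL
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

log_stage <- function(log, stage, t0, ...) {
  rec <- list(stage = stage, elapsed_s = round(
    as.numeric(proc.time()["elapsed"]) - t0, 3), ...)
  c(log, list(rec))
}

#' Bias-corrected Fisher information versus population size
#'
#' Recomputes the fine-discrimination information on nested random unit
#' subsets, for saturation / linear-growth analyses.
#'
#' @param data A two-condition [trial_matrix()] (see [fisher_info_bc()]).
#' @param sizes Population sizes.
#' @param dtheta Half-offset passed through.
#' @param n_resample Random unit subsets averaged per size (default 5).
#' @param seed Integer seed.
#' @return Data frame with `n_units` and mean `info`.
#' @export
fisher_vs_popsize <- function(data, sizes, dtheta = 0.01, n_resample = 5,
                              seed = 1) {
  nu <- n_units(data)
  with_seed(seed, {
    out <- lapply(sizes, function(ns) {
      vals <- vapply(seq_len(n_resample), function(r) {
        u <- sample.int(nu, min(ns, nu))
        fisher_info_bc(subset_trials(data, seq_len(n_trials(data)), u),
                       dtheta = dtheta)$value
      }, numeric(1))
      data.frame(n_units = ns, info = mean(vals))
    })
    do.call(rbind, out)
  })
}

# generate the two standard datasets for one attention level of the ring
# backend: a ring-spanning set and a fine-discrimination pair
ring_level_data <- function(config, level, seed) {
  base <- config$ring
  rp <- ring_params(
    n_units = config$n_units,
    amplitude = mean(base$amplitude), width = mean(base$width),
    baseline = mean(base$baseline), radial_sd = base$radial_sd,
    private_sd = base$private_sd, attention = level,
    attention_gain = base$attention_gain,
    heterogeneity = base$heterogeneity, param_seed = base$param_seed)
  thetas <- (seq_len(config$n_thetas) - 1) / config$n_thetas
  tpt <- max(4L, as.integer(round(config$trials_per_theta * config$scale)))
  ftr <- max(8L, as.integer(round(config$fisher_trials * config$scale)))
  ring_data <- gen_ring_responses(rp, thetas, tpt,
                                  seed = derive_seed(seed, 1))
  pair_data <- gen_ring_responses(
    rp, c(0.5 - config$dtheta, 0.5 + config$dtheta), ftr,
    seed = derive_seed(seed, 2))
  list(ring = ring_data, pair = pair_data, params = rp)
}

#' Run the model-side attention sweep
#'
#' For each attention level, generates (or simulates) population responses
#' and computes the full model-side battery: mean rates, mean pairwise
#' noise correlation, factor-analysis shared eigenvalues, bias-corrected
#' linear Fisher information of the specific decoder, the general
#' decoder's information, pairwise SVM discrimination accuracies in both
#' decoding regimes, and the trial-shuffle controls. Stage failures mark
#' the bundle partial but preserve completed stages.
#'
#' @param config An [experiment_config()].
#' @return A list of class `experiment_bundle` with per-level results,
#'   attended/unattended information ratios, the shuffle controls, a stage
#'   log, the config hash and seeds. If `config$out_dir` is set, CSV/JSON
#'   files are written there.
#' @export
run_model_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  t0 <- as.numeric(proc.time()["elapsed"])
  log <- list()
  levels <- config$attention_levels
  per_level <- list()
  status <- "complete"
  for (li in seq_along(levels)) {
    lev <- levels[li]
    res <- tryCatch({
      seed_l <- derive_seed(config$seed, 100 + li)
      dat <- if (config$backend == "ring") {
        ring_level_data(config, lev, seed_l)
      } else {
        network_level_data(config, lev, seed_l)
      }
      theta0_trials <- subset_trials(
        dat$ring, dat$ring$theta == dat$ring$theta[
          which.min(ring_dist(dat$ring$theta, 0.5))])
      rsc <- noise_correlations(theta0_trials)$mean_rsc
      fa <- factor_fit(theta0_trials$counts, n_factors = 5,
                       seed = derive_seed(seed_l, 3))
      fi <- fisher_info_bc(dat$pair, dtheta = config$dtheta)
      gd <- general_weights(dat$ring)
      gi <- general_info(dat$ring, gd)
      pair_acc <- pair_svm_battery(dat$ring, gd, config,
                                   seed = derive_seed(seed_l, 4))
      shuffled_ring <- shuffle_trials(dat$ring, derive_seed(seed_l, 5))
      shuffled_pair <- shuffle_trials(dat$pair, derive_seed(seed_l, 6))
      fi_sh <- fisher_info_bc(shuffled_pair, dtheta = config$dtheta)
      gd_sh <- general_weights(shuffled_ring)
      gi_sh <- general_info(shuffled_ring, gd_sh)
      list(level = lev, mean_rate = mean(theta0_trials$counts),
           mean_rsc = rsc, fa_eigenvalues = fa$shared_eigenvalues,
           fisher = fi$value, general = gi$value,
           fisher_shuffled = fi_sh$value, general_shuffled = gi_sh$value,
           pair_accuracy = pair_acc, data = dat)
    }, error = function(e) {
      status <<- "partial"
      list(level = lev, error = conditionMessage(e))
    })
    per_level[[li]] <- res
    log <- log_stage(log, sprintf("level_%g", lev), t0,
                     seed = derive_seed(config$seed, 100 + li))
  }
  ratios <- tryCatch({
    ok <- vapply(per_level, function(r) is.null(r$error), TRUE)
    if (sum(ok) >= 2) {
      a <- per_level[[which.max(levels)]]; u <- per_level[[which.min(levels)]]
      list(specific = a$fisher / u$fisher,
           general = a$general / u$general,
           specific_shuffled = a$fisher_shuffled / u$fisher_shuffled,
           general_shuffled = a$general_shuffled / u$general_shuffled)
    } else NULL
  }, error = function(e) { status <<- "partial"; NULL })
  log <- log_stage(log, "ratios", t0)
  bundle <- structure(
    list(kind = "model_sweep", status = status, levels = levels,
         per_level = lapply(per_level, function(r) { r$data <- NULL; r }),
         ratios = ratios, log = log, seed = config$seed,
         config_hash = config_hash(config)),
    class = "experiment_bundle")
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

# pairwise SVM discrimination accuracy, both modes, over orientation pairs
pair_svm_battery <- function(ring_data, decoder, config, seed) {
  th <- sort(unique(ring_data$theta))
  step <- round(config$delta_pair * length(th))
  if (step < 1) stop("'delta_pair' is below the orientation grid spacing")
  starts <- th[round(seq(1, length(th) - step,
                         length.out = config$n_pairs))]
  out <- lapply(seq_along(starts), function(i) {
    t1 <- starts[i]
    t2 <- th[match(t1, th) + step]
    data.frame(
      theta1 = t1, theta2 = t2,
      specific = pair_discrimination(ring_data, t1, t2, "specific",
                                     seed = derive_seed(seed, i)),
      general = pair_discrimination(ring_data, t1, t2, "general",
                                    seed = derive_seed(seed, 1000 + i),
                                    decoder = decoder))
  })
  do.call(rbind, out)
}

# network-backend data for one attention level, shaped like ring_level_data
network_level_data <- function(config, level, seed) {
  ncfg <- config$network
  if (is.null(ncfg)) ncfg <- network_config()
  map <- make_orientation_map(0.2, grid_side = ncfg$l4_grid,
                              seed = derive_seed(seed, 21))
  fb <- calibrate_filterbank(make_filterbank(map),
                             seed = derive_seed(seed, 22))
  conn <- build_connectivity(ncfg, seed = derive_seed(config$seed, 7))
  n_cyc <- ncfg$protocol$n_cycles
  thetas <- (seq_len(config$n_thetas) - 1) / config$n_thetas
  sim_ring <- build_and_simulate(
    ncfg, fb, conn, level,
    rep_len(thetas, n_cyc), seed = derive_seed(seed, 23))
  sim_pair <- build_and_simulate(
    ncfg, fb, conn, level,
    rep_len(c(0.5 - config$dtheta, 0.5 + config$dtheta), n_cyc),
    seed = derive_seed(seed, 24))
  list(ring = sim_ring$v4e, pair = balance_pair(sim_pair$v4e),
       params = ncfg)
}

# equalize the two conditions' trial counts (drop the excess)
balance_pair <- function(tm) {
  th <- sort(unique(tm$theta))
  i1 <- which(tm$theta == th[1]); i2 <- which(tm$theta == th[2])
  k <- min(length(i1), length(i2))
  subset_trials(tm, sort(c(i1[seq_len(k)], i2[seq_len(k)])))
}

#' Run the synthetic-session ("recording day") experiment
#'
#' Generates `n_days` synthetic sessions whose shared-noise amplitude
#' varies day to day, runs the session pipeline on each (specific and
#' choice-trained decoders per cue condition, mean correlated variability,
#' generality ladder), and assembles the cross-day summaries: the
#' performance-versus-correlated-variability correlations with Tukey
#' exclusion and Williams' test, and the ladder trends with a bootstrap
#' confidence interval over days.
#'
#' @param config An [experiment_config()] (fields `n_days`, `session`,
#'   `radial_sd_range`, `seed`, `scale`, `out_dir`).
#' @return A list of class `experiment_bundle`: `day_results` (per
#'   day/condition/decoder performance and mean r_SC), `perf_vs_rsc`
#'   (a [performance_vs_rsc()] report), `williams` (monkey-vs-specific
#'   decoder comparison), `ladder` (per-day ladder summaries and the
#'   cross-day trend statistics with bootstrap CI), `axis_cosines`, a
#'   stage log, config hash and seeds.
#' @export
run_session_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  t0 <- as.numeric(proc.time()["elapsed"])
  log <- list()
  status <- "complete"
  scfg <- config$session
  n_days <- config$n_days
  day_rows <- list(); ladder_days <- list(); cosines <- numeric(n_days)
  with_seed(derive_seed(config$seed, 500), {
    day_radial <- stats::runif(n_days, config$radial_sd_range[1],
                               config$radial_sd_range[2])
    day_dnf <- stats::runif(n_days, config$decode_noise_range[1],
                            config$decode_noise_range[2])
  })
  day_errors <- character(0)
  for (d in seq_len(n_days)) {
    res <- tryCatch({
      cfg_d <- scfg
      cfg_d$ring$radial_sd <- day_radial[d]
      cfg_d$decode_noise_factor <- day_dnf[d]
      s <- gen_session(cfg_d, seed = derive_seed(config$seed, 600 + d))
      rows <- list()
      for (cond in c("cued", "uncued")) {
        perf <- specific_and_monkeys_decoders(s, cond)
        rsc <- session_mean_rsc(s, cond)
        perf$mean_rsc <- rsc
        perf$day <- d
        rows[[cond]] <- perf
      }
      lad <- generality_ladder(s)
      lad_df <- merge(lad$performance, lad$choice_prediction,
                      by = c("level", "subset"), all.x = TRUE)
      mperf <- rows$cued$performance[rows$cued$decoder == "monkey"][1]
      list(rows = do.call(rbind, rows), ladder = lad_df,
           monkey_perf = mperf,
           cosine = monkeys_axis(s, "cued")$cosine)
    }, error = function(e) {
      status <<- "partial"
      day_errors <<- c(day_errors, sprintf("day %d: %s", d,
                                           conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) {
      day_rows[[d]] <- res$rows
      res$ladder$day <- d
      res$ladder$monkey_perf <- res$monkey_perf
      ladder_days[[d]] <- res$ladder
      cosines[d] <- res$cosine
    }
  }
  log <- c(log, lapply(day_errors, function(m) list(stage = "day_error",
                                                    message = m)))
  log <- log_stage(log, "sessions", t0, n_days = n_days)
  day_results <- do.call(rbind, day_rows)
  day_results <- day_results[day_results$status == "ok", ]
  pr <- tryCatch(performance_vs_rsc(day_results),
                 error = function(e) { status <<- "partial"; NULL })
  wt <- tryCatch({
    wide <- stats::reshape(
      day_results[, c("day", "condition", "decoder", "performance",
                      "mean_rsc")],
      idvar = c("day", "condition", "mean_rsc"), timevar = "decoder",
      direction = "wide")
    keep <- wide$mean_rsc <= tukey_upper_fence(wide$mean_rsc)
    wide <- wide[keep, ]
    williams_test(stats::cor(wide$mean_rsc, wide$performance.monkey),
                  stats::cor(wide$mean_rsc, wide$performance.specific),
                  stats::cor(wide$performance.monkey,
                             wide$performance.specific),
                  nrow(wide))
  }, error = function(e) { status <<- "partial"; NULL })
  ladder_all <- do.call(rbind, ladder_days)
  ladder_trend <- tryCatch(
    ladder_trend_stats(ladder_all, seed = derive_seed(config$seed, 900)),
    error = function(e) { status <<- "partial"; NULL })
  log <- log_stage(log, "cross_day", t0)
  bundle <- structure(
    list(kind = "session_experiment", status = status,
         day_results = day_results, perf_vs_rsc = pr, williams = wt,
         ladder = list(per_day = ladder_all, trend = ladder_trend),
         axis_cosines = cosines, log = log, seed = config$seed,
         config_hash = config_hash(config)),
    class = "experiment_bundle")
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

# cross-day ladder trends: Spearman trend of (i) the across-day correlation
# between each (subset, eval amount) decoder's performance and the monkey's
# decoder performance, averaged per generality level, and (ii) choice
# prediction per level, with a bootstrap CI over days. One correlation per
# decoder across days (the paper's Fig 3F convention) keeps eval difficulty
# matched across generality columns.
ladder_trend_stats <- function(ladder_all, n_boot = 200, seed = 1) {
  lv <- sort(unique(ladder_all$level))
  corr_by_level <- function(df) {
    vapply(lv, function(k) {
      d <- df[df$level == k, ]
      rs <- vapply(split(d, paste(d$subset, d$eval_amount)), function(dd) {
        dd <- dd[order(dd$day), ]
        if (nrow(dd) < 4 || stats::sd(dd$performance) == 0 ||
            stats::sd(dd$monkey_perf) == 0) return(NA_real_)
        stats::cor(dd$performance, dd$monkey_perf)
      }, numeric(1))
      mean(rs, na.rm = TRUE)
    }, numeric(1))
  }
  r_monkey <- corr_by_level(ladder_all)
  choice_by_level <- vapply(lv, function(k)
    mean(ladder_all$choice_prediction[ladder_all$level == k],
         na.rm = TRUE), numeric(1))
  trend <- function(y) {
    ok <- is.finite(y)
    if (sum(ok) < 2) return(NA_real_)
    suppressWarnings(stats::cor(lv[ok], y[ok], method = "spearman"))
  }
  days <- unique(ladder_all$day)
  boots <- with_seed(seed, {
    replicate(n_boot, {
      bd <- sample(days, replace = TRUE)
      sub <- do.call(rbind, lapply(bd, function(d)
        ladder_all[ladder_all$day == d, ]))
      trend(vapply(lv, function(k)
        mean(sub$choice_prediction[sub$level == k]), numeric(1)))
    })
  })
  list(levels = lv, r_with_monkey = r_monkey,
       choice_prediction = choice_by_level,
       trend_r_with_monkey = trend(r_monkey),
       trend_choice = trend(choice_by_level),
       trend_choice_ci = stats::quantile(boots, c(0.025, 0.975),
                                         na.rm = TRUE, names = FALSE))
}

#' @export
print.experiment_bundle <- function(x, ...) {
  cat(sprintf("experiment_bundle '%s' (%s)\n", x$kind, x$status))
  if (identical(x$kind, "model_sweep") && !is.null(x$ratios)) {
    cat(sprintf(
      "  info ratio (att/unatt): specific %.3f, general %.3f\n",
      x$ratios$specific, x$ratios$general))
    cat(sprintf(
      "  shuffled:               specific %.3f, general %.3f\n",
      x$ratios$specific_shuffled, x$ratios$general_shuffled))
  }
  if (identical(x$kind, "session_experiment") && !is.null(x$perf_vs_rsc)) {
    print(x$perf_vs_rsc)
    if (!is.null(x$williams)) print(x$williams)
  }
  invisible(x)
}

# write CSV tables and a JSON manifest for a bundle
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(kind = bundle$kind, status = bundle$status,
                   seed = bundle$seed, config_hash = bundle$config_hash,
                   log = bundle$log)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  if (identical(bundle$kind, "model_sweep")) {
    tab <- do.call(rbind, lapply(bundle$per_level, function(r) {
      if (!is.null(r$error)) return(NULL)
      data.frame(level = r$level, mean_rate = r$mean_rate,
                 mean_rsc = r$mean_rsc, fisher = r$fisher,
                 general = r$general, fisher_shuffled = r$fisher_shuffled,
                 general_shuffled = r$general_shuffled,
                 lambda1 = r$fa_eigenvalues[1])
    }))
    utils::write.csv(tab, file.path(out_dir, "levels.csv"),
                     row.names = FALSE)
    if (!is.null(bundle$ratios)) {
      jsonlite::write_json(bundle$ratios,
                           file.path(out_dir, "ratios.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  } else if (identical(bundle$kind, "session_experiment")) {
    utils::write.csv(bundle$day_results,
                     file.path(out_dir, "day_results.csv"),
                     row.names = FALSE)
    utils::write.csv(bundle$ladder$per_day,
                     file.path(out_dir, "ladder.csv"), row.names = FALSE)
  }
  invisible(out_dir)
}
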