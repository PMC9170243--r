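#' Unit inclusion by stimulus drive
#'
#' A unit is kept if its mean stimulus-driven firing rate exceeds 10 Hz and
#' is significantly higher than its baseline rate (two-sided Wilcoxon signed
#' rank test on paired trial rates, p < 1e-10). Units with fewer than 6
#' paired trials are excluded with reason `"insufficient trials"`.
#'
#' @param stim_rates Matrix (trials x units) of stimulus-window firing
#'   rates in Hz.
#' @param baseline_rates Matrix (trials x units) of baseline-window rates
#'   in Hz (paired by trial; the baseline window is the 100 ms before the
#'   first stimulus of each trial).
#' @param rate_threshold_hz Minimum mean stimulus rate (default 10).
#' @param alpha Signed-rank significance threshold (default 1e-10).
#' @return Logical inclusion mask with attribute `stats`: a data frame of
#'   per-unit mean rates, p-values and exclusion reasons.
#' @export
include_units <- function(stim_rates, baseline_rates,
                          rate_threshold_hz = 10, alpha = 1e-10) {
  stim_rates <- as.matrix(stim_rates)
  baseline_rates <- as.matrix(baseline_rates)
  if (!all(dim(stim_rates) == dim(baseline_rates))) {
    stop("'stim_rates' and 'baseline_rates' must be paired (same dim)")
  }
  nu <- ncol(stim_rates)
  mask <- logical(nu)
  stats_df <- data.frame(mean_stim = colMeans(stim_rates),
                         mean_base = colMeans(baseline_rates),
                         p = NA_real_, reason = "", stringsAsFactors = FALSE)
  for (j in seq_len(nu)) {
    if (nrow(stim_rates) < 6) {
      stats_df$reason[j] <- "insufficient trials"
      next
    }
    if (stats_df$mean_stim[j] <= rate_threshold_hz) {
      stats_df$reason[j] <- "rate below threshold"
      next
    }
    d <- stim_rates[, j] - baseline_rates[, j]
    p <- if (all(d == 0)) 1 else
      suppressWarnings(stats::wilcox.test(d, alternative = "two.sided",
                                          exact = FALSE)$p.value)
    stats_df$p[j] <- p
    if (is.na(p) || p >= alpha) {
      stats_df$reason[j] <- "not significant vs baseline"
      next
    }
    mask[j] <- TRUE
  }
  attr(mask, "stats") <- stats_df
  mask
}

# presentations of the median changed orientation and the starting
# presentation immediately before them, for one cue condition; returns
# row indices into the presentation-level matrices plus binary labels
median_change_rows <- function(session, condition) {
  m <- session$meta
  chg <- which(m$change_idx == 3L & m$cued == condition)
  pre <- chg - 1L
  ok <- pre >= 1 & m$trial[pre] == m$trial[chg] & m$change_idx[pre] == 0L &
    !m$first[pre]
  chg <- chg[ok]; pre <- pre[ok]
  list(rows = c(pre, chg),
       stim = rep(c(0L, 1L), c(length(pre), length(chg))),
       choice = m$choice[c(pre, chg)])
}

# rank units by evoked response: mean stimulus-window rate minus mean
# baseline rate (Hz), computed on the given presentation rows
evoked_ranking <- function(session, rows) {
  dur <- session$config$rate_window_ms / 1000
  stim_hz <- colMeans(session$rates$counts[rows, , drop = FALSE]) / dur
  base_hz <- colMeans(session$baseline) / 0.1
  order(stim_hz - base_hz, decreasing = TRUE)
}

#' Specific and choice-trained ("monkey's") decoders for one session
#'
#' Trains, per cue condition and population size, (i) the specific decoder —
#' a linear classifier separating decoder-window responses to the median
#' changed orientation from responses to the starting orientation presented
#' immediately before it — and (ii) the monkey's decoder — trained on the
#' same presentations but labeled by the subject's saccade choice. Both are
#' scored by leave-one-out cross-validation against stimulus identity.
#' Population sizes take the most responsive units first (evoked-response
#' ranking: stimulus rate minus baseline rate).
#'
#' @param session A [gen_session()] result.
#' @param condition `"cued"` or `"uncued"`.
#' @param pop_sizes Integer vector of population sizes (default: all units).
#' @param classifier Passed to [loocv_linear_performance()].
#' @return A data frame with columns `condition`, `pop_size`, `decoder`
#'   (`"specific"`/`"monkey"`), `performance`, `n_presentations`, `status`;
#'   conditions with fewer than 10 usable presentations are returned with
#'   `status = "skipped"` and `NA` performance.
#' @export
specific_and_monkeys_decoders <- function(session, condition,
                                          pop_sizes = NULL,
                                          classifier = "lda") {
  stopifnot(inherits(session, "synthetic_session"))
  stopifnot(identical(session$decode$window, "60-130ms"))
  sel <- median_change_rows(session, condition)
  nu <- n_units(session$decode)
  if (is.null(pop_sizes)) pop_sizes <- nu
  if (length(sel$rows) < 10 || length(unique(sel$choice)) < 2) {
    return(data.frame(condition = condition,
                      pop_size = rep(pop_sizes, each = 2),
                      decoder = rep(c("specific", "monkey"),
                                    length(pop_sizes)),
                      performance = NA_real_,
                      n_presentations = length(sel$rows),
                      status = "skipped"))
  }
  rank_units <- evoked_ranking(session, sel$rows)
  out <- list()
  for (ps in pop_sizes) {
    units <- rank_units[seq_len(min(ps, nu))]
    x <- session$decode$counts[sel$rows, units, drop = FALSE]
    perf_s <- loocv_linear_performance(x, sel$stim,
                                       classifier = classifier)
    perf_m <- loocv_linear_performance(x, sel$choice, eval_labels = sel$stim,
                                       classifier = classifier)
    out[[length(out) + 1L]] <- data.frame(
      condition = condition, pop_size = ps,
      decoder = c("specific", "monkey"),
      performance = c(as.numeric(perf_s), as.numeric(perf_m)),
      n_presentations = length(sel$rows), status = "ok")
  }
  do.call(rbind, out)
}

#' Choice-trained readout axis of a session
#'
#' The regularized linear discriminant separating saccade from no-saccade
#' presentations (median change amount plus preceding starting
#' presentations, given cue condition), for comparison with the session's
#' planted generative axis.
#'
#' @inheritParams specific_and_monkeys_decoders
#' @param ridge Shrinkage for the axis estimate (default 2; axis
#'   estimation benefits from heavier regularization than classification
#'   in the trial-limited regime).
#' @return List with `axis` (unit-norm weight vector over all units) and
#'   `cosine` (absolute cosine similarity with the planted axis).
#' @export
monkeys_axis <- function(session, condition = "cued", ridge = 2) {
  sel <- median_change_rows(session, condition)
  if (length(unique(sel$choice)) < 2) {
    return(list(axis = rep(NA_real_, n_units(session$decode)),
                cosine = NA_real_))
  }
  w <- discriminant_axis(session$decode$counts[sel$rows, , drop = FALSE],
                         sel$choice, ridge = ridge)
  w <- w / sqrt(sum(w^2))
  a <- session$planted_axis / sqrt(sum(session$planted_axis^2))
  list(axis = w, cosine = abs(sum(w * a)))
}

#' Mean correlated variability of a session condition
#'
#' Mean pairwise noise correlation over starting-orientation presentations
#' (rate window, first presentations excluded) for one cue condition.
#'
#' @inheritParams specific_and_monkeys_decoders
#' @return Scalar mean r_SC.
#' @export
session_mean_rsc <- function(session, condition) {
  stopifnot(identical(session$rates$window, "60-260ms"))
  m <- session$meta
  rows <- which(m$change_idx == 0L & !m$first & m$cued == condition)
  tm <- subset_trials(session$rates, rows)
  noise_correlations(tm)$mean_rsc
}

#' Generality ladder: more-general versus more-specific stimulus decoders
#'
#' For each generality level `k` in `levels`, trains one decoder per
#' `k`-subset of the non-median change amounts {1, 2, 4, 5} (the median,
#' 3rd, amount is reserved for the monkey's decoder to avoid an inherent
#' relationship) to differentiate decoder-window responses to the subset's
#' changed orientations from the preceding starting-orientation responses.
#' Each decoder is evaluated on (i) identifying each included changed
#' orientation versus the start (leave-one-out within training amounts,
#' direct scoring for amounts outside the training subset), and (ii)
#' predicting the subject's choices on median-change presentations. Cued
#' trials only.
#'
#' @param session A [gen_session()] result.
#' @param levels Generality levels to compute (subset sizes, default 1:4).
#' @param classifier Passed to [loocv_linear_performance()].
#' @return List of two data frames: `performance` (level, subset, eval
#'   amount, proportion correct, status) and `choice_prediction` (level,
#'   subset, proportion of median-change presentations on which the
#'   stimulus decoder's prediction matched the subject's choice).
#' @export
generality_ladder <- function(session, levels = 1:4, classifier = "lda") {
  stopifnot(inherits(session, "synthetic_session"))
  m <- session$meta
  amounts <- c(1L, 2L, 4L, 5L)
  # rows per change amount (cued), with preceding start rows
  amt_rows <- lapply(c(amounts, 3L), function(k) {
    chg <- which(m$change_idx == k & m$cued == "cued")
    pre <- chg - 1L
    ok <- pre >= 1 & m$trial[pre] == m$trial[chg] & m$change_idx[pre] == 0L &
      !m$first[pre]
    list(chg = chg[ok], pre = pre[ok])
  })
  names(amt_rows) <- as.character(c(amounts, 3L))
  counts <- session$decode$counts
  perf <- list(); choice_pred <- list()
  for (k in levels) {
    subs <- utils::combn(amounts, k, simplify = FALSE)
    for (s in subs) {
      sid <- paste(s, collapse = "+")
      tr_chg <- unlist(lapply(as.character(s), function(a) amt_rows[[a]]$chg))
      tr_pre <- unlist(lapply(as.character(s), function(a) amt_rows[[a]]$pre))
      if (length(tr_chg) < 4) {
        perf[[length(perf) + 1L]] <- data.frame(
          level = k, subset = sid, eval_amount = NA_integer_,
          performance = NA_real_, status = "missing change amount")
        next
      }
      tr_rows <- c(tr_pre, tr_chg)
      tr_lab <- rep(c(0L, 1L), c(length(tr_pre), length(tr_chg)))
      for (a in amounts) {
        ar <- amt_rows[[as.character(a)]]
        if (length(ar$chg) == 0) {
          perf[[length(perf) + 1L]] <- data.frame(
            level = k, subset = sid, eval_amount = a,
            performance = NA_real_, status = "never shown")
          next
        }
        p <- if (a %in% s) {
          # evaluation trials are part of the training set: leave-one-out
          as.numeric(loocv_linear_performance(
            counts[tr_rows, , drop = FALSE], tr_lab,
            classifier = classifier))
        } else {
          w <- discriminant_axis(counts[tr_rows, , drop = FALSE], tr_lab)
          thr <- threshold_midpoint(counts[tr_rows, , drop = FALSE],
                                    tr_lab, w)
          ev_rows <- c(ar$pre, ar$chg)
          ev_lab <- rep(c(0L, 1L), c(length(ar$pre), length(ar$chg)))
          sc <- drop(counts[ev_rows, , drop = FALSE] %*% w)
          mean((sc > thr) == (ev_lab == 1L))
        }
        perf[[length(perf) + 1L]] <- data.frame(
          level = k, subset = sid, eval_amount = a, performance = p,
          status = "ok")
      }
      # choice prediction on median-change presentations
      med <- amt_rows[["3"]]
      if (length(med$chg) > 0) {
        w <- discriminant_axis(counts[tr_rows, , drop = FALSE], tr_lab)
        thr <- threshold_midpoint(counts[tr_rows, , drop = FALSE],
                                  tr_lab, w)
        ev_rows <- c(med$pre, med$chg)
        sc <- drop(counts[ev_rows, , drop = FALSE] %*% w)
        agree <- mean(as.integer(sc > thr) == m$choice[ev_rows])
        choice_pred[[length(choice_pred) + 1L]] <- data.frame(
          level = k, subset = sid, choice_prediction = agree)
      }
    }
  }
  list(performance = do.call(rbind, perf),
       choice_prediction = do.call(rbind, choice_pred))
}

# decision threshold at the midpoint of the two class-mean projections
threshold_midpoint <- function(x, labels, w) {
  s <- drop(x %*% w)
  (mean(s[labels == 0L]) + mean(s[labels == 1L])) / 2
}

#' Decoder performance versus mean correlated variability across days
#'
#' Correlates decoder performance with mean correlated variability across
#' day-condition points (two points per day, one per attention condition),
#' per decoder. Outlying mean r_SC values above the upper Tukey fence
#' (Q3 + 1.5 IQR) are excluded; both the filtered and unfiltered
#' correlations are reported.
#'
#' @param day_results Data frame with columns `day`, `condition`, `decoder`,
#'   `performance`, `mean_rsc` (one row per day x condition x decoder).
#' @return An object of class `perf_rsc_report`: per decoder, Pearson `r`
#'   and `p` with and without the Tukey exclusion, the fence value, and the
#'   indices of excluded points.
#' @export
performance_vs_rsc <- function(day_results) {
  need <- c("day", "condition", "decoder", "performance", "mean_rsc")
  if (!all(need %in% names(day_results))) {
    stop("'day_results' must have columns ", paste(need, collapse = ", "))
  }
  if (nrow(day_results) < 5) stop("need at least 5 day-condition points")
  rsc_points <- unique(day_results[, c("day", "condition", "mean_rsc")])
  fence <- tukey_upper_fence(rsc_points$mean_rsc)
  out <- list()
  for (dec in unique(day_results$decoder)) {
    d <- day_results[day_results$decoder == dec, ]
    keep <- d$mean_rsc <= fence
    corr <- function(dd) {
      if (nrow(dd) < 3 || stats::sd(dd$performance) == 0 ||
          stats::sd(dd$mean_rsc) == 0) {
        return(list(r = NA_real_, p = NA_real_,
                    note = "undefined (constant input)"))
      }
      ct <- stats::cor.test(dd$mean_rsc, dd$performance)
      list(r = unname(ct$estimate), p = ct$p.value, note = "ok")
    }
    out[[dec]] <- list(filtered = corr(d[keep, ]), all = corr(d),
                       n = sum(keep), n_all = nrow(d),
                       excluded = which(!keep))
  }
  structure(list(by_decoder = out, fence = fence), class = "perf_rsc_report")
}

#' @export
print.perf_rsc_report <- function(x, ...) {
  cat(sprintf("performance vs mean r_SC (Tukey upper fence %.4g):\n",
              x$fence))
  for (dec in names(x$by_decoder)) {
    b <- x$by_decoder[[dec]]
    cat(sprintf("  %-10s r = %+.3f (p = %.3g, n = %d)  [unfiltered r = %+.3f]\n",
                dec, b$filtered$r, b$filtered$p, b$n, b$all$r))
  }
  invisible(x)
}

# Q3 + 1.5 IQR (quartiles by type 7, R default)
tukey_upper_fence <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  q[2] + 1.5 * (q[2] - q[1])
}

#' Williams' procedure for comparing dependent correlations
#'
#' Tests whether two correlations that share a variable differ: `r_jk`
#' (e.g., performance of decoder k vs. variable j) against `r_jh`, given
#' the correlation `r_kh` between the two compared variables, over `n`
#' paired observations. Implemented as the Williams/Steiger t2 statistic
#' with `n - 3` degrees of freedom:
#' \deqn{t = (r_{jk} - r_{jh}) \sqrt{\frac{(n-1)(1 + r_{kh})}
#'   {2\frac{n-1}{n-3}|R| + \bar r^2 (1 - r_{kh})^3}},}
#' where \eqn{|R|} is the determinant of the 3x3 correlation matrix and
#' \eqn{\bar r = (r_{jk} + r_{jh})/2}. Calibration of the type-I error
#' under a trivariate-normal null is part of the test suite.
#'
#' @param r_jk,r_jh The two correlations being compared.
#' @param r_kh Correlation between variables k and h.
#' @param n Number of observations (>= 4).
#' @return An object of class `williams_result`: `t`, `p` (two-sided),
#'   `df`, and the inputs.
#' @export
williams_test <- function(r_jk, r_jh, r_kh, n) {
  if (n < 4) stop("'n' must be >= 4")
  if (any(abs(c(r_jk, r_jh, r_kh)) >= 1)) {
    stop("all correlations must satisfy |r| < 1")
  }
  detR <- 1 - r_jk^2 - r_jh^2 - r_kh^2 + 2 * r_jk * r_jh * r_kh
  if (detR <= 0) {
    stop(sprintf(
      "correlation triple is not positive definite (|R| = %.3g)", detR))
  }
  rbar <- (r_jk + r_jh) / 2
  denom <- 2 * detR * (n - 1) / (n - 3) + rbar^2 * (1 - r_kh)^3
  tstat <- (r_jk - r_jh) * sqrt((n - 1) * (1 + r_kh) / denom)
  df <- n - 3
  p <- 2 * stats::pt(-abs(tstat), df)
  structure(list(t = tstat, p = p, df = df,
                 inputs = c(r_jk = r_jk, r_jh = r_jh, r_kh = r_kh, n = n)),
            class = "williams_result")
}

#' @export
print.williams_result <- function(x, ...) {
  cat(sprintf("Williams' t = %.4g, df = %d, two-sided p = %.4g\n",
              x$t, x$df, x$p))
  invisible(x)
}
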