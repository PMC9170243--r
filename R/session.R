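#' Configuration of a synthetic change-detection session
#'
#' Describes one synthetic "day" of the cued orientation change detection
#' task: stimuli flash at a starting orientation until one flash changes to
#' one of five change amounts; attention is cued in blocks, with 80% of a
#' block's change trials at the cued location and the uncued changes
#' restricted to the median and largest amounts. Population responses come
#' from a [ring_params()] model whose shared-gain noise is reduced under
#' attention; choices are generated by a planted linear readout of the
#' decoder-window counts plus Gaussian noise and a fixed threshold.
#'
#' Two counting windows are emulated per stimulus presentation: a rate
#' window (nominally 60-260 ms after stimulus onset, 200 ms long) used for
#' firing rates and correlations, and an abbreviated decoder window
#' (60-130 ms) whose counts are scaled by the window-duration ratio and used
#' for all decoding and for the generative choice model.
#'
#' @param ring A [ring_params()] object (attention field ignored; set per
#'   condition from `attended_level`/`unattended_level`).
#' @param start_theta Starting orientation (all trials in the session).
#' @param change_amounts Five strictly increasing orientation change
#'   amounts (normalized ring units).
#' @param n_blocks Number of cue blocks (default 2).
#' @param cued_per_amount Cued change trials per amount per block
#'   (default 20; the paper-scale block has 5 x 20 cued + 25 uncued = 125).
#' @param uncued_median,uncued_largest Uncued change trials per block at the
#'   median and largest amounts (defaults 20 and 5).
#' @param presentations_per_trial Stimulus presentations per trial: the
#'   final one carries the changed orientation, the earlier ones the
#'   starting orientation; the first presentation of each trial is flagged
#'   for exclusion from analysis. Default 3.
#' @param attended_level,unattended_level Ring-model attention level used
#'   for cued / uncued trials (defaults 1 and 0).
#' @param planted_axis Generative readout axis (length = units). Default
#'   `NULL` builds an equal-parts combination of the mean change direction
#'   across all five amounts (a fixed "general" readout of the
#'   change-detection task) and the negated radial (gain) direction — the
#'   axis along which shared variability lives — so the decision variable
#'   rises monotonically with change amount while remaining fully exposed
#'   to shared gain fluctuations.
#' @param psychometric_noise SD of the additive Gaussian noise on the
#'   decision variable, in units of the start-to-median-change projection
#'   separation (default 0.35).
#' @param baseline_rate_hz Pre-stimulus baseline firing rate used for the
#'   100 ms baseline window counts (default 3 Hz).
#' @param rate_window_ms,decoder_window_ms Durations of the two counting
#'   windows (defaults 200 and 70 ms).
#' @param decode_noise_factor Multiplier on the private noise of the
#'   abbreviated decoder window only (default 1). Emulates day-to-day
#'   variation in early-window count reliability (latency jitter,
#'   adaptation state) that degrades all decoders without altering the
#'   rate-window correlation structure.
#' @return An object of class `session_config`.
#' @export
session_config <- function(ring = ring_params(n_units = 25, amplitude = 12,
                                              private_sd = 2),
                           start_theta = 0.5,
                           change_amounts = c(0.04, 0.07, 0.11, 0.18, 0.3),
                           n_blocks = 2,
                           cued_per_amount = 20,
                           uncued_median = 20,
                           uncued_largest = 5,
                           presentations_per_trial = 3,
                           attended_level = 1,
                           unattended_level = 0,
                           planted_axis = NULL,
                           psychometric_noise = 0.35,
                           baseline_rate_hz = 3,
                           rate_window_ms = 200,
                           decoder_window_ms = 70,
                           decode_noise_factor = 1) {
  if (length(change_amounts) != 5) {
    stop("exactly 5 change amounts are required")
  }
  if (any(diff(change_amounts) <= 0)) {
    stop("'change_amounts' must be strictly increasing")
  }
  if (presentations_per_trial < 2) {
    stop("'presentations_per_trial' must be >= 2 (the first is excluded)")
  }
  structure(
    list(ring = ring, start_theta = start_theta,
         change_amounts = change_amounts, n_blocks = n_blocks,
         cued_per_amount = cued_per_amount, uncued_median = uncued_median,
         uncued_largest = uncued_largest,
         presentations_per_trial = presentations_per_trial,
         attended_level = attended_level,
         unattended_level = unattended_level,
         planted_axis = planted_axis,
         psychometric_noise = psychometric_noise,
         baseline_rate_hz = baseline_rate_hz,
         rate_window_ms = rate_window_ms,
         decoder_window_ms = decoder_window_ms,
         decode_noise_factor = decode_noise_factor),
    class = "session_config"
  )
}

#' Generate a synthetic behavioral session
#'
#' Builds the full trial sequence (blocks, cue conditions, change amounts),
#' draws population responses from the ring model for every stimulus
#' presentation in both counting windows, and generates a choice for every
#' presentation from the planted readout axis: the decision variable is the
#' axis projection of the (mean-centered) decoder-window counts plus
#' Gaussian noise, thresholded midway between the mean projections of the
#' starting and median changed orientations, so hit rate rises with change
#' amount.
#'
#' @param config A [session_config()].
#' @param seed Integer seed; the session is reproducible given
#'   `(config, seed)`.
#' @return An object of class `synthetic_session`: `rates` and `decode`
#'   ([trial_matrix()] objects for the two windows, one row per stimulus
#'   presentation, with attention = cued/uncued and per-presentation choice
#'   labels), `meta` (data frame: trial, block, presentation, change_idx
#'   with 0 = starting orientation, first-presentation flag, hit/false-alarm
#'   bookkeeping), `planted_axis`, `change_amounts`, `psychometric_noise`,
#'   `config`, `baseline` (trials x units counts in the 100 ms pre-trial
#'   window).
#' @examples
#' cfg <- session_config(ring = ring_params(n_units = 15),
#'                       cued_per_amount = 4, uncued_median = 4,
#'                       uncued_largest = 1)
#' s <- gen_session(cfg, seed = 1)
#' table(s$decode$attention)
#' @export
gen_session <- function(config, seed) {
  stopifnot(inherits(config, "session_config"))
  ring <- config$ring
  # --- trial schedule -------------------------------------------------
  sched <- list()
  for (b in seq_len(config$n_blocks)) {
    cued <- data.frame(
      block = b, cued = "cued",
      change_idx = rep(seq_len(5), each = config$cued_per_amount))
    un_idx <- rep(c(3L, 5L), c(config$uncued_median, config$uncued_largest))
    uncued <- if (length(un_idx)) {
      data.frame(block = b, cued = "uncued", change_idx = un_idx)
    } else NULL
    sched[[b]] <- rbind(cued, uncued)
  }
  sched <- do.call(rbind, sched)
  ppt <- config$presentations_per_trial
  dur_rate <- config$rate_window_ms / 1000
  frac <- config$decoder_window_ms / config$rate_window_ms
  with_seed(seed, {
    # shuffle trial order within block
    ord <- unlist(lapply(split(seq_len(nrow(sched)), sched$block), sample),
                  use.names = FALSE)
    sched <- sched[ord, ]
    ntrial <- nrow(sched)
    npres <- ntrial * ppt
    # per-presentation bookkeeping
    meta <- data.frame(
      trial = rep(seq_len(ntrial), each = ppt),
      block = rep(sched$block, each = ppt),
      cued = rep(sched$cued, each = ppt),
      presentation = rep(seq_len(ppt), ntrial),
      change_idx = 0L, first = rep(c(TRUE, rep(FALSE, ppt - 1L)), ntrial))
    is_change <- meta$presentation == ppt
    meta$change_idx[is_change] <- rep(sched$change_idx, each = ppt)[is_change]
    theta <- ifelse(meta$change_idx == 0L, config$start_theta,
                    (config$start_theta +
                       config$change_amounts[pmax(meta$change_idx, 1L)]) %% 1)
    att_level <- ifelse(meta$cued == "cued", config$attended_level,
                        config$unattended_level)
    # --- population responses (shared gain common to both windows) ----
    f_all <- ring_tuning(ring, theta)             # npres x units
    sg <- ring$radial_sd * (1 - ring$attention_gain * att_level)
    g <- stats::rnorm(npres, 0, 1) * sg
    eps_rate <- matrix(stats::rnorm(npres * ring$n_units, 0,
                                    ring$private_sd),
                       npres, ring$n_units)
    eps_dec <- matrix(stats::rnorm(npres * ring$n_units, 0,
                                   ring$private_sd * sqrt(frac) *
                                     config$decode_noise_factor),
                      npres, ring$n_units)
    counts_rate <- pmax(f_all * (1 + g) + eps_rate, 0)
    counts_dec <- pmax(f_all * frac * (1 + g) + eps_dec, 0)
    # --- choices from the planted readout ------------------------------
    axis <- config$planted_axis
    if (is.null(axis)) {
      # default readout: equal-parts mixture of the radial (gain) axis and
      # the mean change direction over all five amounts — the axis of an
      # observer decoding "did anything change?" with one fixed readout
      f0 <- drop(ring_tuning(ring, config$start_theta))
      rad <- f0 / sqrt(sum(f0^2))
      dfs <- vapply(config$change_amounts, function(a) {
        v <- drop(ring_tuning(ring, (config$start_theta + a) %% 1)) - f0
        v / sqrt(sum(v^2))
      }, numeric(ring$n_units))
      gen_dir <- rowMeans(dfs)
      gen_dir <- gen_dir / sqrt(sum(gen_dir^2))
      # the radial component enters negatively: the readout rises both as
      # activity rotates toward any changed orientation and as the
      # start-pattern response drops, keeping the projection monotone in
      # change amount while still loading fully on the gain direction
      axis <- 0.5 * gen_dir - 0.5 * rad
      axis <- axis / sqrt(sum(axis^2))
    }
    proj <- drop(counts_dec %*% axis)
    mu_start <- drop(crossprod(
      axis, drop(ring_tuning(ring, config$start_theta)) * frac))
    mu_med <- drop(crossprod(
      axis, drop(ring_tuning(
        ring, (config$start_theta + config$change_amounts[3]) %% 1)) * frac))
    thr <- (mu_start + mu_med) / 2
    noise_scale <- abs(mu_start - mu_med)
    dv <- proj + stats::rnorm(npres, 0,
                              config$psychometric_noise * noise_scale)
    # saccade when the projection moves away from the starting orientation
    choice <- as.integer(sign(dv - thr) == sign(mu_med - mu_start))
    # --- baseline window (100 ms pre-trial) ----------------------------
    base_mean <- config$baseline_rate_hz * 0.1
    baseline <- matrix(stats::rpois(ntrial * ring$n_units, base_mean),
                       ntrial, ring$n_units)
    rates_tm <- trial_matrix(counts_rate, theta = theta,
                             attention = meta$cued, choice = choice,
                             block = meta$block, window = "60-260ms")
    dec_tm <- trial_matrix(counts_dec, theta = theta,
                           attention = meta$cued, choice = choice,
                           block = meta$block, window = "60-130ms")
    meta$choice <- choice
    meta$hit <- is_change & choice == 1L
    structure(
      list(rates = rates_tm, decode = dec_tm, meta = meta,
           planted_axis = axis, change_amounts = config$change_amounts,
           psychometric_noise = config$psychometric_noise,
           baseline = baseline, config = config),
      class = "synthetic_session"
    )
  })
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat(sprintf(
    "synthetic_session: %d trials (%d presentations), %d units, %d blocks\n",
    max(x$meta$trial), nrow(x$meta), n_units(x$decode),
    length(unique(x$meta$block))))
  hr <- session_hit_rates(x)
  cat("  cued hit rate by change amount: ",
      paste(sprintf("%.2f", hr$cued), collapse = " "), "\n")
  invisible(x)
}

#' Hit rates by change amount
#'
#' Proportion of change presentations answered with a saccade, per change
#' amount and cue condition.
#'
#' @param session A `synthetic_session`.
#' @return List with numeric vectors `cued` (length 5) and `uncued`
#'   (NA for amounts never shown uncued).
#' @export
session_hit_rates <- function(session) {
  m <- session$meta
  hr <- function(cond) {
    vapply(seq_len(5), function(k) {
      i <- m$change_idx == k & m$cued == cond
      if (!any(i)) NA_real_ else mean(m$choice[i])
    }, numeric(1))
  }
  list(cued = hr("cued"), uncued = hr("uncued"))
}

#' Write / read a synthetic session (CSV + JSON sidecar)
#'
#' The presentation-level data go to `<path>.csv` (decoder-window counts
#' plus labels and metadata columns) and `<path>_rates.csv` (rate-window
#' counts); generative parameters including the planted axis go to
#' `<path>.json` for recovery tests.
#'
#' @param session A `synthetic_session`.
#' @param path Base path (without extension).
#' @return Base `path`, invisibly.
#' @export
write_session <- function(session, path) {
  df <- as.data.frame(session$decode)
  df$presentation <- session$meta$presentation
  df$change_idx <- session$meta$change_idx
  df$first <- session$meta$first
  utils::write.csv(df, paste0(path, ".csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(session$rates), paste0(path, "_rates.csv"),
                   row.names = FALSE)
  side <- list(planted_axis = session$planted_axis,
               change_amounts = session$change_amounts,
               psychometric_noise = session$psychometric_noise,
               start_theta = session$config$start_theta,
               n_units = session$config$ring$n_units)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
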