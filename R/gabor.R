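#' Static Gabor image
#'
#' The stimulus: a Gabor patch on the unit square \eqn{\Gamma}, sampled at
#' `pixels x pixels`, with Gaussian envelope width `sigma`, spatial
#' wavelength `lambda` and phase `phase`. The normalized orientation
#' `theta` in `[0,1)` spans one full cycle of grating orientations (angle
#' \eqn{\pi \theta}, since a grating is invariant under rotation by
#' \eqn{\pi}).
#'
#' @param theta Orientation in `[0,1)`.
#' @param pixels Pixels per side (default 25).
#' @param sigma Envelope width (default 0.2).
#' @param lambda Spatial wavelength (default 0.6).
#' @param phase Phase (default 0).
#' @param center Length-2 center of the patch on `Gamma` (default origin).
#' @return Numeric vector of pixel values (length `pixels^2`, row-major),
#'   with attributes `pixels` and the parameters.
#' @export
gabor_patch <- function(theta, pixels = 25, sigma = 0.2, lambda = 0.6,
                        phase = 0, center = c(0, 0)) {
  if (sigma <= 0 || lambda <= 0) stop("'sigma' and 'lambda' must be positive")
  pos <- grid_positions(pixels)
  dx <- pos$x - center[1]; dy <- pos$y - center[2]
  a <- pi * theta
  img <- exp(-(dx^2 + dy^2) / (2 * sigma^2)) *
    cos(2 * pi / lambda * (dx * cos(a) + dy * sin(a)) + phase)
  structure(img, pixels = pixels, sigma = sigma, lambda = lambda,
            phase = phase, theta = theta)
}

#' Ornstein-Uhlenbeck pixel noise
#'
#' Each pixel of the stimulus is corrupted by independent OU noise
#' \eqn{\tau_n \, d\eta = -\eta \, dt + \sigma_n \, dW} with stationary
#' variance \eqn{\sigma_n^2 / (2 \tau_n)}. `ou_stationary_sd` gives that
#' analytic value; `ou_init` draws from the stationary distribution;
#' `ou_step` advances the state by `dt` using the exact discretization
#' (exponential decay plus Gaussian increment), so the stationary variance
#' is preserved for any `dt`.
#'
#' @param n Number of pixels (state dimension).
#' @param tau_n Noise correlation time in ms (default 40).
#' @param sigma_n Noise amplitude of the driving term (default 3.5).
#' @param eta Current state vector.
#' @param dt Time step in ms.
#' @return `ou_init`/`ou_step`: numeric state vector; `ou_stationary_sd`:
#'   scalar.
#' @export
ou_stationary_sd <- function(tau_n = 40, sigma_n = 3.5) {
  sigma_n / sqrt(2 * tau_n)
}

#' @rdname ou_stationary_sd
#' @export
ou_init <- function(n, tau_n = 40, sigma_n = 3.5) {
  stats::rnorm(n, 0, ou_stationary_sd(tau_n, sigma_n))
}

#' @rdname ou_stationary_sd
#' @export
ou_step <- function(eta, dt, tau_n = 40, sigma_n = 3.5) {
  a <- exp(-dt / tau_n)
  sd_inc <- ou_stationary_sd(tau_n, sigma_n) * sqrt(1 - a^2)
  a * eta + stats::rnorm(length(eta), 0, sd_inc)
}

#' Gabor filter bank for the layer-4 front end
#'
#' One Gabor filter per layer-4 unit, sharing the stimulus image's envelope
#' width, wavelength and phase, centered on the unit's grid position with
#' the unit's map-preferred orientation. A unit's firing rate in response to
#' a (noisy) image `img` is the rectified filter response
#' \eqn{r_i = s\,[F_i \cdot \tilde I]_+}, where the normalization `s`
#' (`rate_scale`, in Hz per unit filter response) is set by
#' [calibrate_filterbank()] so that the grand-mean ON-interval rate is a
#' target value (10 Hz by default).
#'
#' @param map An [make_orientation_map()] result; one filter is built per
#'   map grid point.
#' @param pixels,sigma,lambda,phase Image/filter parameters (see
#'   [gabor_patch()]).
#' @return An object of class `filter_bank`: `F` (units x pixels^2 matrix),
#'   `rate_scale` (initially 1), parameters.
#' @export
make_filterbank <- function(map, pixels = 25, sigma = 0.2, lambda = 0.6,
                            phase = 0) {
  stopifnot(inherits(map, "orientation_map"))
  n <- length(map$orientation)
  FF <- matrix(0, n, pixels^2)
  for (i in seq_len(n)) {
    FF[i, ] <- gabor_patch(map$orientation[i], pixels = pixels,
                           sigma = sigma, lambda = lambda, phase = phase,
                           center = c(map$x[i], map$y[i]))
  }
  structure(
    list(F = FF, rate_scale = 1, pixels = pixels, sigma = sigma,
         lambda = lambda, phase = phase, map = map),
    class = "filter_bank"
  )
}

#' @export
print.filter_bank <- function(x, ...) {
  cat(sprintf("filter_bank: %d Gabor filters on %dx%d pixels, rate_scale %.4g\n",
              nrow(x$F), x$pixels, x$pixels, x$rate_scale))
  invisible(x)
}

#' Calibrate the filter-bank rate normalization
#'
#' Chooses `rate_scale` so that the mean rectified filter response —
#' averaged over units, a uniform grid of stimulus orientations, and the
#' stationary distribution of the OU pixel noise — equals `target_hz`.
#'
#' @param fb A [make_filterbank()] object.
#' @param target_hz Target grand-mean ON rate in Hz (default 10).
#' @param n_thetas Orientations in the calibration grid (default 50).
#' @param noise_draws Stationary noise draws per orientation (default 40).
#' @param tau_n,sigma_n OU parameters (defaults 40 ms, 3.5).
#' @param seed Seed for the calibration draws.
#' @return The filter bank with `rate_scale` set.
#' @export
calibrate_filterbank <- function(fb, target_hz = 10, n_thetas = 50,
                                 noise_draws = 40, tau_n = 40,
                                 sigma_n = 3.5, seed = 1) {
  stopifnot(inherits(fb, "filter_bank"))
  thetas <- (seq_len(n_thetas) - 1) / n_thetas
  npx <- fb$pixels^2
  sd0 <- ou_stationary_sd(tau_n, sigma_n)
  tot <- 0
  with_seed(seed, {
    for (t0 in thetas) {
      img <- gabor_patch(t0, fb$pixels, fb$sigma, fb$lambda, fb$phase)
      base <- drop(fb$F %*% img)
      # filter response to noise is Gaussian; sample it directly
      eta <- matrix(stats::rnorm(npx * noise_draws, 0, sd0),
                    npx, noise_draws)
      resp <- pmax(base + fb$F %*% eta, 0)
      tot <- tot + mean(resp)
    }
  })
  m <- tot / n_thetas
  if (m <= 0) stop("calibration failed: zero mean rectified response")
  fb$rate_scale <- target_hz / m
  fb
}

#' Default ON/OFF stimulus protocol
#'
#' Alternating OFF (blank, layer-4 units fire as independent Poisson at
#' `r_x` Hz) and ON (stimulus present) intervals.
#'
#' @param off_ms,on_ms Interval durations (defaults 300 and 200 ms).
#' @param total_ms Total simulated time (default 20000 ms).
#' @param r_x OFF-interval layer-4 rate in Hz (default 5).
#' @param rate_dt_ms Time step for updating the OU noise and the layer-4
#'   rates (default 2 ms; must be at most `tau_n / 10`).
#' @return A list of class `stim_protocol`.
#' @export
stim_protocol <- function(off_ms = 300, on_ms = 200, total_ms = 20000,
                          r_x = 5, rate_dt_ms = 2) {
  n_cycles <- floor(total_ms / (off_ms + on_ms))
  structure(list(off_ms = off_ms, on_ms = on_ms, total_ms = total_ms,
                 r_x = r_x, rate_dt_ms = rate_dt_ms, n_cycles = n_cycles),
            class = "stim_protocol")
}

#' Layer-4 rate time series for a stimulus sequence
#'
#' Advances the OU pixel noise with the exact update at `rate_dt_ms`
#' resolution through alternating OFF/ON intervals and evaluates the
#' rectified, calibrated filter responses during ON intervals; OFF
#' intervals have constant rate `r_x`. Used both by the pure Poisson
#' front-end simulator and as input drive to the recurrent network.
#'
#' @param fb Calibrated [make_filterbank()] object.
#' @param protocol A [stim_protocol()].
#' @param orientation_sequence One orientation per ON interval (length >=
#'   `protocol$n_cycles`; recycled if length 1).
#' @param tau_n,sigma_n OU parameters.
#' @param seed Integer seed.
#' @param contrast Image contrast multiplier (default 1; 0 gives a blank
#'   image so ON responses are rectified noise only).
#' @return List: `rates` (units x n_bins matrix, Hz), `bin_ms`,
#'   `on_bins` (logical per bin), `cycle` (ON-interval index per bin, 0 in
#'   OFF), `orientations` (per ON interval).
#' @export
l4_rate_series <- function(fb, protocol, orientation_sequence, tau_n = 40,
                           sigma_n = 3.5, seed = 1, contrast = 1) {
  stopifnot(inherits(fb, "filter_bank"), inherits(protocol, "stim_protocol"))
  if (protocol$rate_dt_ms > tau_n / 10) {
    stop("'rate_dt_ms' must be at most tau_n / 10")
  }
  ors <- rep_len(orientation_sequence, protocol$n_cycles)
  dt <- protocol$rate_dt_ms
  cyc_ms <- protocol$off_ms + protocol$on_ms
  nbins <- floor(protocol$n_cycles * cyc_ms / dt)
  t_ms <- (seq_len(nbins) - 1) * dt
  phase_ms <- t_ms %% cyc_ms
  on <- phase_ms >= protocol$off_ms
  cyc <- ifelse(on, floor(t_ms / cyc_ms) + 1, 0)
  n <- nrow(fb$F)
  rates <- matrix(protocol$r_x, n, nbins)
  with_seed(seed, {
    eta <- ou_init(fb$pixels^2, tau_n, sigma_n)
    img_cache <- NULL; cur_cycle <- -1L
    for (b in seq_len(nbins)) {
      eta <- ou_step(eta, dt, tau_n, sigma_n)
      if (on[b]) {
        if (cyc[b] != cur_cycle) {
          cur_cycle <- cyc[b]
          img_cache <- contrast *
            gabor_patch(ors[cur_cycle], fb$pixels, fb$sigma, fb$lambda,
                        fb$phase)
        }
        rates[, b] <- fb$rate_scale * pmax(fb$F %*% (img_cache + eta), 0)
      }
    }
  })
  list(rates = rates, bin_ms = dt, on_bins = on, cycle = cyc,
       orientations = ors)
}

#' Simulate the Poisson layer-4 front end
#'
#' Generates inhomogeneous-Poisson spike counts for the layer-4 units:
#' during ON intervals at the rectified, calibrated Gabor-filter rate
#' (including OU image noise), during OFF intervals at the constant rate
#' `protocol$r_x`. Returns per-interval spike counts; the rates underlying
#' them are returned for diagnostics.
#'
#' @inheritParams l4_rate_series
#' @param drop_first Drop the first ON interval's counts (default TRUE,
#'   matching the convention that the first count of each simulation is
#'   excluded).
#' @return List: `on_counts` ([trial_matrix()], one row per retained ON
#'   interval, `theta` = presented orientation), `off_counts` (matrix, one
#'   row per OFF interval), `on_rate_hz`, `off_rate_hz` (grand means),
#'   `series` (the rate time series).
#' @export
simulate_l4 <- function(fb, protocol, orientation_sequence, seed = 1,
                        tau_n = 40, sigma_n = 3.5, contrast = 1,
                        drop_first = TRUE) {
  ser <- l4_rate_series(fb, protocol, orientation_sequence, tau_n, sigma_n,
                        seed = derive_seed(seed, 1), contrast = contrast)
  n <- nrow(ser$rates)
  dt <- ser$bin_ms
  with_seed(derive_seed(seed, 2), {
    on_counts <- matrix(0, protocol$n_cycles, n)
    for (k in seq_len(protocol$n_cycles)) {
      lam <- rowSums(ser$rates[, ser$cycle == k, drop = FALSE]) * dt / 1000
      on_counts[k, ] <- stats::rpois(n, lam)
    }
    n_off_bins <- sum(!ser$on_bins)
    off_counts <- matrix(
      stats::rpois(protocol$n_cycles * n,
                   protocol$r_x * protocol$off_ms / 1000),
      protocol$n_cycles, n)
    keep <- if (drop_first) -1L else seq_len(protocol$n_cycles)
    on_kept <- on_counts[keep, , drop = FALSE]
    ors_kept <- ser$orientations[keep]
    list(
      on_counts = trial_matrix(on_kept, theta = ors_kept,
                               window = sprintf("ON %dms", protocol$on_ms)),
      off_counts = off_counts,
      on_rate_hz = mean(on_kept) / (protocol$on_ms / 1000),
      off_rate_hz = mean(off_counts) / (protocol$off_ms / 1000),
      series = ser)
  })
}
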