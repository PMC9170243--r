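#' Attention parameterization of the circuit model
#'
#' Attention is modeled as a joint change of two V4 parameters, linearly
#' interpolated between the unattended and attended endpoints: the
#' feedforward projection strength from V1 (L2/3) to V4,
#' \eqn{\gamma} (with E and I targets receiving \eqn{\gamma [1, 0.4]}),
#' varying from 20 to 23 mV, and the depolarizing current to V4 inhibitory
#' neurons \eqn{\mu_i}, varying from 0 to 0.5 mV/ms.
#'
#' @param level Attentional modulation scale in `[0, 1]`.
#' @return List with `gamma` (mV) and `mu_i` (mV/ms).
#' @examples
#' attention_params(0)   # gamma 20, mu_i 0
#' attention_params(1)   # gamma 23, mu_i 0.5
#' @export
attention_params <- function(level) {
  if (!is.finite(level) || level < 0 || level > 1) {
    stop("'level' must lie in [0, 1]")
  }
  list(gamma = 20 + 3 * level, mu_i = 0.5 * level)
}

#' Configuration of the three-layer spiking circuit model
#'
#' Parameterizes the scaled spiking network: a Gabor-filtered Poisson
#' layer-4 (L4) front end, a recurrent excitatory/inhibitory V1 (L2/3)
#' layer, and a recurrent E/I V4 layer, all on periodic grids over the unit
#' square. Connection probability decays with wrapped distance (Gaussian
#' width per projection); each postsynaptic neuron draws a fixed in-degree.
#' The printed model constants — feedforward width 0.05 for V1 to V4,
#' feedforward strengths gamma [1, 0.4], the attention ranges of gamma and
#' mu_i, OFF-interval input rate 5 Hz, integration step 0.01 ms, and the
#' 300/200 ms OFF/ON protocol — are defaults here; the remaining
#' single-neuron and coupling constants follow the companion
#' excitatory-inhibitory model family and are adopted, documented defaults,
#' all overridable. Default layer sizes are scaled far below the original
#' cluster runs; paper-scale values remain reachable via the arguments.
#'
#' @param l4_grid,v1e_grid,v1i_grid,v4e_grid,v4i_grid Grid side per
#'   population (sizes are the squares).
#' @param alpha_ffwd_l4 Feedforward projection width L4 -> V1 (default
#'   0.05).
#' @param alpha_ffwd_v4 Feedforward projection width V1 -> V4 (default
#'   0.05).
#' @param alpha_rec Recurrent projection width within layers (default 0.1).
#' @param k_ffwd In-degree of feedforward projections (default 50).
#' @param k_from_e,k_from_i Recurrent in-degrees from E and I populations
#'   (defaults 40 and 10).
#' @param j_ee,j_ie,j_ei,j_ii Recurrent synaptic increments (mV/ms added to
#'   the target's synaptic state per spike; `j_ei`, `j_ii` negative).
#' @param gamma_l4 Feedforward strength of the L4 -> V1 projection (mV;
#'   fixed across attention conditions, default 20).
#' @param ffwd_i_factor I-target feedforward strength as a fraction of the
#'   E-target strength (default 0.4).
#' @param ffwd_scale Conversion from the feedforward strength gamma to the
#'   per-spike synaptic increment: increment = gamma * ffwd_scale /
#'   k_ffwd.
#' @param tau_e,tau_i Synaptic decay constants (ms).
#' @param taum_e,taum_i,EL,VT,Vth,Vre,DeltaT_e,DeltaT_i,tauref_e,tauref_i
#'   EIF single-neuron constants (companion-model style defaults).
#' @param v_floor Reflecting lower bound on the membrane potential (mV,
#'   default -100): strong compound inhibition in a small network can
#'   otherwise drive unphysiological excursions.
#' @param bg_sigma,bg_tau Amplitude (mV/ms, stationary SD) and timescale
#'   (ms) of an optional slow Ornstein-Uhlenbeck current common to all V4
#'   neurons (default amplitude 0: disabled). Available for experiments
#'   probing the network's response to an externally imposed common
#'   drive; note that a balanced network largely cancels a common input
#'   delivered to E and I alike.
#' @param bg_i_factor Coupling of the shared background current to V4
#'   inhibitory neurons relative to excitatory ones (default 1).
#' @param dt Integration step in ms (default 0.01; scaled-down analyses may
#'   raise it).
#' @param protocol A [stim_protocol()] (OFF/ON timing, total length, OFF
#'   rate).
#' @param rate_ceiling_hz Healthy-regime ceiling; exceeding mean rates are
#'   reported with a warning, never clipped (default 200).
#' @return An object of class `network_config`.
#' @export
network_config <- function(l4_grid = 24,
                           v1e_grid = 24, v1i_grid = 12,
                           v4e_grid = 24, v4i_grid = 12,
                           alpha_ffwd_l4 = 0.05,
                           alpha_ffwd_v4 = 0.05,
                           alpha_rec = 0.1,
                           k_ffwd = 50,
                           k_from_e = 40, k_from_i = 10,
                           j_ee = 0.6, j_ie = 2.4,
                           j_ei = -6, j_ii = -6,
                           gamma_l4 = 20,
                           ffwd_i_factor = 0.4,
                           ffwd_scale = 10,
                           v_floor = -100,
                           bg_sigma = 0,
                           bg_tau = 150,
                           bg_i_factor = 1,
                           tau_e = 5, tau_i = 8,
                           taum_e = 15, taum_i = 10,
                           EL = -60, VT = -50, Vth = -10, Vre = -65,
                           DeltaT_e = 2, DeltaT_i = 0.5,
                           tauref_e = 1.5, tauref_i = 0.5,
                           dt = 0.01,
                           protocol = stim_protocol(),
                           rate_ceiling_hz = 200) {
  if (dt <= 0) stop("'dt' must be positive")
  stopifnot(alpha_ffwd_l4 > 0, alpha_ffwd_v4 > 0, alpha_rec > 0)
  cfg <- as.list(environment())
  class(cfg) <- "network_config"
  cfg
}

#' @export
print.network_config <- function(x, ...) {
  cat(sprintf(
    "network_config: L4 %d, V1 %dE/%dI, V4 %dE/%dI neurons; dt %g ms\n",
    x$l4_grid^2, x$v1e_grid^2, x$v1i_grid^2, x$v4e_grid^2, x$v4i_grid^2,
    x$dt))
  cat(sprintf("  protocol: OFF %g / ON %g ms, total %g ms, r_x %g Hz\n",
              x$protocol$off_ms, x$protocol$on_ms, x$protocol$total_ms,
              x$protocol$r_x))
  invisible(x)
}

# sample distance-dependent in-degree connectivity between two gridded
# populations (wrapped-Gaussian profile on the periodic unit square);
# returns a list of presynaptic index vectors, one per postsynaptic neuron
sample_projection <- function(pre_grid, post_grid, width, k_in) {
  pre <- grid_positions(pre_grid)
  post <- grid_positions(post_grid)
  n_pre <- nrow(pre)
  k_in <- min(k_in, n_pre)
  lapply(seq_len(nrow(post)), function(j) {
    d <- wrapped_sq_dist(pre$x - post$x[j], pre$y - post$y[j])
    p <- exp(-d^2 / (2 * width^2))
    sample.int(n_pre, k_in, prob = p)
  })
}

#' Build the fixed connectivity of a network configuration
#'
#' Draws every projection's distance-dependent random connections once,
#' given a seed; the same `network_connectivity` object is reused across
#' simulations of that configuration (connectivity fixed per condition,
#' initial membrane potentials randomized per simulation).
#'
#' @param config A [network_config()].
#' @param seed Integer seed for the connectivity draw.
#' @return An object of class `network_connectivity` holding CSR edge
#'   arrays (without the attention-dependent V1->V4 weights, which are
#'   filled in at simulation time) and population index bookkeeping.
#' @export
build_connectivity <- function(config, seed = 1) {
  stopifnot(inherits(config, "network_config"))
  n_l4 <- config$l4_grid^2
  n_v1e <- config$v1e_grid^2; n_v1i <- config$v1i_grid^2
  n_v4e <- config$v4e_grid^2; n_v4i <- config$v4i_grid^2
  n_eif <- n_v1e + n_v1i + n_v4e + n_v4i
  # global indices: pre = L4, then EIF populations; targets are EIF-local
  pop <- list(
    l4 = seq_len(n_l4),
    v1e = n_l4 + seq_len(n_v1e),
    v1i = n_l4 + n_v1e + seq_len(n_v1i),
    v4e = n_l4 + n_v1e + n_v1i + seq_len(n_v4e),
    v4i = n_l4 + n_v1e + n_v1i + n_v4e + seq_len(n_v4i))
  tgt0 <- list(v1e = 0L, v1i = n_v1e, v4e = n_v1e + n_v1i,
               v4i = n_v1e + n_v1i + n_v4e)
  grids <- list(l4 = config$l4_grid, v1e = config$v1e_grid,
                v1i = config$v1i_grid, v4e = config$v4e_grid,
                v4i = config$v4i_grid)
  with_seed(seed, {
    # projections: (pre pop, post pop, width, k_in, weight tag)
    proj <- list(
      list("l4", "v1e", config$alpha_ffwd_l4, config$k_ffwd, "ffwd_l4_e"),
      list("l4", "v1i", config$alpha_ffwd_l4, config$k_ffwd, "ffwd_l4_i"),
      list("v1e", "v1e", config$alpha_rec, config$k_from_e, "ee"),
      list("v1e", "v1i", config$alpha_rec, config$k_from_e, "ie"),
      list("v1i", "v1e", config$alpha_rec, config$k_from_i, "ei"),
      list("v1i", "v1i", config$alpha_rec, config$k_from_i, "ii"),
      list("v1e", "v4e", config$alpha_ffwd_v4, config$k_ffwd, "ffwd_v4_e"),
      list("v1e", "v4i", config$alpha_ffwd_v4, config$k_ffwd, "ffwd_v4_i"),
      list("v4e", "v4e", config$alpha_rec, config$k_from_e, "ee"),
      list("v4e", "v4i", config$alpha_rec, config$k_from_e, "ie"),
      list("v4i", "v4e", config$alpha_rec, config$k_from_i, "ei"),
      list("v4i", "v4i", config$alpha_rec, config$k_from_i, "ii"))
    acc_pre <- list(); acc_tgt <- list(); acc_tag <- list()
    for (pr in proj) {
      conns <- sample_projection(grids[[pr[[1]]]], grids[[pr[[2]]]],
                                 pr[[3]], pr[[4]])
      k_len <- lengths(conns)
      acc_pre[[length(acc_pre) + 1L]] <- pop[[pr[[1]]]][unlist(conns)]
      acc_tgt[[length(acc_tgt) + 1L]] <-
        rep(tgt0[[pr[[2]]]] + seq_along(conns) - 1L, k_len)
      acc_tag[[length(acc_tag) + 1L]] <- rep(pr[[5]], sum(k_len))
    }
    pre_of_edge <- unlist(acc_pre)
    tgt_of_edge <- unlist(acc_tgt)
    tag_of_edge <- unlist(acc_tag)
  })
  if (length(pre_of_edge) == 0) warning("network has no connections")
  ord <- order(pre_of_edge)
  pre_of_edge <- pre_of_edge[ord]
  tgt_of_edge <- tgt_of_edge[ord]
  tag_of_edge <- tag_of_edge[ord]
  n_pre_total <- n_l4 + n_eif
  ptr <- cumsum(c(0L, tabulate(pre_of_edge, n_pre_total)))
  structure(
    list(edge_ptr = as.integer(ptr), edge_tgt = as.integer(tgt_of_edge),
         edge_tag = tag_of_edge, n_l4 = n_l4, n_eif = n_eif,
         sizes = c(v1e = n_v1e, v1i = n_v1i, v4e = n_v4e, v4i = n_v4i),
         seed = seed),
    class = "network_connectivity"
  )
}

# per-edge weights for a given attention level
edge_weights <- function(config, conn, gamma, mu_unused = NULL) {
  k <- config$k_ffwd
  wmap <- c(
    ffwd_l4_e = config$gamma_l4 * config$ffwd_scale / k,
    ffwd_l4_i = config$gamma_l4 * config$ffwd_i_factor *
      config$ffwd_scale / k,
    ffwd_v4_e = gamma * config$ffwd_scale / k,
    ffwd_v4_i = gamma * config$ffwd_i_factor * config$ffwd_scale / k,
    ee = config$j_ee, ie = config$j_ie, ei = config$j_ei, ii = config$j_ii)
  unname(wmap[conn$edge_tag])
}

#' Simulate the spiking circuit model
#'
#' Runs one full simulation of the three-layer model: the L4 rate series is
#' generated from the orientation map's Gabor filter bank under the OFF/ON
#' protocol (OU-noisy images during ON, blank OFF intervals at the OFF
#' rate), L4 spikes are drawn as inhomogeneous Poisson processes, and the
#' recurrent V1 and V4 E/I populations are integrated as EIF neurons by
#' forward Euler at `config$dt`. Attention sets the V1-to-V4 feedforward
#' strength gamma and the V4 inhibitory depolarization mu_i via
#' [attention_params()]. ON-interval spike counts are returned with the
#' first count of the simulation dropped.
#'
#' @param config A [network_config()].
#' @param fb A calibrated [make_filterbank()] built on the L4 orientation
#'   map (its map defines the L4 grid; `nrow(fb$F)` must equal
#'   `config$l4_grid^2`).
#' @param conn A [build_connectivity()] object for `config` (connectivity
#'   fixed across simulations of a condition).
#' @param attention_level Attentional modulation scale in `[0, 1]`.
#' @param orientation_sequence One orientation per ON interval (recycled).
#' @param seed Integer seed (L4 noise, L4/EIF spiking, membrane init).
#' @return A list of class `network_sim`: `v4e`, `v1e` ([trial_matrix()]
#'   of ON-interval spike counts per excitatory neuron, first interval
#'   dropped), `counts_all` (all EIF neurons), `mean_rates_hz` (per
#'   population), `v_range`, `attention`, `gamma`, `mu_i`.
#' @export
build_and_simulate <- function(config, fb, conn, attention_level,
                               orientation_sequence, seed = 1) {
  stopifnot(inherits(config, "network_config"),
            inherits(fb, "filter_bank"),
            inherits(conn, "network_connectivity"))
  if (nrow(fb$F) != conn$n_l4) {
    stop("filter bank size does not match the configured L4 grid")
  }
  ap <- attention_params(attention_level)
  ew <- edge_weights(config, conn, ap$gamma)
  ser <- l4_rate_series(fb, config$protocol, orientation_sequence,
                        seed = derive_seed(seed, 11))
  sz <- conn$sizes
  n_eif <- conn$n_eif
  is_i <- rep(c(FALSE, TRUE, FALSE, TRUE), sz)
  is_v4i <- rep(c(FALSE, FALSE, FALSE, TRUE), sz)
  par_e <- function(e, i) ifelse(is_i, i, e)
  mu <- ifelse(is_v4i, ap$mu_i, 0)
  n_bins <- length(ser$cycle)
  bg_series <- if (config$bg_sigma > 0) {
    with_seed(derive_seed(seed, 13), {
      bg <- numeric(n_bins)
      bg[1] <- stats::rnorm(1, 0, config$bg_sigma)
      a <- exp(-ser$bin_ms / config$bg_tau)
      sd_inc <- config$bg_sigma * sqrt(1 - a^2)
      for (b in 2:n_bins) bg[b] <- a * bg[b - 1] + stats::rnorm(1, 0, sd_inc)
      bg
    })
  } else {
    numeric(n_bins)
  }
  bg_weight <- rep(c(0, 0, 1, config$bg_i_factor), sz)
  res <- with_seed(derive_seed(seed, 12), {
    V0 <- stats::runif(n_eif, config$Vre, config$VT)
    .eif_net_sim(ser$rates, ser$bin_ms, config$dt,
                 as.integer(ser$cycle[seq(1, length(ser$cycle))]),
                 config$protocol$n_cycles,
                 conn$edge_ptr, conn$edge_tgt, ew,
                 par_e(config$taum_e, config$taum_i),
                 rep(config$EL, n_eif), rep(config$VT, n_eif),
                 rep(config$Vth, n_eif), rep(config$Vre, n_eif),
                 par_e(config$DeltaT_e, config$DeltaT_i),
                 par_e(config$tauref_e, config$tauref_i),
                 mu, config$tau_e, config$tau_i, V0, config$v_floor,
                 bg_series, bg_weight)
  })
  sim_s <- res$sim_ms / 1000
  mean_rates <- tapply(res$total_spikes / sim_s,
                       rep(names(sz), sz), mean)
  ceiling_hz <- config$rate_ceiling_hz
  hot <- sum(res$total_spikes / sim_s > ceiling_hz)
  if (hot > 0) {
    warning(sprintf("%d neurons exceed the %g Hz rate ceiling", hot,
                    ceiling_hz))
  }
  counts <- res$counts[-1L, , drop = FALSE]  # drop first ON count
  thetas <- ser$orientations[-1L]
  att_lab <- sprintf("att%.3g", attention_level)
  idx <- split(seq_len(n_eif), rep(names(sz), sz))
  mk <- function(cols) {
    trial_matrix(counts[, cols, drop = FALSE], theta = thetas,
                 attention = rep(att_lab, nrow(counts)),
                 window = sprintf("ON %gms", config$protocol$on_ms))
  }
  structure(
    list(v4e = mk(idx$v4e), v1e = mk(idx$v1e), counts_all = counts,
         mean_rates_hz = mean_rates,
         v_range = c(res$v_min, res$v_max),
         attention = attention_level, gamma = ap$gamma, mu_i = ap$mu_i),
    class = "network_sim"
  )
}

#' @export
print.network_sim <- function(x, ...) {
  cat(sprintf(
    "network_sim: attention %.2f (gamma %.3g mV, mu_i %.3g mV/ms)\n",
    x$attention, x$gamma, x$mu_i))
  cat("  mean rates (Hz): ",
      paste(sprintf("%s %.2f", names(x$mean_rates_hz), x$mean_rates_hz),
            collapse = ", "), "\n")
  cat(sprintf("  %d ON-interval counts retained (first dropped)\n",
              n_trials(x$v4e)))
  invisible(x)
}

#' Write the printed model parameters to JSON
#'
#' Emits a structured file mirroring the configuration field names,
#' recording every printed model parameter (column spacing 0.2, image
#' sigma 0.2, lambda 0.6, phase 0, tau_n 40 ms, sigma_n 3.5, feedforward
#' width 0.05, gamma range 20-23 mV, mu_i range 0-0.5 mV/ms, r_x 5 Hz,
#' dt 0.01 ms, OFF 300 / ON 200 ms, total 20000 ms).
#'
#' @param path Output path.
#' @param config A [network_config()]; defaults to `network_config()`.
#' @return `path`, invisibly.
#' @export
write_paper_config <- function(path, config = network_config()) {
  x <- unclass(config)
  x$protocol <- unclass(x$protocol)
  x$stimulus <- list(column_spacing = 0.2, pixels = 25, sigma = 0.2,
                     lambda = 0.6, phase = 0, tau_n = 40, sigma_n = 3.5)
  x$attention <- list(gamma_range = c(20, 23), mu_i_range = c(0, 0.5))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
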