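# shared fixture builders

# small heterogeneous ring population
tiny_ring <- function(n_units = 20, radial_sd = 0.2, private_sd = 1.5,
                      attention = 0, ...) {
  ring_params(n_units = n_units, radial_sd = radial_sd,
              private_sd = private_sd, attention = attention, ...)
}

# uniform orientation grid
theta_grid <- function(n) (seq_len(n) - 1) / n

# two-condition Gaussian fixture whose analytic Fisher information is
# f' S^-1 f' for fprime, with the condition means dtheta*fprime apart so
# that (f+ - f-)/dtheta = fprime under the printed estimator convention
gaussian_pair <- function(fprime, covariance, ntr, dtheta, seed) {
  gen_gaussian_population(dtheta / 2 * fprime, -dtheta / 2 * fprime,
                          covariance, ntr, seed = seed)
}

# a fast scaled-down session configuration
tiny_session_config <- function(n_units = 15, radial_sd = 0.2,
                                private_sd = 2, cued_per_amount = 8,
                                ...) {
  session_config(
    ring = ring_params(n_units = n_units, amplitude = 15,
                       radial_sd = radial_sd, private_sd = private_sd),
    cued_per_amount = cued_per_amount,
    uncued_median = cued_per_amount, uncued_largest = 2, ...)
}
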