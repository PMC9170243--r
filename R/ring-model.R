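#' Parametric ring-model population
#'
#' A parametric surrogate for an orientation-tuned population whose shared
#' ("noise") variability is dominated by a single multiplicative gain mode.
#' Each unit has a wrapped-Gaussian (circular bump) tuning curve
#' \deqn{f_j(\theta) = b + A \exp(-d(\theta, \phi_j)^2 / (2 w^2)),}
#' where \eqn{d} is ring distance and \eqn{\phi_j} the unit's preferred
#' orientation. On each trial the whole population is scaled by a common gain
#' \eqn{(1 + g_t)} with \eqn{g_t \sim N(0, \sigma_r^2 (1 - c\,a)^2)} — the
#' "radial" fluctuation, elongating trial clouds along the direction of the
#' mean response — plus independent private noise per unit. The attention
#' level \eqn{a \in [0,1]} shrinks the shared gain SD by the factor
#' \eqn{(1 - c a)}, emulating the attention-related quenching of
#' low-dimensional shared variability.
#'
#' @param n_units Number of units (>= 2).
#' @param preferred Preferred orientations in `[0,1)`; default uniform grid.
#' @param amplitude Tuning amplitude in spikes per counting window (scalar
#'   or per-unit vector; this and the next two are mean values when
#'   `heterogeneity > 0`).
#' @param width Tuning width (ring-distance scale; scalar or per-unit).
#' @param baseline Baseline response in spikes per counting window (scalar
#'   or per-unit).
#' @param radial_sd SD of the shared gain fluctuation at attention 0.
#' @param private_sd SD of per-unit private noise (spikes per window).
#' @param attention Attention level in `[0,1]`.
#' @param attention_gain Scaling constant `c`: the shared-gain SD is
#'   multiplied by `(1 - c * attention)`. Default 0.5, so full attention
#'   halves the shared fluctuation.
#' @param heterogeneity Relative log-normal dispersion of per-unit tuning
#'   parameters around their means (default 0.3), emulating the tuning
#'   diversity of recorded and network-simulated populations; 0 gives an
#'   exactly homogeneous ring. Heterogeneous tuning is what makes a single
#'   fixed ring readout unable to cancel shared gain fluctuations.
#' @param param_seed Seed for the per-unit parameter draw (part of the
#'   population's identity, separate from trial noise; default 1).
#' @return An object of class `ring_params`.
#' @export
ring_params <- function(n_units = 50,
                        preferred = NULL,
                        amplitude = 20,
                        width = 0.15,
                        baseline = 2,
                        radial_sd = 0.2,
                        private_sd = 1,
                        attention = 0,
                        attention_gain = 0.5,
                        heterogeneity = 0.3,
                        param_seed = 1) {
  if (is.null(preferred)) preferred <- (seq_len(n_units) - 1) / n_units
  for (nm in c("amplitude", "width", "baseline")) {
    v <- get(nm)
    if (!length(v) %in% c(1L, n_units)) {
      stop(sprintf("'%s' must be scalar or one value per unit", nm))
    }
  }
  if (heterogeneity < 0) stop("'heterogeneity' must be nonnegative")
  if (heterogeneity > 0) {
    dil <- with_seed(param_seed, {
      matrix(stats::rnorm(3 * n_units, 0, heterogeneity), n_units, 3)
    })
    amplitude <- amplitude * exp(dil[, 1])
    width <- width * exp(dil[, 2] * 0.5)   # widths vary less than gains
    baseline <- baseline * exp(dil[, 3])
  }
  p <- list(n_units = as.integer(n_units), preferred = preferred,
            amplitude = rep_len(amplitude, n_units),
            width = rep_len(width, n_units),
            baseline = rep_len(baseline, n_units),
            radial_sd = radial_sd, private_sd = private_sd,
            attention = attention, attention_gain = attention_gain,
            heterogeneity = heterogeneity, param_seed = param_seed)
  for (nm in c("amplitude", "width", "baseline", "radial_sd", "private_sd",
               "attention", "attention_gain")) {
    stop_if_not_finite(p[[nm]], nm)
  }
  stop_if_not_finite(p$preferred, "preferred")
  if (p$n_units < 2) stop("'n_units' must be >= 2")
  if (length(p$preferred) != p$n_units) {
    stop("'preferred' must have one entry per unit")
  }
  if (p$radial_sd < 0 || p$private_sd < 0) {
    stop("noise SDs ('radial_sd', 'private_sd') must be nonnegative")
  }
  if (p$attention < 0 || p$attention > 1) {
    stop("'attention' must lie in [0, 1]")
  }
  if (any(p$width <= 0)) stop("'width' must be positive")
  gaps <- diff(c(sort(p$preferred %% 1), min(p$preferred %% 1) + 1))
  if (max(gaps) >= 0.5) {
    stop("'preferred' orientations must cover the ring (largest gap < 0.5)")
  }
  class(p) <- "ring_params"
  p
}

#' @export
print.ring_params <- function(x, ...) {
  cat(sprintf(
    "ring_params: %d units, mean amp %.3g, mean width %.3g, mean baseline %.3g\n",
    x$n_units, mean(x$amplitude), mean(x$width), mean(x$baseline)))
  cat(sprintf("  radial_sd %.3g (effective %.3g at attention %.2f, c = %.2f), private_sd %.3g\n",
              x$radial_sd, effective_radial_sd(x), x$attention,
              x$attention_gain, x$private_sd))
  invisible(x)
}

# shared-gain SD after attentional scaling
effective_radial_sd <- function(params) {
  params$radial_sd * (1 - params$attention_gain * params$attention)
}

#' Ring-model tuning curves and derivatives
#'
#' @param params A [ring_params()] object.
#' @param theta Orientation(s) in `[0,1)`.
#' @return `ring_tuning`: matrix (length(theta) x units) of mean responses.
#'   `ring_tuning_deriv`: matrix of derivatives d f / d theta.
#' @export
ring_tuning <- function(params, theta) {
  d <- outer(theta, params$preferred, ring_dist, signed = TRUE)
  b <- matrix(params$baseline, length(theta), params$n_units, byrow = TRUE)
  a <- matrix(params$amplitude, length(theta), params$n_units, byrow = TRUE)
  w2 <- matrix(params$width^2, length(theta), params$n_units, byrow = TRUE)
  b + a * exp(-d^2 / (2 * w2))
}

#' @rdname ring_tuning
#' @export
ring_tuning_deriv <- function(params, theta) {
  d <- outer(theta, params$preferred, ring_dist, signed = TRUE)
  a <- matrix(params$amplitude, length(theta), params$n_units, byrow = TRUE)
  w2 <- matrix(params$width^2, length(theta), params$n_units, byrow = TRUE)
  -a * (d / w2) * exp(-d^2 / (2 * w2))
}

#' Analytic trial covariance of the ring model at one orientation
#'
#' Before zero-truncation, counts are \eqn{r = f(\theta)(1+g) + \epsilon}
#' with \eqn{g \sim N(0, \sigma_g^2)} shared and \eqn{\epsilon} private, so
#' \deqn{\Sigma(\theta) = \sigma_g^2 f(\theta) f(\theta)^T +
#'   \sigma_p^2 I.}
#' Used as the exact-moment oracle for decoder tests; the small departure of
#' generated data from this matrix (zero-truncation) is quantified in tests.
#'
#' @inheritParams ring_tuning
#' @return Covariance matrix (units x units).
#' @export
ring_covariance <- function(params, theta) {
  f <- drop(ring_tuning(params, theta))
  sg <- effective_radial_sd(params)
  sg^2 * tcrossprod(f) + diag(params$private_sd^2, params$n_units)
}

#' Generate ring-model population responses
#'
#' Draws `trials_per_theta` trials at each requested orientation. Counts are
#' `f(theta) * (1 + g) + private noise`, truncated at zero; the gain `g` is
#' shared across units within a trial and has SD
#' `radial_sd * (1 - attention_gain * attention)`.
#'
#' @param params A [ring_params()] object.
#' @param thetas Orientations to present, each in `[0,1)`.
#' @param trials_per_theta Trials per orientation (>= 2).
#' @param seed Integer seed; output is reproducible given `(params, seed)`.
#' @param attention_label Label stored in the attention field; defaults to
#'   the numeric attention level.
#' @return A [trial_matrix()].
#' @examples
#' p <- ring_params(n_units = 20, radial_sd = 0.2)
#' tm <- gen_ring_responses(p, thetas = c(0.25, 0.5), trials_per_theta = 50,
#'                          seed = 1)
#' @export
gen_ring_responses <- function(params, thetas, trials_per_theta, seed,
                               attention_label = NULL) {
  stopifnot(inherits(params, "ring_params"))
  if (trials_per_theta < 2) stop("'trials_per_theta' must be >= 2")
  stop_if_not_finite(thetas, "thetas")
  if (is.null(attention_label)) {
    attention_label <- sprintf("att%.3g", params$attention)
  }
  f <- ring_tuning(params, thetas)             # n_theta x units
  sg <- effective_radial_sd(params)
  with_seed(seed, {
    counts <- matrix(0, length(thetas) * trials_per_theta, params$n_units)
    theta_lab <- rep(thetas, each = trials_per_theta)
    row <- 1L
    for (k in seq_along(thetas)) {
      g <- stats::rnorm(trials_per_theta, 0, sg)
      eps <- matrix(stats::rnorm(trials_per_theta * params$n_units,
                                 0, params$private_sd),
                    trials_per_theta, params$n_units)
      blk <- outer(1 + g, f[k, ]) + eps
      counts[row:(row + trials_per_theta - 1L), ] <- pmax(blk, 0)
      row <- row + trials_per_theta
    }
    trial_matrix(counts, theta = theta_lab,
                 attention = rep(attention_label, nrow(counts)))
  })
}

#' Expected mean pairwise noise correlation of the rank-1 gain model
#'
#' For units with means \eqn{f_j} and covariance
#' \eqn{\sigma_g^2 f f^T + \sigma_p^2 I}, the pairwise correlation is
#' \eqn{\sigma_g^2 f_j f_k / \sqrt{(\sigma_g^2 f_j^2 + \sigma_p^2)
#' (\sigma_g^2 f_k^2 + \sigma_p^2)}}. Returns its mean over distinct pairs —
#' the closed-form target used to validate the generator.
#'
#' @inheritParams ring_tuning
#' @param theta Single orientation.
#' @return Scalar expected mean pairwise correlation.
#' @export
ring_expected_rsc <- function(params, theta) {
  f <- drop(ring_tuning(params, theta))
  sg <- effective_radial_sd(params)
  v <- sg^2 * f^2 + params$private_sd^2
  cmat <- (sg^2 * tcrossprod(f)) / sqrt(tcrossprod(v))
  mean(cmat[upper.tri(cmat)])
}

#' Generate a two-condition Gaussian population
#'
#' Multivariate-normal spike "counts" with stated condition means and a
#' common covariance — the analytic oracle input for Fisher-information
#' estimators, where the true information is known in closed form.
#'
#' @param f_plus,f_minus Mean vectors of the two conditions.
#' @param covariance Common covariance matrix (symmetric positive definite).
#' @param trials_per_condition Trials drawn per condition.
#' @param seed Integer seed.
#' @param theta Optional length-2 vector of orientation labels for the two
#'   conditions (default `c(0.51, 0.49)`).
#' @return A [trial_matrix()] with the `+` condition first.
#' @export
gen_gaussian_population <- function(f_plus, f_minus, covariance,
                                    trials_per_condition, seed,
                                    theta = c(0.51, 0.49)) {
  covariance <- as.matrix(covariance)
  n <- length(f_plus)
  if (length(f_minus) != n || !all(dim(covariance) == n)) {
    stop("'f_plus', 'f_minus' and 'covariance' dimensions must agree")
  }
  if (max(abs(covariance - t(covariance))) > 1e-8 * max(1, abs(covariance))) {
    stop("'covariance' must be symmetric")
  }
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop(sprintf("'covariance' is not positive definite (smallest eigenvalue %.3g)",
                 min(ev)))
  }
  with_seed(seed, {
    xp <- MASS::mvrnorm(trials_per_condition, f_plus, covariance)
    xm <- MASS::mvrnorm(trials_per_condition, f_minus, covariance)
    trial_matrix(rbind(xp, xm),
                 theta = rep(theta, each = trials_per_condition))
  })
}

#' Shuffle trial order independently per unit within condition
#'
#' Destroys trial-by-trial correlations between units while preserving each
#' unit's marginal count distribution within every (orientation, attention)
#' condition cell — the trial-shuffle control used to isolate the
#' contribution of correlated variability to decoder performance.
#'
#' @param data A [trial_matrix()].
#' @param seed Integer seed.
#' @return A [trial_matrix()] with per-unit within-condition permuted counts.
#' @export
shuffle_trials <- function(data, seed) {
  stopifnot(inherits(data, "trial_matrix"))
  cells <- condition_cells(data)
  if (any(vapply(cells, length, 1L) < 2L)) {
    stop("each (orientation, attention) condition needs >= 2 trials to shuffle")
  }
  counts <- data$counts
  with_seed(seed, {
    for (idx in cells) {
      for (j in seq_len(ncol(counts))) {
        counts[idx, j] <- counts[sample(idx), j]
      }
    }
  })
  out <- data
  out$counts <- counts
  out
}
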