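#' Pairwise noise (spike-count) correlations
#'
#' The noise correlation of a unit pair is the Pearson correlation of their
#' trial-wise spike counts across repeated presentations of the same
#' stimulus. All trials in `data` must share one stimulus (and attention)
#' condition. Units with zero count variance are excluded and their pairs
#' dropped listwise; the exclusions are reported in the result.
#'
#' @param data A [trial_matrix()] restricted to a single condition (>= 3
#'   trials).
#' @return An object of class `correlation_summary`: `pairs` (two-column
#'   index matrix), `r_noise`, `mean_rsc`, `excluded_units`.
#' @export
noise_correlations <- function(data) {
  stopifnot(inherits(data, "trial_matrix"))
  if (n_trials(data) < 3) stop("need at least 3 trials")
  if (length(condition_cells(data)) != 1) {
    stop("all trials must share one (orientation, attention) condition")
  }
  v <- apply(data$counts, 2, stats::var)
  keep <- which(v > 0)
  excluded <- setdiff(seq_len(n_units(data)), keep)
  if (length(keep) < 2) stop("fewer than 2 units with nonzero variance")
  cm <- stats::cor(data$counts[, keep, drop = FALSE])
  ut <- which(upper.tri(cm), arr.ind = TRUE)
  pairs <- cbind(keep[ut[, 1]], keep[ut[, 2]])
  r <- cm[ut]
  structure(
    list(pairs = pairs, r_noise = r, mean_rsc = mean(r),
         r_signal = NULL, noise_vs_signal_r = NULL,
         excluded_units = excluded),
    class = "correlation_summary"
  )
}

#' @export
print.correlation_summary <- function(x, ...) {
  cat(sprintf("correlation_summary: %d pairs, mean r_SC = %.4f\n",
              length(x$r_noise), x$mean_rsc))
  if (!is.null(x$noise_vs_signal_r)) {
    cat(sprintf("  correlation of noise vs signal correlations: r = %.4f\n",
                x$noise_vs_signal_r))
  }
  if (length(x$excluded_units)) {
    cat(sprintf("  excluded units: %s\n",
                paste(x$excluded_units, collapse = ", ")))
  }
  invisible(x)
}

#' Relationship between noise and signal correlations
#'
#' Signal correlation of a pair is the Pearson correlation of the two units'
#' mean tuning across orientations; noise correlation is computed within
#' each (orientation, attention) condition cell and averaged across cells.
#' The summary statistic is the correlation, across unit pairs, between
#' noise and signal correlations — positive when shared variability aligns
#' with tuning similarity, and weakened by attention in both the recorded
#' and modeled populations this package emulates.
#'
#' @param data A [trial_matrix()] spanning at least 5 orientations, with >=
#'   3 trials per condition cell.
#' @return A `correlation_summary` with `r_noise` (cell-averaged), `r_signal`,
#'   `noise_vs_signal_r`, `mean_rsc`, and `excluded_units` (zero noise
#'   variance or flat tuning; their pairs are dropped listwise from both
#'   vectors).
#' @export
signal_vs_noise <- function(data) {
  stopifnot(inherits(data, "trial_matrix"))
  th <- sort(unique(data$theta))
  if (length(th) < 5) stop("need at least 5 orientations")
  cells <- condition_cells(data)
  if (any(vapply(cells, length, 1L) < 3L)) {
    stop("each condition cell needs >= 3 trials")
  }
  nu <- n_units(data)
  # tuning: mean response per orientation (pooled over attention)
  tuning <- t(vapply(th, function(t0)
    colMeans(data$counts[data$theta == t0, , drop = FALSE]),
    numeric(nu)))
  flat <- which(apply(tuning, 2, stats::var) == 0)
  # per-cell noise correlations, then average across cells per pair
  zero_var <- integer(0)
  csum <- matrix(0, nu, nu); cnum <- matrix(0, nu, nu)
  for (idx in cells) {
    x <- data$counts[idx, , drop = FALSE]
    v <- apply(x, 2, stats::var)
    ok <- which(v > 0)
    zero_var <- union(zero_var, which(v == 0))
    if (length(ok) >= 2) {
      cm <- stats::cor(x[, ok, drop = FALSE])
      csum[ok, ok] <- csum[ok, ok] + cm
      cnum[ok, ok] <- cnum[ok, ok] + 1
    }
  }
  excluded <- sort(union(flat, zero_var))
  keep <- setdiff(seq_len(nu), excluded)
  if (length(keep) < 2) stop("fewer than 2 usable units")
  noise_mat <- csum[keep, keep] / pmax(cnum[keep, keep], 1)
  sig_mat <- stats::cor(tuning[, keep, drop = FALSE])
  ut <- which(upper.tri(noise_mat), arr.ind = TRUE)
  pairs <- cbind(keep[ut[, 1]], keep[ut[, 2]])
  r_noise <- noise_mat[ut]
  r_signal <- sig_mat[ut]
  nvs <- if (stats::sd(r_noise) > 0 && stats::sd(r_signal) > 0) {
    stats::cor(r_noise, r_signal)
  } else NA_real_
  structure(
    list(pairs = pairs, r_noise = r_noise, mean_rsc = mean(r_noise),
         r_signal = r_signal, noise_vs_signal_r = nvs,
         excluded_units = excluded),
    class = "correlation_summary"
  )
}

#' Factor analysis of spike counts by expectation-maximization
#'
#' Fits the Gaussian factor model \eqn{x \sim N(\mu, L L^T + \Psi)} with
#' `m` latent factors and diagonal private variances \eqn{\Psi} by EM, and
#' reports the descending eigenvalues of the shared covariance \eqn{L L^T}
#' — the shared-variability eigenspectrum whose leading mode is quenched by
#' attention. Initialization is principal-component based; if the
#' log-likelihood fails to converge within `max_iter` iterations the fit is
#' retried from jittered starts.
#'
#' @param counts Numeric matrix (trials x units) from one condition, or a
#'   [trial_matrix()].
#' @param n_factors Number of latent factors `m` (default 5).
#' @param max_iter Maximum EM iterations per start (default 2000).
#' @param tol Convergence tolerance on the relative log-likelihood change
#'   (default 1e-8).
#' @param n_restarts Additional jittered restarts on non-convergence
#'   (default 10).
#' @param seed Seed for the restart jitter.
#' @return An object of class `factor_fit`: `mean`, `loadings` (units x m),
#'   `private_variances`, `shared_eigenvalues` (length m, descending,
#'   nonnegative), `loglik` (final), `loglik_trace`, `converged`,
#'   `n_factors`.
#' @export
factor_fit <- function(counts, n_factors = 5, max_iter = 2000, tol = 1e-8,
                       n_restarts = 10, seed = 1) {
  if (inherits(counts, "trial_matrix")) counts <- counts$counts
  counts <- as.matrix(counts)
  n <- nrow(counts); p <- ncol(counts)
  if (n_factors >= p) stop("'n_factors' must be smaller than the unit count")
  if (n <= p) {
    warning(sprintf(
      "only %d trials for %d units; factor fit may be unstable", n, p))
  }
  mu <- colMeans(counts)
  C <- crossprod(sweep(counts, 2, mu)) / n       # ML covariance
  psi_floor <- 1e-8 * mean(diag(C)) + 1e-12
  fit <- fa_em_run(C, n, n_factors, max_iter, tol, psi_floor, jitter = NULL)
  if (!fit$converged && n_restarts > 0) {
    with_seed(seed, {
      for (k in seq_len(n_restarts)) {
        cand <- fa_em_run(C, n, n_factors, max_iter, tol, psi_floor,
                          jitter = 0.1 * k)
        if (cand$converged) { fit <- cand; break }
        if (cand$loglik > fit$loglik) fit <- cand
      }
    })
  }
  LL <- tcrossprod(fit$L)
  ev <- eigen(LL, symmetric = TRUE, only.values = TRUE)$values
  lam <- sort(pmax(ev, 0), decreasing = TRUE)[seq_len(n_factors)]
  structure(
    list(mean = mu, loadings = fit$L, private_variances = fit$psi,
         shared_eigenvalues = lam, loglik = fit$loglik,
         loglik_trace = fit$trace, converged = fit$converged,
         n_factors = n_factors),
    class = "factor_fit"
  )
}

# one EM run on ML covariance C (n samples); returns L, psi, loglik, trace
fa_em_run <- function(C, n, m, max_iter, tol, psi_floor, jitter = NULL) {
  p <- ncol(C)
  es <- eigen(C, symmetric = TRUE)
  lam <- pmax(es$values, 0)
  resid <- if (p > m) mean(lam[(m + 1):p]) else 0
  L <- es$vectors[, seq_len(m), drop = FALSE] %*%
    diag(sqrt(pmax(lam[seq_len(m)] - resid, psi_floor)), m)
  if (!is.null(jitter)) {
    L <- L * (1 + jitter * matrix(stats::rnorm(p * m), p, m))
  }
  psi <- pmax(diag(C) - rowSums(L^2), psi_floor)
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # E-step via Woodbury: beta = G^-1 L' Psi^-1, G = I + L' Psi^-1 L
    LtPi <- t(L / psi)                       # m x p
    G <- diag(m) + LtPi %*% L
    beta <- solve(G, LtPi)                   # m x p
    bC <- beta %*% C                         # m x p
    Ezz <- solve(G) + bC %*% t(beta)         # m x m
    L <- t(solve(Ezz, bC))                   # p x m
    psi <- pmax(diag(C) - rowSums(L * t(bC)), psi_floor)
    # log-likelihood of N(mu, LL' + Psi); det/inverse via Woodbury
    LtPi2 <- t(L / psi)                      # m x p, = L' Psi^-1
    G2 <- diag(m) + LtPi2 %*% L
    logdet <- sum(log(psi)) + determinant(G2, logarithm = TRUE)$modulus
    # tr(Sigma^-1 C) with Sigma^-1 = Psi^-1 - Psi^-1 L G2^-1 L' Psi^-1
    Sinv_C_tr <- sum(diag(C) / psi) -
      sum((L / psi) * t(solve(G2, LtPi2 %*% C)))
    ll <- -n / 2 * (p * log(2 * pi) + as.numeric(logdet) + Sinv_C_tr)
    trace <- c(trace, ll)
    if (is.finite(ll_old) && ll < ll_old - 1e-6 * abs(ll_old)) {
      break  # likelihood decreased: numerical trouble, stop this run
    }
    if (is.finite(ll_old) &&
        abs(ll - ll_old) <= tol * abs(ll_old)) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  list(L = L, psi = psi, loglik = ll_old, trace = trace,
       converged = converged)
}

#' @export
print.factor_fit <- function(x, ...) {
  cat(sprintf("factor_fit: %d units, m = %d factors%s\n",
              length(x$mean), x$n_factors,
              if (x$converged) "" else " (NOT converged)"))
  cat("  shared eigenvalues: ",
      paste(sprintf("%.4g", x$shared_eigenvalues), collapse = ", "), "\n")
  invisible(x)
}

#' Write pairwise correlations as CSV
#'
#' One row per unit pair: `unit_i`, `unit_j`, `r_noise` and (when
#' available) `r_signal`.
#'
#' @param object A `correlation_summary`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pairs_csv <- function(object, path) {
  stopifnot(inherits(object, "correlation_summary"))
  df <- data.frame(unit_i = object$pairs[, 1], unit_j = object$pairs[, 2],
                   r_noise = object$r_noise)
  if (!is.null(object$r_signal)) df$r_signal <- object$r_signal
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a correlation summary or factor fit to JSON
#' @param object A `correlation_summary` or `factor_fit`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stats_json <- function(object, path) {
  x <- unclass(object)
  x$loglik_trace <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}
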