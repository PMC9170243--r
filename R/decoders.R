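#' Optimal specific (local linear) decoder
#'
#' The specific decoder estimates a stimulus near a reference orientation
#' \eqn{\theta_0} from a fine discrimination of \eqn{\theta_\pm = \theta_0
#' \pm d\theta}: \eqn{\hat\theta = \theta_0 + w^T (r - (f_+ + f_-)/2)} with
#' the minimum-mean-squared-error weights
#' \deqn{w = \Sigma^{-1} f' / (f'^T \Sigma^{-1} f').}
#' The derivative is approximated from the two condition means as
#' \eqn{f' = (f_+ - f_-) / (2 d\theta)}. With exact moments the decoder is
#' locally unbiased (\eqn{w^T f' = 1}) and its variance is
#' \eqn{1 / (f'^T \Sigma^{-1} f')}, the inverse linear Fisher information.
#'
#' @param f_plus,f_minus Mean response vectors at `theta0 + dtheta` and
#'   `theta0 - dtheta`.
#' @param covariance Noise covariance matrix (ideally positive definite; a
#'   singular matrix triggers a Moore-Penrose pseudo-inverse with a warning).
#' @param dtheta Half-offset of the discriminanda from `theta0` (> 0).
#'   Default 0.01.
#' @param theta0 Reference orientation. Default 0.5.
#' @return An object of class `specific_decoder` with elements `weights`,
#'   `theta0`, `dtheta`, `midpoint`, `info` (\eqn{f'^T \Sigma^{-1} f'}),
#'   `variance` (\eqn{w^T \Sigma w}) and `pseudo_inverse` flag.
#' @examples
#' w <- specific_weights(c(1.01, 1.01), c(0.99, 0.99),
#'                       diag(2), dtheta = 0.01)
#' coef(w)
#' @export
specific_weights <- function(f_plus, f_minus, covariance, dtheta = 0.01,
                             theta0 = 0.5) {
  if (dtheta <= 0) stop("'dtheta' must be positive")
  covariance <- as.matrix(covariance)
  n <- length(f_plus)
  stopifnot(length(f_minus) == n, all(dim(covariance) == n))
  fprime <- (f_plus - f_minus) / (2 * dtheta)
  pinv_used <- FALSE
  sol <- tryCatch(solve(covariance, fprime), error = function(e) NULL)
  if (is.null(sol) || !all(is.finite(sol))) {
    warning("singular covariance: falling back to Moore-Penrose pseudo-inverse")
    sol <- drop(MASS::ginv(covariance) %*% fprime)
    pinv_used <- TRUE
  }
  info <- drop(crossprod(fprime, sol))
  w <- sol / info
  structure(
    list(weights = drop(w), fprime = fprime, theta0 = theta0,
         dtheta = dtheta, midpoint = (f_plus + f_minus) / 2,
         info = info, variance = drop(crossprod(w, covariance %*% w)),
         pseudo_inverse = pinv_used),
    class = "specific_decoder"
  )
}

#' @export
print.specific_decoder <- function(x, ...) {
  cat(sprintf(
    "specific_decoder: %d units, theta0 = %.4g, dtheta = %.4g\n",
    length(x$weights), x$theta0, x$dtheta))
  cat(sprintf("  linear Fisher information f'S^-1f' = %.6g (variance %.6g)\n",
              x$info, x$variance))
  if (x$pseudo_inverse) cat("  note: pseudo-inverse used (singular covariance)\n")
  invisible(x)
}

#' @export
coef.specific_decoder <- function(object, ...) object$weights

#' @export
predict.specific_decoder <- function(object, newdata, ...) {
  counts <- if (inherits(newdata, "trial_matrix")) newdata$counts else
    as.matrix(newdata)
  drop(object$theta0 +
         (counts - matrix(object$midpoint, nrow(counts),
                          ncol(counts), byrow = TRUE)) %*% object$weights)
}

#' Bias-corrected linear Fisher information
#'
#' Estimates the linear Fisher information carried by a population about a
#' fine orientation change from empirical means and covariances of two
#' stimulus conditions \eqn{\theta_\pm}, applying the finite-trial
#' bias correction
#' \deqn{\hat I = \frac{(\hat f_+ - \hat f_-)^T}{d\theta}
#'   \left(\frac{\hat\Sigma_+ + \hat\Sigma_-}{2}\right)^{-1}
#'   \frac{\hat f_+ - \hat f_-}{d\theta}\,
#'   \frac{2 N_{tr} - N - 3}{2 N_{tr} - 2} \; - \; \frac{2N}{N_{tr} d\theta^2},}
#' where \eqn{N} is the number of units and \eqn{N_{tr}} the number of trials
#' per condition. The condition-mean difference is divided by `dtheta`
#' exactly as in this formula; fixtures and callers must use the matching
#' convention for how far apart the two conditions sit (see
#' [specific_weights()], where the means are `2*dtheta` apart). The
#' correction requires `2*Ntr > N + 3`; negative estimates are legitimate
#' near zero information and are returned as-is.
#'
#' @param data A [trial_matrix()] containing exactly two orientation
#'   conditions with equal trial counts.
#' @param dtheta Orientation offset entering the derivative quotient.
#' @param corrected If `FALSE`, return the naive plug-in quadratic form
#'   (no correction factor, no subtraction).
#' @return An object of class `fisher_estimate`: list with `value`, `naive`,
#'   `n_units`, `trials_per_condition`, `dtheta`, `corrected`.
#' @export
fisher_info_bc <- function(data, dtheta = 0.01, corrected = TRUE) {
  stopifnot(inherits(data, "trial_matrix"))
  th <- sort(unique(data$theta))
  if (length(th) != 2) {
    stop("'data' must contain exactly two orientation conditions")
  }
  im <- data$theta == th[1]; ip <- data$theta == th[2]
  ntr <- sum(ip)
  if (sum(im) != ntr) stop("both conditions must have equal trial counts")
  nu <- n_units(data)
  if (2 * ntr <= nu + 3) {
    stop(sprintf(paste0(
      "bias correction requires 2*Ntr > N + 3 (got Ntr = %d, N = %d); ",
      "the correction factor (2Ntr-N-3)/(2Ntr-2) is invalid otherwise"),
      ntr, nu))
  }
  xp <- data$counts[ip, , drop = FALSE]
  xm <- data$counts[im, , drop = FALSE]
  du <- (colMeans(xp) - colMeans(xm)) / dtheta
  S <- (stats::cov(xp) + stats::cov(xm)) / 2
  quad <- drop(crossprod(du, solve(S, du)))
  value <- if (corrected) {
    quad * (2 * ntr - nu - 3) / (2 * ntr - 2) - 2 * nu / (ntr * dtheta^2)
  } else {
    quad
  }
  structure(
    list(value = value, naive = quad, n_units = nu,
         trials_per_condition = ntr, dtheta = dtheta, corrected = corrected),
    class = "fisher_estimate"
  )
}

#' @export
print.fisher_estimate <- function(x, ...) {
  cat(sprintf("fisher_estimate: %s = %.6g  (N = %d units, Ntr = %d%s)\n",
              if (x$corrected) "bias-corrected I" else "naive I",
              x$value, x$n_units, x$trials_per_condition,
              if (is.null(x$dtheta)) "" else
                sprintf(", dtheta = %g", x$dtheta)))
  invisible(x)
}

#' Optimal general (complex linear) decoder
#'
#' A single complex weight vector `w`, fixed across all orientations, that
#' maps a population response to a point on the stimulus ring:
#' \eqn{\hat z = w^T r}, decoded orientation \eqn{\hat\theta =
#' \arg(\hat z)/2\pi}. The weights minimizing the mean squared error
#' \eqn{E = \langle |\hat z - z|^2 \rangle_{\theta, r}} with
#' \eqn{z = e^{i 2\pi\theta}} are
#' \deqn{w = \langle \Sigma(\theta) + f f^T \rangle_\theta^{-1}
#'   \langle f e^{i 2\pi\theta} \rangle_\theta,}
#' with attained error \eqn{E = 1 - \langle f e^{i2\pi\theta}\rangle^{*}
#' \langle \Sigma + ff^T\rangle^{-1} \langle f e^{i2\pi\theta}\rangle}.
#' Empirical per-orientation moments use the maximum-likelihood (divide by
#' `n`) covariance so that, with equal trials per orientation, the
#' moment-based solution coincides exactly with the least-squares regression
#' of \eqn{z} on the raw responses.
#'
#' @param data A [trial_matrix()] spanning the ring (orientations
#'   approximately uniform on `[0,1)`), or `NULL` when `moments` is given.
#' @param moments Optional list with elements `M` (the averaged second-moment
#'   matrix \eqn{\langle \Sigma + ff^T \rangle}) and `b`
#'   (\eqn{\langle f e^{i2\pi\theta} \rangle}) for closed-form use.
#' @param max_ridge_cond Condition threshold: if the reciprocal condition
#'   number of `M` falls below this, a ridge `10^k * mean(diag(M))` with the
#'   smallest integer `k` restoring it is added and recorded.
#' @return An object of class `general_decoder`: `weights` (complex),
#'   `expected_mse`, `ridge` (0 if none), `n_units`, `thetas`.
#' @examples
#' p <- ring_params(n_units = 12, radial_sd = 0, private_sd = 0.5)
#' tm <- gen_ring_responses(p, thetas = (0:19) / 20, trials_per_theta = 30,
#'                          seed = 2)
#' g <- general_weights(tm)
#' @export
general_weights <- function(data = NULL, moments = NULL,
                            max_ridge_cond = 1e-10) {
  if (is.null(moments)) {
    stopifnot(inherits(data, "trial_matrix"))
    th <- unique(data$theta)
    if (length(th) < 3) stop("need responses spanning >= 3 orientations")
    nu <- n_units(data)
    M <- matrix(0, nu, nu)
    b <- complex(real = rep(0, nu))
    for (t0 in th) {
      x <- data$counts[data$theta == t0, , drop = FALSE]
      M <- M + crossprod(x) / nrow(x)           # E[r r^T] at theta, ML
      b <- b + colMeans(x) * ring_phase(t0)
    }
    M <- M / length(th)
    b <- b / length(th)
    thetas <- sort(th)
  } else {
    M <- moments$M; b <- moments$b
    nu <- nrow(M); thetas <- NULL
  }
  ridge <- 0
  rc <- rcond(M)
  if (!is.finite(rc) || rc < max_ridge_cond) {
    k <- -12
    repeat {
      ridge <- 10^k * mean(diag(M))
      if (rcond(M + diag(ridge, nu)) >= max_ridge_cond || k >= 6) break
      k <- k + 1
    }
    warning(sprintf(
      "ill-conditioned second-moment matrix: ridge %.3g added", ridge))
    M <- M + diag(ridge, nu)
  }
  w <- solve(M, b)
  emse <- 1 - Re(crossprod(Conj(b), solve(M, b)))
  structure(
    list(weights = drop(w), expected_mse = drop(emse), ridge = ridge,
         n_units = nu, thetas = thetas),
    class = "general_decoder"
  )
}

#' @export
print.general_decoder <- function(x, ...) {
  cat(sprintf("general_decoder: %d complex weights, expected MSE %.6g\n",
              x$n_units, x$expected_mse))
  if (x$ridge > 0) cat(sprintf("  ridge regularization: %.3g\n", x$ridge))
  invisible(x)
}

#' @export
coef.general_decoder <- function(object, ...) object$weights

#' Decode orientations with a general decoder
#'
#' @param object A `general_decoder`.
#' @param newdata A `trial_matrix` or counts matrix.
#' @param type `"theta"` for decoded orientations in `[0,1)`, `"z"` for the
#'   raw complex readout.
#' @param ... Unused.
#' @return Numeric or complex vector, one entry per trial.
#' @export
predict.general_decoder <- function(object, newdata, type = c("theta", "z"),
                                    ...) {
  type <- match.arg(type)
  counts <- if (inherits(newdata, "trial_matrix")) newdata$counts else
    as.matrix(newdata)
  z <- drop(counts %*% object$weights)
  if (type == "z") z else ring_angle(z)
}

#' Information of the general decoder
#'
#' Measures general-decoder performance as the inverse variance of the
#' circular decoding residual, with a finite-trial bias factor:
#' \deqn{\hat I^g = \frac{1}{\mathrm{Var}(\hat\theta - \theta)}
#'   \cdot \frac{N_{tr} - N - 2}{N_{tr} - 1},}
#' where residuals \eqn{\hat\theta - \theta} are wrapped to `(-0.5, 0.5]` on
#' the normalized ring before the (linear) variance is taken, and
#' \eqn{N_{tr}} is the total number of trials over all orientations. The
#' variance convention matches that of the specific decoder, so the two
#' informations share units of \eqn{1/\theta^2} (normalized orientation).
#' Zero residual variance (noiseless decoding) yields the sentinel
#' `unbounded = TRUE` with `value = Inf` rather than a finite number.
#'
#' @param data A [trial_matrix()] spanning the ring.
#' @param decoder A `general_decoder`, typically from [general_weights()];
#'   fitted on `data` itself for the in-sample estimator (the bias factor
#'   accounts for that optimism) or on independent data for a hold-out
#'   measurement (then use `corrected = FALSE`).
#' @param corrected Apply the `(Ntr - N - 2)/(Ntr - 1)` factor (default TRUE).
#' @return A `fisher_estimate` with extra fields `residual_var` and
#'   `unbounded`.
#' @export
general_info <- function(data, decoder, corrected = TRUE) {
  stopifnot(inherits(data, "trial_matrix"),
            inherits(decoder, "general_decoder"))
  ntr <- n_trials(data)
  nu <- n_units(data)
  if (corrected && ntr <= nu + 2) {
    stop(sprintf(paste0(
      "the bias factor (Ntr-N-2)/(Ntr-1) requires Ntr > N + 2 ",
      "(got Ntr = %d total trials, N = %d units)"), ntr, nu))
  }
  that <- predict(decoder, data)
  resid <- wrap_ring(that - data$theta)
  v <- stats::var(resid)
  unbounded <- (v < 1e-18)   # exact decode up to floating-point noise
  value <- if (unbounded) Inf else {
    if (corrected) (1 / v) * (ntr - nu - 2) / (ntr - 1) else 1 / v
  }
  structure(
    list(value = value, naive = if (unbounded) Inf else 1 / v,
         residual_var = v, unbounded = unbounded, n_units = nu,
         trials_per_condition = ntr, dtheta = NULL, corrected = corrected),
    class = "fisher_estimate"
  )
}

#' Cross-validated pairwise orientation discrimination
#'
#' Two-fold cross-validated linear classification accuracy for two nearby
#' orientations, in either decoding regime: `"specific"` trains a linear
#' support vector machine directly on the N-dimensional responses to the two
#' orientations; `"general"` first projects every trial through a fixed
#' complex readout fitted on responses to *all* orientations, then trains
#' the SVM on the resulting two-dimensional points `(Re z, Im z)`.
#'
#' @param data A [trial_matrix()] containing at least the two target
#'   orientations; for `mode = "general"` it should span the ring (the
#'   complex readout is fitted on all trials of `data`).
#' @param theta1,theta2 The two orientations to discriminate (must be
#'   present in `data`). Equal values are allowed (chance-level control).
#' @param mode `"specific"` or `"general"`.
#' @param folds Number of stratified CV folds (default 2).
#' @param seed Integer seed controlling the fold assignment.
#' @param decoder Optional pre-fitted `general_decoder` to reuse in
#'   `"general"` mode.
#' @return Proportion of correctly classified held-out trials.
#' @export
pair_discrimination <- function(data, theta1, theta2,
                                mode = c("specific", "general"),
                                folds = 2, seed = 1, decoder = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(data, "trial_matrix"))
  same <- isTRUE(all.equal(theta1, theta2))
  i1 <- which(data$theta == theta1)
  if (same) {
    # split one condition's trials into two pseudo-classes
    if (length(i1) < 2 * folds) stop("not enough trials at theta1")
    half <- length(i1) %/% 2
    i2 <- i1[(half + 1):length(i1)]
    i1 <- i1[1:half]
  } else {
    i2 <- which(data$theta == theta2)
  }
  if (length(i1) < folds || length(i2) < folds) {
    stop("both orientations need at least one trial per fold")
  }
  feats <- if (mode == "specific") {
    data$counts
  } else {
    if (is.null(decoder)) decoder <- general_weights(data)
    z <- predict(decoder, data, type = "z")
    cbind(Re(z), Im(z))
  }
  idx <- c(i1, i2)
  y <- factor(rep(c(0L, 1L), c(length(i1), length(i2))))
  x <- feats[idx, , drop = FALSE]
  with_seed(seed, {
    # stratified fold assignment so every fold holds both classes
    fold <- integer(length(idx))
    fold[y == 0L] <- sample(rep_len(seq_len(folds), sum(y == 0L)))
    fold[y == 1L] <- sample(rep_len(seq_len(folds), sum(y == 1L)))
    correct <- 0L
    for (k in seq_len(folds)) {
      tr <- fold != k
      fit <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "linear",
                        scale = FALSE, cost = 1)
      pred <- predict(fit, x[!tr, , drop = FALSE])
      correct <- correct + sum(pred == y[!tr])
    }
    correct / length(idx)
  })
}

#' Leave-one-out cross-validated linear classification
#'
#' The workhorse for the electrophysiology-style decoders. For each trial, a
#' linear classifier is fitted on all remaining trials' `train_labels`, the
#' left-out trial is scored, and the prediction is compared against that
#' trial's `eval_label`. For the stimulus-trained ("specific") decoders the
#' two label vectors coincide; for the choice-trained ("monkey's") decoder
#' the classifier is trained on the animal's saccade choices but scored on
#' stimulus identity. The default classifier is a ridge-regularized linear
#' discriminant (pooled covariance plus a small diagonal load) with the
#' intercept refit on each training fold; a logistic or linear-SVM
#' classifier can be selected instead. Exact ties at the boundary are
#' assigned to the first (lower) class.
#'
#' @param counts Numeric matrix, trials x units.
#' @param train_labels Binary vector (0/1) used for fitting.
#' @param eval_labels Binary vector (0/1) used for scoring; defaults to
#'   `train_labels`.
#' @param classifier `"lda"` (default), `"logistic"`, or `"svm"`.
#' @param ridge Diagonal regularization for `"lda"`, as a fraction of the
#   mean pooled variance. Default 0.1 (shrinkage suited to trial-limited regimes).
#' @return Proportion correct, with attribute `degenerate_folds`: the number
#'   of left-out trials whose training fold contained a single class (those
#'   trials are scored by the training majority class and still counted).
#' @export
loocv_linear_performance <- function(counts, train_labels,
                                     eval_labels = train_labels,
                                     classifier = c("lda", "logistic", "svm"),
                                     ridge = 1) {
  classifier <- match.arg(classifier)
  counts <- as.matrix(counts)
  n <- nrow(counts)
  stopifnot(length(train_labels) == n, length(eval_labels) == n)
  y <- as.integer(train_labels)
  ye <- as.integer(eval_labels)
  if (length(unique(y)) < 2) stop("'train_labels' must contain both classes")
  correct <- logical(n)
  degenerate <- 0L
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    ytr <- y[tr]
    if (length(unique(ytr)) < 2) {
      degenerate <- degenerate + 1L
      pred <- as.integer(names(which.max(table(ytr))))
    } else {
      pred <- switch(classifier,
        lda = {
          x0 <- counts[tr[ytr == 0L], , drop = FALSE]
          x1 <- counts[tr[ytr == 1L], , drop = FALSE]
          m0 <- colMeans(x0); m1 <- colMeans(x1)
          S <- (crossprod(sweep(x0, 2, m0)) + crossprod(sweep(x1, 2, m1))) /
            (length(tr) - 2)
          S <- S + diag(ridge * mean(diag(S)) + 1e-12, ncol(S))
          w <- solve(S, m1 - m0)
          s <- drop(crossprod(counts[i, ] - (m0 + m1) / 2, w))
          if (s > 0) 1L else 0L     # tie (s == 0) goes to the first class
        },
        logistic = {
          xdf <- as.data.frame(counts)
          df <- cbind(data.frame(y = ytr), xdf[tr, , drop = FALSE])
          fit <- suppressWarnings(
            stats::glm(y ~ ., data = df, family = stats::binomial()))
          p <- stats::predict(fit, newdata = xdf[i, , drop = FALSE],
                              type = "response")
          if (p > 0.5) 1L else 0L
        },
        svm = {
          fit <- e1071::svm(counts[tr, , drop = FALSE], factor(ytr),
                            kernel = "linear", scale = FALSE, cost = 1)
          as.integer(as.character(
            predict(fit, counts[i, , drop = FALSE])))
        })
    }
    correct[i] <- (pred == ye[i])
  }
  structure(mean(correct), degenerate_folds = degenerate)
}

#' Linear discriminant axis (ridge-regularized)
#'
#' The weight vector of the regularized linear discriminant used by
#' [loocv_linear_performance()], fitted on all trials. Useful for comparing
#' a choice-trained readout axis against a known generative axis.
#'
#' @inheritParams loocv_linear_performance
#' @param labels Binary class vector (0/1).
#' @return Numeric weight vector (class 1 minus class 0 direction).
#' @export
discriminant_axis <- function(counts, labels, ridge = 1) {
  counts <- as.matrix(counts)
  y <- as.integer(labels)
  x0 <- counts[y == 0L, , drop = FALSE]
  x1 <- counts[y == 1L, , drop = FALSE]
  m0 <- colMeans(x0); m1 <- colMeans(x1)
  S <- (crossprod(sweep(x0, 2, m0)) + crossprod(sweep(x1, 2, m1))) /
    (nrow(counts) - 2)
  S <- S + diag(ridge * mean(diag(S)) + 1e-12, ncol(S))
  drop(solve(S, m1 - m0))
}

#' Serialize a decoder to JSON
#'
#' Weights are stored as real/imaginary pairs with training metadata.
#'
#' @param object A `specific_decoder` or `general_decoder`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_decoder_json <- function(object, path) {
  if (inherits(object, "general_decoder")) {
    x <- list(type = "general",
              weights_re = Re(object$weights),
              weights_im = Im(object$weights),
              expected_mse = object$expected_mse, ridge = object$ridge)
  } else if (inherits(object, "specific_decoder")) {
    x <- list(type = "specific", weights_re = object$weights,
              weights_im = rep(0, length(object$weights)),
              theta0 = object$theta0, dtheta = object$dtheta,
              info = object$info)
  } else stop("unsupported decoder object")
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
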