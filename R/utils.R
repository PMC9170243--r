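#' Circular distance on the normalized orientation ring
#'
#' Orientations live on the normalized ring \eqn{\theta \in [0, 1)}, where
#' \eqn{\theta} and \eqn{\theta + 1} are the same stimulus. The circular
#' distance is the shortest signed or unsigned separation on that ring.
#'
#' @param a,b Numeric vectors of orientations (recycled).
#' @param signed If `TRUE`, return the signed difference in `(-0.5, 0.5]`.
#' @return Numeric vector of distances; unsigned distances are in `[0, 0.5]`.
#' @export
ring_dist <- function(a, b, signed = FALSE) {
  d <- (a - b) %% 1
  d <- ifelse(d > 0.5, d - 1, d)
  if (signed) d else abs(d)
}

#' Map a normalized orientation to the unit circle
#'
#' The general decoder represents the stimulus as a point on the complex unit
#' circle. A normalized orientation \eqn{\theta \in [0,1)} is embedded as
#' \eqn{z = e^{i 2 \pi \theta}} so that one period of \eqn{\theta} covers the
#' circle exactly once. All ring/complex conversions in the package go through
#' this function (and [ring_angle()] for the inverse), so the embedding
#' convention lives in one place.
#'
#' @param theta Numeric vector of orientations in `[0, 1)`.
#' @return Complex vector on the unit circle.
#' @seealso [ring_angle()]
#' @export
ring_phase <- function(theta) {
  exp(2i * pi * theta)
}

#' Map a complex number back to a normalized orientation
#'
#' Inverse of [ring_phase()]: \eqn{\theta = \arg(z) / 2\pi \bmod 1}.
#'
#' @param z Complex vector.
#' @return Numeric vector of orientations in `[0, 1)`.
#' @export
ring_angle <- function(z) {
  (Arg(z) / (2 * pi)) %% 1
}

#' Wrap angular residuals to the principal branch
#'
#' Residuals on the normalized ring are wrapped to `(-0.5, 0.5]` before any
#' variance is taken, so a decode of 0.99 against a target of 0.01 counts as
#' an error of 0.02, not 0.98.
#'
#' @param x Numeric vector of ring residuals (normalized units).
#' @return Wrapped residuals in `(-0.5, 0.5]`.
#' @export
wrap_ring <- function(x) {
  w <- x %% 1
  ifelse(w > 0.5, w - 1, w)
}

# Shortest wrapped displacement between positions on the periodic unit square
# (used for distance-dependent connectivity). x, y in [-0.5, 0.5].
wrapped_sq_dist <- function(dx, dy) {
  dx <- abs(dx) %% 1; dx <- pmin(dx, 1 - dx)
  dy <- abs(dy) %% 1; dy <- pmin(dy, 1 - dy)
  sqrt(dx^2 + dy^2)
}

# Derive a stream-specific 32-bit seed from a base seed without consuming RNG
# state. Keeps all derived seeds < 2^31.
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(stream)) %% 2147483647
}

stop_if_not_finite <- function(x, name) {
  if (!all(is.finite(x))) {
    stop(sprintf("'%s' contains non-finite values", name), call. = FALSE)
  }
  invisible(x)
}

# local RNG scope: evaluate expr with a temporary seed, restoring global state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}
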