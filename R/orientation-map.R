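#' Synthesize an orientation preference map
#'
#' Generates a smooth, quasi-periodic orientation preference map on the unit
#' square \eqn{\Gamma = [-0.5, 0.5]^2} as the argument of a superposition of
#' `n_waves` randomly phased and randomly directed plane waves at fixed
#' wavenumber \eqn{2\pi/\Lambda}:
#' \deqn{z(x) = \sum_j \exp(i\,k\,(x \cos\psi_j + y \sin\psi_j) + i\phi_j),
#'   \qquad \theta(x) = \frac{\arg z(x)}{2\pi} \bmod 1.}
#' The construction yields iso-orientation columns with average spacing
#' \eqn{\Lambda}; its defining property — the dominant spatial frequency of
#' the complex field is \eqn{1/\Lambda} — is checked by
#' [map_dominant_frequency()].
#'
#' @param column_spacing Average hypercolumn spacing \eqn{\Lambda} (default
#'   0.2, in units of the domain side).
#' @param grid_side Number of grid points per side (>= 8).
#' @param seed Integer seed.
#' @param n_waves Number of plane waves in the superposition (default 30).
#' @return An object of class `orientation_map`: `x`, `y` (grid positions),
#'   `orientation` (in `[0,1)`, row-major over the grid), `field` (complex),
#'   `column_spacing`, `grid_side`.
#' @examples
#' m <- make_orientation_map(0.2, grid_side = 24, seed = 1)
#' range(m$orientation)
#' @export
make_orientation_map <- function(column_spacing = 0.2, grid_side = 24,
                                 seed = 1, n_waves = 30) {
  if (column_spacing <= 0) stop("'column_spacing' must be positive")
  if (column_spacing >= 1) {
    stop("'column_spacing' must be smaller than the domain size (1): ",
         "no orientation columns are representable otherwise")
  }
  if (grid_side < 8) stop("'grid_side' must be >= 8")
  pos <- grid_positions(grid_side)
  k <- 2 * pi / column_spacing
  with_seed(seed, {
    psi <- stats::runif(n_waves, 0, 2 * pi)
    phi <- stats::runif(n_waves, 0, 2 * pi)
    z <- complex(real = rep(0, nrow(pos)))
    for (j in seq_len(n_waves)) {
      z <- z + exp(1i * (k * (pos$x * cos(psi[j]) + pos$y * sin(psi[j])) +
                           phi[j]))
    }
    structure(
      list(x = pos$x, y = pos$y, orientation = (Arg(z) / (2 * pi)) %% 1,
           field = z, column_spacing = column_spacing,
           grid_side = grid_side),
      class = "orientation_map"
    )
  })
}

#' @export
print.orientation_map <- function(x, ...) {
  cat(sprintf(
    "orientation_map: %dx%d grid, column spacing %.3g, dominant frequency %.3g\n",
    x$grid_side, x$grid_side, x$column_spacing, map_dominant_frequency(x)))
  invisible(x)
}

# uniform grid of cell centers covering [-0.5, 0.5]^2, row-major
grid_positions <- function(grid_side) {
  u <- (seq_len(grid_side) - 0.5) / grid_side - 0.5
  expand.grid(x = u, y = u)
}

#' Dominant spatial frequency of an orientation map
#'
#' Computes the radially averaged power spectrum of the unit-modulus complex
#' orientation field \eqn{e^{i \arg z}} and returns the frequency (cycles
#' per unit length) of its peak. For a plane-wave superposition map this
#' should fall within one frequency bin of `1 / column_spacing`.
#'
#' @param map An `orientation_map`.
#' @return List with `peak` (cycles/unit), `bin_width`, `freq`, `power`.
#' @export
map_dominant_frequency <- function(map) {
  g <- map$grid_side
  zmat <- matrix(map$field / Mod(map$field), g, g)
  P <- Mod(stats::fft(zmat))^2
  fx <- c(0:(g %/% 2), -((g - g %/% 2 - 1):1))  # cycles per unit (domain = 1)
  fr <- sqrt(outer(fx^2, fx^2, "+"))
  # radial average in unit-width bins
  bins <- floor(fr + 0.5)
  pw <- tapply(as.vector(P), as.vector(bins), mean)
  freq <- as.numeric(names(pw))
  nz <- freq > 0
  structure(list(peak = freq[nz][which.max(pw[nz])], bin_width = 1,
                 freq = freq[nz], power = unname(pw[nz])),
            class = "map_spectrum")
}

#' @export
print.map_spectrum <- function(x, ...) {
  cat(sprintf("map spectrum peak at %.3g cycles/unit\n", x$peak))
  invisible(x)
}
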