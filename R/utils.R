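## small numeric helpers shared across solvers

#' Convert an amplitude ratio to decibels
#'
#' The package-wide convention: all dB values are amplitude dB,
#' `20 * log10(ratio)`.
#' @param ratio positive amplitude ratio(s).
#' @return numeric dB value(s).
#' @export
amplitude_db <- function(ratio) 20 * log10(ratio)

## composite-trapezoid quadrature weights for a uniform grid of n points
trapz_weights <- function(n, dx) {
  w <- rep(dx, n)
  w[c(1L, n)] <- dx / 2
  w
}

trapz <- function(y, dx) sum(trapz_weights(length(y), dx) * y)

## cumulative trapezoid, same length as y, starting at 0; works for complex y
cumtrapz <- function(y, dx) {
  n <- length(y)
  c(0, cumsum((y[-n] + y[-1]) / 2) * dx)
}

## linear interpolation usable for complex values
interp_lin <- function(x, y, xout) {
  if (is.complex(y)) {
    re <- stats::approx(x, Re(y), xout)$y
    im <- stats::approx(x, Im(y), xout)$y
    complex(real = re, imaginary = im)
  } else {
    stats::approx(x, y, xout)$y
  }
}
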