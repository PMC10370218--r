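#' WKB Green's function of the cochlear waveguide
#'
#' Slowly-varying-waveguide (WKB) approximation to the pressure Green's
#' function with reflectionless ends:
#' \deqn{G(x,x') \approx \frac{1}{2i}\sqrt{\frac{A(x')}{A(x)}}
#'   \frac{1}{\sqrt{k(x)k(x')}}
#'   \exp\left(-i \int_{\min(x,x')}^{\max(x,x')} k\, d\hat x\right),}
#' with the phase integral evaluated by composite trapezoid on the model grid.
#' Satisfies the area-weighted reciprocity `A(x) G(x, x') = A(x') G(x', x)`.
#'
#' @param model a [cochlear_model()].
#' @param x,xp receiver and source positions in metres (vectorised over `x`).
#' @param frequency frequency in Hz.
#' @param activity `"on"` or `"off"`.
#' @return complex Green's function value(s), units 1/m (field per unit
#'   point-source strength).
#' @export
wkb_green <- function(model, x, xp, frequency, activity = c("on", "off")) {
  activity <- match.arg(activity)
  stopifnot(length(xp) == 1L)
  x <- check_positions(model, x)
  xp <- check_positions(model, xp)
  kg <- wavenumber(model, model$x, frequency, activity)
  if (any(Mod(kg) < 1e-6 / model$length))
    warning(sprintf("WKB singular: |k| ~ 0 near x = %.2f mm",
                    1e3 * model$x[which.min(Mod(kg))]))
  Kc <- cumtrapz(kg, model$dx)          # complex phase integral from 0
  kx <- wavenumber(model, x, frequency, activity)
  kxp <- wavenumber(model, xp, frequency, activity)
  Kx <- interp_lin(model$x, Kc, x)
  Kxp <- interp_lin(model$x, Kc, xp)
  phase <- -1i * abs_path(Kx, Kxp, x, xp)
  (1 / 2i) * sqrt(area_profile(model, xp) / area_profile(model, x)) /
    sqrt(kx * kxp) * exp(phase)
}

## integral of k from min(x, xp) to max(x, xp), given cumulative values
abs_path <- function(Kx, Kxp, x, xp) {
  ifelse(x >= xp, Kx - Kxp, Kxp - Kx)
}

#' Stapes-driven pressure response (WKB)
#'
#' Pressure along the duct when the cochlea is driven from the stapes with
#' entrance pressure `P(0)`: `P(x) = 2i P(0) k(0) G(x, 0)`. With the
#' amplifier on the response peaks near the characteristic place and is larger
#' and more localised than the passive response.
#'
#' @param model a [cochlear_model()].
#' @param frequency frequency in Hz.
#' @param activity `"on"` or `"off"`.
#' @param p0 complex entrance pressure (default 1).
#' @return A `"wave_field"` data frame with columns `x`, `pressure`
#'   (complex), `magnitude_db` (re entrance pressure), `phase_cycles`,
#'   `wavenumber` (complex), plus attributes `frequency` and `activity`.
#' @export
stapes_response_wkb <- function(model, frequency, activity = c("on", "off"),
                                p0 = 1 + 0i) {
  activity <- match.arg(activity)
  G <- wkb_green(model, model$x, 0, frequency, activity)
  k0 <- wavenumber(model, 0, frequency, activity)
  P <- 2i * p0 * k0 * G
  wave_field(model, frequency, activity, P)
}

## assemble the standard wave-field container
wave_field <- function(model, frequency, activity, pressure,
                       k = wavenumber(model, model$x, frequency, activity)) {
  out <- data.frame(
    x = model$x,
    pressure = pressure,
    magnitude_db = amplitude_db(Mod(pressure) / Mod(pressure[1])),
    phase_cycles = Arg(pressure) / (2 * pi),
    wavenumber = k
  )
  attr(out, "frequency") <- frequency
  attr(out, "activity") <- activity
  class(out) <- c("wave_field", "data.frame")
  out
}

#' @exportS3Method base::print
print.wave_field <- function(x, ...) {
  f <- attr(x, "frequency"); act <- attr(x, "activity")
  pk <- which.max(Mod(x$pressure))
  cat(sprintf("Wave field at %.2f kHz (amplifier %s), %d grid points\n",
              f / 1e3, act, nrow(x)))
  cat(sprintf("  |P| peak: %.1f dB re entrance at x = %.2f mm\n",
              x$magnitude_db[pk], 1e3 * x$x[pk]))
  invisible(x)
}

#' Green's-function matrix over the model grid
#'
#' Computes `G[i, j] = G(x_i, x_j)` for all grid points, using the WKB form or
#' one of the finite-difference solvers. This is the workhorse behind the
#' noise-propagation integrals: the rms noise at `x` due to spatially
#' incoherent unit-density sources is `sqrt(integral |G(x, x')|^2 dx')`.
#'
#' @param model a [cochlear_model()].
#' @param frequency frequency in Hz.
#' @param activity `"on"` or `"off"`.
#' @param provider `"wkb"`, `"fd1d"` or `"fd2d"`.
#' @param ... passed to the finite-difference providers (e.g. `ny`,
#'   `stapes_reflectance` for `"fd2d"`).
#' @return A list of class `"greens_matrix"` with elements `x`, `dx`, `G`
#'   (complex matrix, receiver rows x source columns), `frequency`,
#'   `activity`, `provider`.
#' @export
green_matrix <- function(model, frequency, activity = c("on", "off"),
                         provider = c("wkb", "fd1d", "fd2d"), ...) {
  activity <- match.arg(activity)
  provider <- match.arg(provider)
  G <- switch(provider,
    wkb = green_matrix_wkb(model, frequency, activity),
    fd1d = green_matrix_fd1d(model, frequency, activity, ...),
    fd2d = green_matrix_fd2d(model, frequency, activity, ...)
  )
  structure(list(x = model$x, dx = model$dx, G = G, frequency = frequency,
                 activity = activity, provider = provider),
            class = "greens_matrix")
}

green_matrix_wkb <- function(model, frequency, activity) {
  k <- wavenumber(model, model$x, frequency, activity)
  A <- area_profile(model)
  Kc <- cumtrapz(k, model$dx)
  n <- length(k)
  hi <- pmax(row(matrix(0, n, n)), col(matrix(0, n, n)))
  lo <- pmin(row(matrix(0, n, n)), col(matrix(0, n, n)))
  phase <- matrix(Kc[hi] - Kc[lo], n, n)
  pref_r <- 1 / sqrt(A * k)   # receiver factor (rows)
  pref_s <- sqrt(A / k)       # source factor (columns)
  (1 / 2i) * outer(pref_r, pref_s) * exp(-1i * phase)
}
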