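## --- 1D finite-difference frequency-domain solver ---------------------------
## Discretises (1/A) d/dx (A dP/dx) + k^2 P = f with second-order central
## differences on the uniform model grid. Boundary conditions are imposed via
## ghost-node elimination: a prescribed pressure (Dirichlet) or a one-way
## radiation condition matched to the local wavenumber, optionally with a
## basal wave reflectance R_st. The apical end is always radiating; the sharp
## cut-off makes apical reflections negligible for in-band frequencies.

## area without the [0, L] bounds check, for half-cell and ghost positions
area_raw <- function(model, x) {
  model$area_base * model$area_apex_ratio^(x / model$length)
}

## The finite-difference domain extends a short distance past the apex: the
## tonotopic map and admittance continue smoothly to CFs below cf_apex, so
## waves whose characteristic place abuts the apex complete their natural
## cut-off inside the extension (tens of dB of decay) before meeting the
## far-end radiation condition. Nothing reflects back into the physical duct
## [0, L], emulating the reflectionless apical termination assumed by the
## WKB Green's function; any residual far-end reflection is attenuated twice
## over by the cut-off. Only the physical duct is ever reported; noise
## sources and quadratures live on [0, L].

fd_extension <- function(model, frac = 0.18) {
  m_ext <- ceiling(frac * (model$grid - 1))
  x_full <- seq(0, by = model$dx, length.out = model$grid + m_ext)
  list(m_ext = m_ext, x_full = x_full, n_tot = length(x_full))
}

## wavenumber on the extended grid (tonotopic map continued past the apex)
wavenumber_ext <- function(model, x_full, frequency, activity) {
  mx <- model
  # continue the exponential map: same formula, no position clamp
  cf <- model$cf_base * (model$cf_apex / model$cf_base)^(x_full / model$length)
  s <- frequency / cf
  r0 <- model$resonance_ratio
  delta <- damping_ratio(model, s, activity)
  D <- complex(real = r0^2 - s^2, imaginary = delta * s * r0)
  k2 <- (s / model$wave_scale)^2 * r0^2 / D
  k <- sqrt(k2)
  if (isTRUE(model$cutoff_ablated) && activity == "on")
    k <- complex(real = Re(k), imaginary = pmax(Im(k), 0))
  k
}

## complex tridiagonal system in triplet form on the extended grid;
## base_bc "dirichlet" or "radiation" (outgoing toward the base, with
## optional reflectance)
fd1d_system <- function(model, frequency, activity, base_bc = "dirichlet",
                        stapes_reflectance = 0) {
  ext <- fd_extension(model)
  n <- ext$n_tot
  dx <- model$dx
  x <- ext$x_full
  k <- wavenumber_ext(model, x, frequency, activity)
  k2 <- k^2
  A <- area_raw(model, x)
  Am <- area_raw(model, x - dx / 2)  # A_{i-1/2}
  Ap <- area_raw(model, x + dx / 2)  # A_{i+1/2}
  i <- 2:(n - 1)
  ii <- c(i, i, i)
  jj <- c(i - 1L, i, i + 1L)
  vv <- c(Am[i] / (A[i] * dx^2),
          -(Am[i] + Ap[i]) / (A[i] * dx^2) + k2[i],
          Ap[i] / (A[i] * dx^2))
  # far-end radiation: P'(x_end) = -i k P, ghost-eliminated (the cut-off has
  # attenuated everything in band by here)
  kend <- k[n]
  ii <- c(ii, n, n)
  jj <- c(jj, n - 1L, n)
  vv <- c(vv, (Am[n] + Ap[n]) / (A[n] * dx^2),
          -(Am[n] + Ap[n]) / (A[n] * dx^2) -
            2 * dx * 1i * kend * Ap[n] / (A[n] * dx^2) + k2[n])
  if (base_bc == "dirichlet") {
    ii <- c(ii, 1L); jj <- c(jj, 1L); vv <- c(vv, 1 + 0i)
  } else {
    # basal radiation toward x < 0 with reflectance R_st of the returning
    # wave: P'(0) = +i k(0) (1 - R)/(1 + R) P(0)
    R <- stapes_reflectance
    if (Mod(R) >= 1) stop("|stapes_reflectance| must be < 1")
    beta <- (1 - R) / (1 + R)
    ii <- c(ii, 1L, 1L)
    jj <- c(jj, 2L, 1L)
    vv <- c(vv, (Am[1] + Ap[1]) / (A[1] * dx^2),
            -(Am[1] + Ap[1]) / (A[1] * dx^2) -
              2 * dx * 1i * k[1] * beta * Am[1] / (A[1] * dx^2) + k2[1])
  }
  list(ii = ii, jj = jj, vv = vv, n = n)
}

#' 1D finite-difference solution of the cochlear waveguide
#'
#' Solves the transmission-line equation
#' `(1/A) d/dx(A dP/dx) + k^2 P = 0` (plus a point source, if requested) with
#' one sparse complex linear solve at the given frequency. The stapes drive
#' prescribes the entrance pressure `P(0) = p0` (matching the WKB stapes
#' response normalisation); a point source uses a radiating basal boundary,
#' optionally with wave reflectance `stapes_reflectance`. The apical boundary
#' is a one-way radiation condition matched to the local wavenumber,
#' emulating a reflectionless apex.
#'
#' @param model a [cochlear_model()].
#' @param frequency frequency in Hz.
#' @param activity `"on"` or `"off"`.
#' @param drive `"stapes"` or `"point"`.
#' @param source_position position of the point source (m), for
#'   `drive = "point"`.
#' @param p0 entrance pressure for the stapes drive.
#' @param stapes_reflectance basal wave reflectance `R_st` (`|R_st| < 1`),
#'   used by the point-source drive.
#' @param warn_resolution check the 20-points-per-wavelength contract and warn
#'   if violated.
#' @return a `"wave_field"` data frame (see [stapes_response_wkb()]).
#' @export
solve_fd_1d <- function(model, frequency, activity = c("on", "off"),
                        drive = c("stapes", "point"), source_position = NULL,
                        p0 = 1 + 0i, stapes_reflectance = 0,
                        warn_resolution = TRUE) {
  activity <- match.arg(activity)
  drive <- match.arg(drive)
  if (warn_resolution) check_resolution(model, frequency)
  n <- model$grid
  if (drive == "stapes") {
    sys <- fd1d_system(model, frequency, activity, "dirichlet")
    b <- rep(0 + 0i, sys$n)
    b[1] <- p0
  } else {
    if (is.null(source_position))
      stop("'source_position' is required for a point-source drive")
    sys <- fd1d_system(model, frequency, activity, "radiation",
                       stapes_reflectance)
    b <- rep(0 + 0i, sys$n)
    j <- which.min(abs(model$x - source_position))
    j <- min(max(j, 2L), n - 1L)  # sources live on interior nodes
    b[j] <- -1 / model$dx         # discrete delta: (1/A)(A G')' + k^2 G = -delta
  }
  P <- solve_complex_sparse(sys$ii, sys$jj, sys$vv, b, sys$n)
  wave_field(model, frequency, activity, P[seq_len(n)])
}

## full Green's matrix: one factorisation, one RHS per interior source node
green_matrix_fd1d <- function(model, frequency, activity,
                              stapes_reflectance = 0) {
  n <- model$grid
  sys <- fd1d_system(model, frequency, activity, "radiation",
                     stapes_reflectance)
  B <- matrix(0 + 0i, sys$n, n)
  j <- 2:n                       # apical nodes are interior of the extended grid
  B[cbind(j, j)] <- -1 / model$dx
  G <- solve_complex_sparse(sys$ii, sys$jj, sys$vv, B, sys$n)
  G <- G[seq_len(n), , drop = FALSE]
  # the basal boundary node is not representable (its row carries the BC);
  # it enters quadratures with half trapezoid weight, so reuse the neighbour
  G[, 1] <- G[, 2]
  G
}

#' Stapes-driven response via a chosen solver
#'
#' Convenience dispatcher: `provider = "wkb"` uses the analytic WKB response,
#' `"fd1d"` the finite-difference transmission line, `"fd2d"` the partition
#' pressure of the 2D box model (normalised to its entrance value).
#'
#' @inheritParams solve_fd_1d
#' @param provider `"wkb"`, `"fd1d"` or `"fd2d"`.
#' @param ... passed to the provider.
#' @return a `"wave_field"` data frame.
#' @export
stapes_response <- function(model, frequency, activity = c("on", "off"),
                            provider = c("wkb", "fd1d", "fd2d"), ...) {
  activity <- match.arg(activity)
  provider <- match.arg(provider)
  switch(provider,
    wkb = stapes_response_wkb(model, frequency, activity, ...),
    fd1d = solve_fd_1d(model, frequency, activity, drive = "stapes", ...),
    fd2d = {
      bm <- solve_2d(model, frequency, activity, drive = "stapes", ...)
      wave_field(model, frequency, activity,
                 interp_lin(bm$x, bm$pressure_at_partition, model$x))
    }
  )
}
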