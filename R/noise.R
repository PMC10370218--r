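#' Spatially incoherent noise-source ensemble
#'
#' Describes the internal-noise model: within a narrow frequency band, the
#' noise is a set of spatially incoherent sinusoidal sources, one per grid
#' cell, with phases i.i.d. uniform on `[0, 2*pi)` and non-negative random
#' magnitudes of mean `mu` and standard deviation `sigma`. Only the effective
#' strength `gamma^2 = mu^2 + sigma^2` (the mean-square source amplitude)
#' enters the closed-form noise propagation, which is precisely what the
#' choice of `magnitude_law` is exposed to demonstrate.
#'
#' Magnitude laws: `"rayleigh"` (default) draws Rayleigh magnitudes matched to
#' the total power `gamma^2` (the Rayleigh family has a fixed sd/mean ratio,
#' so it cannot match `mu` and `sigma` separately); `"gamma"` and
#' `"lognormal"` match `mu` and `sigma` exactly; `"fixed"` uses constant
#' magnitude `gamma` (random phase only).
#'
#' @param positions source positions (m); typically a model grid.
#' @param mu,sigma mean and sd of the source magnitude (non-negative).
#' @param magnitude_law one of `"rayleigh"`, `"gamma"`, `"lognormal"`,
#'   `"fixed"`.
#' @return An object of class `"noise_ensemble"` with fields
#'   `source_positions`, `magnitude_mean`, `magnitude_sd`, `magnitude_law`
#'   and `effective_strength` (`gamma`).
#' @export
noise_ensemble <- function(positions, mu = 1, sigma = 0.5,
                           magnitude_law = c("rayleigh", "gamma",
                                             "lognormal", "fixed")) {
  magnitude_law <- match.arg(magnitude_law)
  if (mu < 0 || sigma < 0) stop("'mu' and 'sigma' must be non-negative")
  if (sigma > 0 && mu == 0 && magnitude_law %in% c("gamma", "lognormal"))
    stop("magnitude law '", magnitude_law, "' requires mu > 0 when sigma > 0")
  structure(list(
    source_positions = positions,
    magnitude_mean = mu,
    magnitude_sd = sigma,
    magnitude_law = magnitude_law,
    effective_strength = sqrt(mu^2 + sigma^2)
  ), class = "noise_ensemble")
}

#' @exportS3Method base::print
print.noise_ensemble <- function(x, ...) {
  cat(sprintf("Incoherent noise ensemble: %d sources, %s magnitudes\n",
              length(x$source_positions), x$magnitude_law))
  cat(sprintf("  mu = %g, sigma = %g, effective strength gamma = %g\n",
              x$magnitude_mean, x$magnitude_sd, x$effective_strength))
  invisible(x)
}

draw_magnitudes <- function(ens, n) {
  mu <- ens$magnitude_mean; sg <- ens$magnitude_sd
  gam <- ens$effective_strength
  if (gam == 0) return(numeric(n))
  switch(ens$magnitude_law,
    fixed = rep(gam, n),
    rayleigh = sqrt(gam^2 / 2) * sqrt(-2 * log(stats::runif(n))),
    gamma = if (sg == 0) rep(mu, n) else
      stats::rgamma(n, shape = mu^2 / sg^2, rate = mu / sg^2),
    lognormal = if (sg == 0) rep(mu, n) else {
      s2 <- log(1 + sg^2 / mu^2)
      stats::rlnorm(n, meanlog = log(mu) - s2 / 2, sdlog = sqrt(s2))
    }
  )
}

#' Draw realisations of the noise-source ensemble
#'
#' One column per realisation of the complex source amplitudes
#' `a_j = m_j * exp(i phi_j)`, with magnitudes from the ensemble's law and
#' phases uniform. Reproducible for a fixed seed; the ensemble mean-square
#' amplitude converges to `gamma^2 = mu^2 + sigma^2`.
#'
#' @param ensemble a [noise_ensemble()].
#' @param num_realizations number of independent realisations.
#' @param seed integer seed.
#' @return complex matrix, `length(source_positions)` x `num_realizations`.
#' @export
sample_noise_sources <- function(ensemble, num_realizations = 1, seed = 1L) {
  stopifnot(inherits(ensemble, "noise_ensemble"))
  set.seed(seed)
  ns <- length(ensemble$source_positions)
  n <- ns * num_realizations
  mag <- draw_magnitudes(ensemble, n)
  phase <- stats::runif(n, 0, 2 * pi)
  matrix(mag * exp(1i * phase), nrow = ns, ncol = num_realizations)
}

#' Monte-Carlo noise pressure through a Green's-function provider
#'
#' Propagates realisations of the incoherent source ensemble through a
#' Green's-function matrix and returns the empirical rms noise pressure at
#' every receiver location, with its standard error. Source strengths are
#' scaled by `sqrt(dx)` (one source per grid cell) so the result converges,
#' as realisations accumulate, to the continuum quadrature
#' `gamma * sqrt(integral |G(x, x')|^2 dx')` independently of the grid.
#'
#' @param ensemble a [noise_ensemble()] whose sources sit on the provider
#'   grid.
#' @param gm a `"greens_matrix"` from [green_matrix()] (same grid).
#' @param num_realizations number of Monte-Carlo realisations.
#' @param seed integer seed.
#' @return data frame with `x`, `noise_rms` (empirical), `noise_rms_se`, and
#'   `noise_rms_closed_form` (the discrete quadrature of the
#'   `|G|^2`-integral).
#' @export
ensemble_noise_pressure <- function(ensemble, gm, num_realizations = 200,
                                    seed = 1L) {
  stopifnot(inherits(ensemble, "noise_ensemble"),
            inherits(gm, "greens_matrix"))
  if (length(ensemble$source_positions) != ncol(gm$G))
    stop("ensemble sources and Green's-matrix grid do not match")
  a <- sample_noise_sources(ensemble, num_realizations, seed)
  w <- trapz_weights(ncol(gm$G), gm$dx)
  field <- gm$G %*% (a * sqrt(w))   # receivers x realisations
  p2 <- Mod(field)^2
  mean_p2 <- rowMeans(p2)
  se_p2 <- apply(p2, 1, stats::sd) / sqrt(num_realizations)
  rms <- sqrt(mean_p2)
  closed <- ensemble$effective_strength *
    sqrt(as.numeric(Mod(gm$G)^2 %*% w))
  data.frame(
    x = gm$x,
    noise_rms = rms,
    noise_rms_se = ifelse(rms > 0, se_p2 / (2 * rms), 0),
    noise_rms_closed_form = closed
  )
}
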