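#' Narrowband noise rms along the cochlea
#'
#' Closed-form rms noise pressure due to spatially incoherent unit-density
#' sources distributed along the whole partition:
#' `N(x) = gamma * sqrt(integral_0^L |G(x, x')|^2 dx')`, evaluated by
#' composite trapezoid on the provider grid.
#'
#' @param gm a `"greens_matrix"` from [green_matrix()].
#' @param gamma effective source strength (`sqrt(mu^2 + sigma^2)`).
#' @return numeric vector of noise rms at every grid location.
#' @export
narrowband_noise_rms <- function(gm, gamma = 1) {
  stopifnot(inherits(gm, "greens_matrix"))
  w <- trapz_weights(ncol(gm$G), gm$dx)
  gamma * sqrt(as.numeric(Mod(gm$G)^2 %*% w))
}

#' Basal/apical decomposition of the noise power
#'
#' Splits the noise-power integral at each receiver location `x` into the
#' contributions of sources basal (`x' <= x`) and apical (`x' > x`) to it.
#' The two parts sum to the total of [narrowband_noise_rms()] squared.
#'
#' @inheritParams narrowband_noise_rms
#' @return data frame with `x`, `basal_noise_power`, `apical_noise_power`.
#' @export
basal_apical_decomposition <- function(gm, gamma = 1) {
  stopifnot(inherits(gm, "greens_matrix"))
  n <- ncol(gm$G)
  w <- trapz_weights(n, gm$dx)
  P <- sweep(Mod(gm$G)^2, 2, w, "*")
  basal <- apical <- numeric(n)
  for (i in seq_len(n)) {
    basal[i] <- gamma^2 * sum(P[i, seq_len(i)])
    apical[i] <- gamma^2 * sum(P[i, seq.int(i + 1L, length.out = n - i)])
  }
  data.frame(x = gm$x, basal_noise_power = basal, apical_noise_power = apical)
}

#' Narrowband SNR profile along the cochlea
#'
#' Signal rms from the stapes-driven response and noise rms from the
#' incoherent-source quadrature, on the same grid and through the same
#' Green's-function provider, giving
#' `R(x) proportional to |G(x, 0)| / sqrt(int_0^x |G|^2 + int_x^L |G|^2)`.
#' Absolute SNR depends on the (arbitrary) stimulus level and noise strength;
#' only ratios between modes are physically fixed, so `signal_scale` and
#' `gamma` default to 1.
#'
#' @param model a [cochlear_model()].
#' @param frequency frequency in Hz.
#' @param activity `"on"` or `"off"`.
#' @param provider Green's-function provider (see [green_matrix()]).
#' @param gamma effective noise-source strength.
#' @param signal_scale entrance-pressure scale of the stapes drive.
#' @param gm optional precomputed `"greens_matrix"` (must match model/mode).
#' @return A data frame of class `"snr_profile"`: `x`, `signal_rms`,
#'   `noise_rms`, `basal_noise_power`, `apical_noise_power`, `snr`; attributes
#'   `frequency` and `activity`.
#' @export
snr_profile <- function(model, frequency, activity = c("on", "off"),
                        provider = c("wkb", "fd1d", "fd2d"), gamma = 1,
                        signal_scale = 1, gm = NULL) {
  activity <- match.arg(activity)
  provider <- match.arg(provider)
  if (is.null(gm)) gm <- green_matrix(model, frequency, activity, provider)
  dec <- basal_apical_decomposition(gm, gamma)
  # stapes-driven signal through the same Green's function (entrance column)
  k0 <- wavenumber(model, 0, frequency, activity)
  signal <- signal_scale * Mod(2i * k0 * gm$G[, 1])
  noise <- sqrt(dec$basal_noise_power + dec$apical_noise_power)
  out <- data.frame(
    x = gm$x,
    signal_rms = signal,
    noise_rms = noise,
    basal_noise_power = dec$basal_noise_power,
    apical_noise_power = dec$apical_noise_power,
    snr = signal / noise
  )
  attr(out, "frequency") <- frequency
  attr(out, "activity") <- activity
  attr(out, "provider") <- provider
  class(out) <- c("snr_profile", "data.frame")
  out
}

#' @exportS3Method base::print
print.snr_profile <- function(x, ...) {
  f <- attr(x, "frequency")
  pk <- which.max(x$snr)
  cat(sprintf("SNR profile at %.2f kHz (amplifier %s, provider %s)\n",
              f / 1e3, attr(x, "activity"), attr(x, "provider")))
  cat(sprintf("  max SNR at x = %.2f mm\n", 1e3 * x$x[pk]))
  invisible(x)
}

#' Narrowband near-CF SNR enhancement along the cochlea
#'
#' For each probe frequency, evaluates the SNR with the amplifier on and off
#' at the frequency's characteristic place and reports the on/off ratio — the
#' narrowband (zero-bandwidth) enhancement factor at CF. Locations where the
#' enhancement does not exceed 1 are flagged `near_base`: there, CF waves do
#' not travel far enough to gain from amplification.
#'
#' @param model a [cochlear_model()].
#' @param frequencies probe frequencies in Hz (must lie within the CF band);
#'   default: 33 log-spaced frequencies spanning the map.
#' @param provider Green's-function provider.
#' @param ... passed to [green_matrix()].
#' @return A data frame of class `"enhancement_profile"`: `frequency`, `x`
#'   (characteristic place), `snr_on`, `snr_off`, `enhancement`,
#'   `enhancement_db`, `near_base`.
#' @export
enhancement_profile_narrowband <- function(model, frequencies = NULL,
                                           provider = c("wkb", "fd1d", "fd2d"),
                                           ...) {
  provider <- match.arg(provider)
  if (is.null(frequencies))
    # probe the CFs of interior places: at the extreme ends the characteristic
    # place falls outside the grid and the near-CF convention is undefined
    frequencies <- cf_map(model, seq(0.98, 0.02, length.out = 33) *
                            model$length)
  if (any(frequencies < model$cf_apex * (1 - 1e-9) |
          frequencies > model$cf_base * (1 + 1e-9)))
    stop(sprintf("probe frequencies must lie in the CF band [%.1f, %.1f] kHz",
                 model$cf_apex / 1e3, model$cf_base / 1e3))
  out <- lapply(frequencies, function(f) {
    xhat <- characteristic_place(model, f)
    son <- snr_profile(model, f, "on", provider, ...)
    soff <- snr_profile(model, f, "off", provider, ...)
    ron <- stats::approx(son$x, son$snr, xhat)$y
    roff <- stats::approx(soff$x, soff$snr, xhat)$y
    c(f, xhat, ron, roff)
  })
  out <- do.call(rbind, out)
  enh <- out[, 3] / out[, 4]
  res <- data.frame(
    frequency = out[, 1], x = out[, 2],
    snr_on = out[, 3], snr_off = out[, 4],
    enhancement = enh,
    enhancement_db = amplitude_db(enh),
    near_base = enh <= 1
  )
  attr(res, "band") <- "narrowband near-CF"
  class(res) <- c("enhancement_profile", "data.frame")
  res
}

#' Broadband SNR enhancement along the cochlea
#'
#' Signal and noise both white over the band (default: the model's full CF
#' range, 4--70 kHz), summed incoherently (in power) across log-spaced
#' frequencies: per location, signal power is the sum of stapes-driven
#' `|P(x; f)|^2` and noise power the sum of the incoherent-source
#' quadratures. The enhancement is the on/off ratio of the resulting
#' broadband SNR, in amplitude dB. Locations whose CF-narrowband enhancement
#' does not exceed 1 (too basal for CF waves to gain) are flagged
#' `near_base`.
#'
#' @param model a [cochlear_model()].
#' @param band frequency band (Hz, length 2) within the CF map.
#' @param num_freqs number of log-spaced frequencies (>= 16; default 64).
#' @param provider Green's-function provider.
#' @param gamma effective noise-source strength.
#' @return A data frame of class `"enhancement_profile"`: `x`, `snr_on`,
#'   `snr_off`, `enhancement`, `enhancement_db`, `near_base`.
#' @export
enhancement_profile_broadband <- function(model, band = NULL, num_freqs = 64,
                                          provider = c("wkb", "fd1d", "fd2d"),
                                          gamma = 1) {
  provider <- match.arg(provider)
  if (is.null(band)) band <- c(model$cf_apex, model$cf_base)
  if (band[1] < model$cf_apex || band[2] > model$cf_base || band[1] >= band[2])
    stop(sprintf("band must be increasing and lie within the CF map [%.1f, %.1f] kHz",
                 model$cf_apex / 1e3, model$cf_base / 1e3))
  if (num_freqs < 1) stop("'num_freqs' must be >= 1")
  freqs <- if (num_freqs == 1) mean(band) else
    exp(seq(log(band[1]), log(band[2]), length.out = num_freqs))
  n <- model$grid
  sig <- list(on = numeric(n), off = numeric(n))
  noi <- list(on = numeric(n), off = numeric(n))
  for (f in freqs) {
    for (mode in c("on", "off")) {
      gm <- green_matrix(model, f, mode, provider)
      k0 <- wavenumber(model, 0, f, mode)
      sig[[mode]] <- sig[[mode]] + Mod(2i * k0 * gm$G[, 1])^2
      noi[[mode]] <- noi[[mode]] + narrowband_noise_rms(gm, gamma)^2
    }
  }
  enh <- sqrt((sig$on / noi$on) / (sig$off / noi$off))
  nb <- enhancement_profile_narrowband(model, provider = provider)
  near_base_x <- near_base_extent(nb)
  cf_x <- cf_map(model, model$x)
  # locations whose CF wave cannot complete its apical cut-off inside the
  # duct (within the logistic switch width of the apex) see a truncated
  # apical noise integral; their on/off ratio is a boundary artifact
  apex_margin <- exp(4 / model$cutoff_sharpness)
  res <- data.frame(
    x = model$x,
    snr_on = sqrt(sig$on / noi$on),
    snr_off = sqrt(sig$off / noi$off),
    enhancement = enh,
    enhancement_db = amplitude_db(enh),
    near_base = model$x <= near_base_x | cf_x > band[2] / apex_margin,
    near_apex = cf_x < band[1] * apex_margin
  )
  attr(res, "band") <- sprintf("broadband %.1f-%.1f kHz, %d frequencies",
                               band[1] / 1e3, band[2] / 1e3, length(freqs))
  class(res) <- c("enhancement_profile", "data.frame")
  res
}

## most apical extent of the contiguous near-base flagged region (m)
near_base_extent <- function(nb_profile) {
  ord <- order(nb_profile$x)
  flags <- nb_profile$near_base[ord]
  xs <- nb_profile$x[ord]
  if (!flags[1]) return(-Inf)
  last <- which(!flags)[1]
  if (is.na(last)) return(Inf)
  xs[last - 1L]
}

#' @exportS3Method base::print
print.enhancement_profile <- function(x, ...) {
  cat("SNR enhancement profile (", attr(x, "band"), ")\n", sep = "")
  ok <- !x$near_base
  if (any(ok)) {
    pk <- which.max(ifelse(ok, x$enhancement_db, -Inf))
    cat(sprintf("  peak enhancement %.1f dB at x = %.2f mm (excluding near-base region)\n",
                x$enhancement_db[pk], 1e3 * x$x[pk]))
  }
  cat(sprintf("  %d of %d locations flagged near-base\n",
              sum(x$near_base), nrow(x)))
  invisible(x)
}

#' Peak enhancement outside the near-base region
#'
#' @param profile an `"enhancement_profile"`.
#' @return list with `enhancement_db`, `x`, and (narrowband) `frequency`.
#' @export
peak_enhancement <- function(profile) {
  stopifnot(inherits(profile, "enhancement_profile"))
  ok <- !profile$near_base
  if (!is.null(profile$near_apex)) ok <- ok & !profile$near_apex
  if (!any(ok)) stop("all locations are flagged near-base")
  i <- which.max(ifelse(ok, profile$enhancement_db, -Inf))
  out <- list(enhancement_db = profile$enhancement_db[i], x = profile$x[i])
  if ("frequency" %in% names(profile)) out$frequency <- profile$frequency[i]
  out
}

#' Normalized signal and noise curves, amplifier on and off
#'
#' The four magnitude curves (signal and noise, amplifier on and off) at one
#' frequency, normalised so that the passive (postmortem) signal and noise are
#' equal at the characteristic place. In the active mode the signal curve
#' exceeds the noise curve near the characteristic place, while towards the
#' base the noise is amplified relative to the signal.
#'
#' @inheritParams snr_profile
#' @return data frame with `x`, `signal_on`, `signal_off`, `noise_on`,
#'   `noise_off` (normalised amplitudes) plus attribute `xhat`.
#' @export
normalized_signal_noise_curves <- function(model, frequency,
                                           provider = c("wkb", "fd1d", "fd2d")) {
  provider <- match.arg(provider)
  xhat <- characteristic_place(model, frequency)
  son <- snr_profile(model, frequency, "on", provider)
  soff <- snr_profile(model, frequency, "off", provider)
  s_ref <- stats::approx(soff$x, soff$signal_rms, xhat)$y
  n_ref <- stats::approx(soff$x, soff$noise_rms, xhat)$y
  out <- data.frame(
    x = son$x,
    signal_on = son$signal_rms / s_ref,
    signal_off = soff$signal_rms / s_ref,
    noise_on = son$noise_rms / n_ref,
    noise_off = soff$noise_rms / n_ref
  )
  attr(out, "xhat") <- xhat
  attr(out, "frequency") <- frequency
  out
}
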