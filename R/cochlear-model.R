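#' Linear active cochlear waveguide model
#'
#' Constructs a one-dimensional transmission-line description of the cochlea:
#' an exponential tonotopic map, a tapered cross-sectional area profile, and a
#' phenomenological cochlear-partition admittance that determines the complex
#' wavenumber `k(x, omega)`. The same partition description drives the 1D
#' finite-difference solver, the WKB Green's function and the 2D box-model
#' solver, so the three agree in their common limits.
#'
#' @details
#' The squared wavenumber is modelled in the scaling-symmetric form
#' \deqn{k^2(x,\omega) = (s/\ell)^2 \, r_0^2 / (r_0^2 - s^2 + i\,\delta(s)\, s\, r_0),}
#' where `s = omega / omega_c(x)` is frequency normalised to the local
#' characteristic frequency `CF(x) = cf_base * (cf_apex/cf_base)^(x/L)`,
#' `ell = wave_scale` sets the local long-wave speed `c(x) = omega_c(x) * ell`,
#' and the partition resonance sits at `r_0 = resonance_ratio` times the local
#' CF. Because `k` depends on position and frequency only through `s` (apart
#' from the fixed scale `1/ell`), responses at different frequencies are
#' translates of one another along the cochlea, a standard idealisation of
#' cochlear maps.
#'
#' The damping ratio `delta` is place- and frequency-dependent when the
#' amplifier is on: outer-hair-cell activity makes the partition locally
#' undamped (`delta = damping_active < 0`) for waves below their characteristic
#' place (`s < 1`) and relaxes smoothly to the passive value
#' (`damping_passive > 0`) past it, via a logistic switch in `log(s)` of slope
#' `cutoff_sharpness`, anchored so that `delta = 0` exactly at `s = 1`. This
#' gives the active sign structure of the traveling-wave gain: `Im(k) > 0`
#' (gain) basal to the characteristic place, a single zero crossing there, and
#' `Im(k) < 0` (sharp cut-off) apical to it. With the amplifier off, `delta`
#' equals `damping_passive` everywhere and `Im(k) < 0` at every position and
#' frequency. The forward-wave convention is `exp(+i omega t)`,
#' `P ~ exp(-i integral k dx)`, so `Im(k)` is the log-gain per unit length.
#'
#' Default parameter values are calibration constants: they are chosen to give
#' mouse-like numbers (5 mm duct, CFs 4--70 kHz, peak wavelengths of a fraction
#' of a millimetre, tens of dB of active gain) and are all user-overridable.
#'
#' @param length duct length L in metres (default 5 mm).
#' @param height scala height H in metres, used by the 2D box model.
#' @param grid number of spatial samples (uniform grid on `[0, L]`).
#' @param cf_base,cf_apex characteristic frequencies (Hz) at `x = 0` (stapes)
#'   and `x = L` (apex); must satisfy `cf_base > cf_apex > 0`.
#' @param area_base cross-sectional area at the base (m^2).
#' @param area_apex_ratio `A(L)/A(0)` of the exponential ear-horn taper
#'   (1 = untapered).
#' @param wave_scale length scale `ell` (m) of the map from normalised
#'   frequency to wavenumber; the long-wave phase velocity is
#'   `2 * pi * CF(x) * wave_scale`.
#' @param damping_active dimensionless damping ratio with the amplifier on,
#'   `< 0` (power injection basal to the characteristic place).
#' @param damping_passive passive damping ratio, `> 0`.
#' @param cutoff_sharpness slope of the logistic activity switch in `log(s)`;
#'   larger values give a sharper transition from gain to cut-off.
#' @param resonance_ratio partition resonance frequency in units of the local
#'   CF (`> 1`, keeping the undamped pole away from the `Im(k) = 0` crossing).
#' @param fluid_density cochlear fluid density (kg/m^3).
#' @return An object of class `"cochlear_model"`.
#' @examples
#' cm <- cochlear_model()
#' cm
#' cf_map(cm, c(0, 2.5e-3, 5e-3))
#' @export
cochlear_model <- function(length = 5e-3,
                           height = 0.5e-3,
                           grid = 641L,
                           cf_base = 70e3,
                           cf_apex = 4e3,
                           area_base = 2.5e-7,
                           area_apex_ratio = 0.25,
                           wave_scale = 7e-5,
                           damping_active = -0.3,
                           damping_passive = 0.25,
                           cutoff_sharpness = 20,
                           resonance_ratio = 1.13,
                           fluid_density = 1000) {
  if (length <= 0 || height <= 0) stop("'length' and 'height' must be positive")
  if (!(cf_base > cf_apex && cf_apex > 0))
    stop("need cf_base > cf_apex > 0")
  if (grid < 16) stop("'grid' must have at least 16 samples")
  if (area_base <= 0 || area_apex_ratio <= 0)
    stop("area profile must be strictly positive")
  if (damping_active >= 0) stop("'damping_active' must be negative")
  if (damping_passive <= 0) stop("'damping_passive' must be positive")
  if (resonance_ratio <= 1)
    stop("'resonance_ratio' must exceed 1 (resonance basalward of the pole)")
  m <- structure(list(
    length = length, height = height, grid = as.integer(grid),
    cf_base = cf_base, cf_apex = cf_apex,
    area_base = area_base, area_apex_ratio = area_apex_ratio,
    wave_scale = wave_scale,
    damping_active = damping_active, damping_passive = damping_passive,
    cutoff_sharpness = cutoff_sharpness, resonance_ratio = resonance_ratio,
    fluid_density = fluid_density
  ), class = "cochlear_model")
  m$x <- seq(0, length, length.out = m$grid)
  m$dx <- m$x[2] - m$x[1]
  m
}

#' @exportS3Method base::print
print.cochlear_model <- function(x, ...) {
  cat("Cochlear waveguide model\n")
  cat(sprintf("  duct: L = %.2f mm, H = %.2f mm, %d grid points (dx = %.1f um)\n",
              1e3 * x$length, 1e3 * x$height, x$grid, 1e6 * x$dx))
  cat(sprintf("  tonotopic map: %.0f kHz (base) -> %.0f kHz (apex), exponential\n",
              x$cf_base / 1e3, x$cf_apex / 1e3))
  cat(sprintf("  damping: active %.2f / passive %.2f, cut-off sharpness %.0f, resonance at %.2f CF\n",
              x$damping_active, x$damping_passive, x$cutoff_sharpness,
              x$resonance_ratio))
  invisible(x)
}

#' @exportS3Method base::summary
summary.cochlear_model <- function(object, ...) {
  band <- c(object$cf_apex, object$cf_base)
  res <- grid_resolution(object, band)
  cat("Cochlear waveguide model summary\n")
  print(object)
  cat(sprintf("  in-band resolution: %.1f grid points per shortest wavelength (contract: >= 20)\n",
              res$points_per_wavelength))
  cat(sprintf("  shortest in-band wavelength: %.0f um at %.1f kHz\n",
              1e6 * res$min_wavelength, res$frequency / 1e3))
  invisible(res)
}

check_positions <- function(model, x) {
  tol <- 1e-9 * model$length
  if (any(x < -tol | x > model$length + tol))
    stop("position(s) outside the cochlear duct [0, ", model$length, "]")
  pmin(pmax(x, 0), model$length)
}

#' Tonotopic map: characteristic frequency of a place
#'
#' Exponential place-frequency map
#' `CF(x) = cf_base * (cf_apex / cf_base)^(x / L)`, strictly decreasing from
#' base to apex.
#'
#' @param model a [cochlear_model()].
#' @param x position(s) in metres, `0 <= x <= L`.
#' @return characteristic frequency in Hz.
#' @export
cf_map <- function(model, x) {
  x <- check_positions(model, x)
  model$cf_base * (model$cf_apex / model$cf_base)^(x / model$length)
}

#' Inverse tonotopic map: place of a characteristic frequency
#'
#' @param model a [cochlear_model()].
#' @param frequency frequency(ies) in Hz within `[cf_apex, cf_base]`.
#' @return position(s) in metres.
#' @export
cf_place <- function(model, frequency) {
  if (any(frequency < model$cf_apex | frequency > model$cf_base))
    stop(sprintf("frequency outside the mapped CF band [%.0f, %.0f] Hz",
                 model$cf_apex, model$cf_base))
  model$length * log(frequency / model$cf_base) /
    log(model$cf_apex / model$cf_base)
}

## effective damping ratio at normalised frequency s = omega / omega_c(x)
damping_ratio <- function(model, s, activity) {
  if (activity == "off") return(rep(model$damping_passive, length(s)))
  d_on <- model$damping_active; d_off <- model$damping_passive
  p0 <- d_off / (d_off - d_on)        # switch value where delta crosses zero
  u0 <- log(p0 / (1 - p0))
  sw <- stats::plogis(-model$cutoff_sharpness * log(s) + u0)
  d_off + (d_on - d_off) * sw
}

#' Complex wavenumber of the cochlear traveling wave
#'
#' Evaluates `k(x, omega)` of the partition admittance model (see
#' [cochlear_model()] for the functional form and sign conventions). With the
#' amplifier on, `Im(k) > 0` basal to the characteristic place of the
#' frequency and `Im(k) < 0` apical to it, crossing zero exactly once; with
#' the amplifier off, `Im(k) < 0` everywhere.
#'
#' @param model a [cochlear_model()].
#' @param x position(s) in metres (default: the model grid).
#' @param frequency stimulus frequency in Hz (scalar).
#' @param activity `"on"` (amplifier active) or `"off"` (passive/postmortem).
#' @return complex wavenumber(s), units 1/m; principal branch with
#'   `Re(k) >= 0` (forward-traveling).
#' @export
wavenumber <- function(model, x = model$x, frequency, activity = c("on", "off")) {
  activity <- match.arg(activity)
  stopifnot(length(frequency) == 1L, frequency > 0)
  x <- check_positions(model, x)
  s <- frequency / cf_map(model, x)
  r0 <- model$resonance_ratio
  delta <- damping_ratio(model, s, activity)
  D <- complex(real = r0^2 - s^2, imaginary = delta * s * r0)
  if (any(Mod(D) < 1e-12))
    stop("admittance pole encountered: invalid frequency/position combination")
  k2 <- (s / model$wave_scale)^2 * r0^2 / D
  k <- sqrt(k2)  # principal branch: Re >= 0, sign(Im k) = sign(Im k2)
  if (isTRUE(model$cutoff_ablated) && activity == "on")
    k <- complex(real = Re(k), imaginary = pmax(Im(k), 0))
  k
}

#' Synthetic no-cut-off model variant
#'
#' Returns a copy of the model in which the active-mode `Im(k)` is clamped to
#' be non-negative, removing the sharp wave cut-off apical to the
#' characteristic place while leaving the basal gain untouched. A purely
#' synthetic ablation used to quantify how much the cut-off protects the
#' characteristic place from apical noise sources.
#'
#' @param model a [cochlear_model()].
#' @return the modified model (class unchanged).
#' @export
ablate_cutoff <- function(model) {
  model$cutoff_ablated <- TRUE
  model
}

#' Partition admittance of the box model
#'
#' Admittance `Y(x, omega)` relating partition velocity to the driving
#' pressure difference, `V_CP = Y * P0`. Defined from the 1D wavenumber via
#' the long-wave relation `k^2 = 2 i omega rho Y / H`, so the 2D box model
#' reduces to the 1D transmission line when the wavelength is long compared
#' with the scala height.
#'
#' @inheritParams wavenumber
#' @return complex admittance(s), units (m/s)/Pa.
#' @export
partition_admittance <- function(model, x = model$x, frequency,
                                 activity = c("on", "off")) {
  activity <- match.arg(activity)
  k <- wavenumber(model, x, frequency, activity)
  omega <- 2 * pi * frequency
  k^2 * model$height / (2i * omega * model$fluid_density)
}

#' Cross-sectional area profile
#'
#' Exponential ear-horn taper `A(x) = area_base * area_apex_ratio^(x/L)`.
#'
#' @inheritParams cf_map
#' @return area(s) in m^2.
#' @export
area_profile <- function(model, x = model$x) {
  x <- check_positions(model, x)
  model$area_base * model$area_apex_ratio^(x / model$length)
}

#' Characteristic place of a frequency
#'
#' Finds the zero crossing of `Im(k(x, omega))` along the duct with the
#' amplifier on — the place where traveling-wave gain turns into cut-off and
#' the wave peaks. Located by the sign change on the model grid, refined by
#' linear interpolation within the bracketing cell.
#'
#' @param model a [cochlear_model()].
#' @param frequency frequency in Hz.
#' @param activity activity state; must be `"on"` (passive waves have no gain
#'   region and no crossing).
#' @return position `xhat` in metres.
#' @export
characteristic_place <- function(model, frequency, activity = "on") {
  if (activity != "on")
    stop("Im(k) has no sign change with the amplifier off")
  ik <- Im(wavenumber(model, model$x, frequency, "on"))
  sgn <- sign(ik)
  idx <- which(sgn[-length(sgn)] > 0 & sgn[-1] <= 0)
  if (length(idx) == 0)
    stop(sprintf("no Im(k) sign change in [0, L] at %.1f kHz: frequency out of band",
                 frequency / 1e3))
  i <- idx[1]
  x0 <- model$x[i]; x1 <- model$x[i + 1]
  y0 <- ik[i]; y1 <- ik[i + 1]
  x0 + (x1 - x0) * y0 / (y0 - y1)
}

#' Grid resolution diagnostics
#'
#' Checks the sampling contract of the spatial grid: at least 20 grid points
#' per local wavelength everywhere in the frequency band. Returns the worst
#' case over a frequency scan.
#'
#' @param model a [cochlear_model()].
#' @param band frequency band in Hz (length 2); default the full CF band.
#' @param num_freqs number of log-spaced probe frequencies.
#' @return list with `points_per_wavelength` (worst case), `min_wavelength`,
#'   `frequency` at which it occurs, and logical `ok`.
#' @export
grid_resolution <- function(model, band = c(model$cf_apex, model$cf_base),
                            num_freqs = 24) {
  freqs <- exp(seq(log(band[1]), log(band[2]), length.out = num_freqs))
  worst <- Inf; wl <- NA_real_; wf <- NA_real_
  for (f in freqs) {
    k <- wavenumber(model, model$x, f, "on")
    kmax <- max(Mod(k))
    ppw <- 2 * pi / (kmax * model$dx)
    if (ppw < worst) { worst <- ppw; wl <- 2 * pi / kmax; wf <- f }
  }
  list(points_per_wavelength = worst, min_wavelength = wl, frequency = wf,
       ok = worst >= 20)
}

## warn once per call if a solve is run under-resolved
check_resolution <- function(model, frequency) {
  k <- wavenumber(model, model$x, frequency, "on")
  ppw <- 2 * pi / (max(Mod(k)) * model$dx)
  if (ppw < 20)
    warning(sprintf("grid under-resolved at %.1f kHz: %.1f points per wavelength (< 20)",
                    frequency / 1e3, ppw))
  invisible(ppw)
}
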