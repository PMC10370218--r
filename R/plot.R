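## base-graphics methods for the main result containers

#' @export
plot.wave_field <- function(x, ...) {
  graphics::plot(1e3 * x$x, x$magnitude_db, type = "l",
                 xlab = "distance from stapes (mm)",
                 ylab = "|P| (dB re entrance)",
                 main = sprintf("%.1f kHz, amplifier %s",
                                attr(x, "frequency") / 1e3,
                                attr(x, "activity")), ...)
  invisible(x)
}

#' @export
plot.snr_profile <- function(x, ...) {
  graphics::plot(1e3 * x$x, amplitude_db(x$snr / max(x$snr)), type = "l",
                 xlab = "distance from stapes (mm)",
                 ylab = "SNR (dB re maximum)",
                 main = sprintf("SNR profile, %.1f kHz, amplifier %s",
                                attr(x, "frequency") / 1e3,
                                attr(x, "activity")), ...)
  invisible(x)
}

#' @export
plot.enhancement_profile <- function(x, ...) {
  pch <- ifelse(x$near_base, 1, 16)  # open symbols in the near-base region
  graphics::plot(1e3 * x$x, x$enhancement_db, pch = pch, type = "b",
                 xlab = "distance from stapes (mm)",
                 ylab = "SNR enhancement (dB)",
                 main = attr(x, "band"), ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' @export
plot.chain_response <- function(x, ...) {
  graphics::plot(x$node_index, amplitude_db(x$snr / x$snr[1]), type = "b",
                 xlab = "node", ylab = "SNR (dB re node 0)",
                 main = "Noisy amplifier chain", ...)
  invisible(x)
}

#' @export
plot.bm_response <- function(x, ...) {
  v <- Mod(x$bm_velocity)
  graphics::plot(1e3 * x$x, amplitude_db(v / v[1]), type = "l",
                 xlab = "distance from stapes (mm)",
                 ylab = "|V_CP| (dB re entrance)",
                 main = sprintf("BM velocity, %.1f kHz, amplifier %s",
                                x$frequency / 1e3, x$activity), ...)
  invisible(x)
}
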