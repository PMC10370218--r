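test_that("noise quadrature vanishes with gamma and splits exactly at x", {
  m <- coarse_model()
  gm <- green_matrix(m, 10e3, "on", provider = "wkb")
  expect_equal(narrowband_noise_rms(gm, gamma = 0), rep(0, m$grid))
  dec <- basal_apical_decomposition(gm, gamma = 1.3)
  total <- narrowband_noise_rms(gm, gamma = 1.3)^2
  expect_equal(dec$basal_noise_power + dec$apical_noise_power, total,
               tolerance = 1e-12)
  # at x = 0 the basal integral is empty up to the half-weight self-cell
  # (one cell of |G(0,0)|^2 against the whole-duct apical integral)
  expect_lt(dec$basal_noise_power[1], 0.01 * dec$apical_noise_power[1])
})

test_that("SNR decays monotonically along a passive uniform line", {
  m <- cochlear_model(cf_base = 70e3, cf_apex = 70e3 * (1 - 1e-6),
                      damping_passive = 1e-4, damping_active = -1e-4,
                      area_apex_ratio = 1, grid = 321)
  prof <- snr_profile(m, 10e3, "off", provider = "wkb")
  # noise accumulates while the signal doesn't grow: R(x) non-increasing
  expect_true(all(diff(prof$snr) < 1e-9))
})

test_that("amplification boosts SNR at the characteristic place, not at the base", {
  m <- coarse_model()
  f <- 10e3
  xh <- characteristic_place(m, f)
  on <- snr_profile(m, f, "on", provider = "wkb")
  off <- snr_profile(m, f, "off", provider = "wkb")
  enh <- on$snr / off$snr
  ih <- which.min(abs(m$x - xh))
  expect_gt(enh[ih], 1)
  # towards the entrance the noise is amplified more than the signal
  expect_lt(min(enh[m$x < 0.3 * xh]), 1)
  # apical noise is negligible against basal noise at the peak (active)
  expect_lt(on$apical_noise_power[ih], 0.01 * on$basal_noise_power[ih])
})

test_that("the enhancement is invariant to signal and noise rescaling", {
  m <- coarse_model()
  f <- 12e3
  gm_on <- green_matrix(m, f, "on", provider = "wkb")
  gm_off <- green_matrix(m, f, "off", provider = "wkb")
  set.seed(31)
  for (rep in 1:3) {
    sc <- exp(stats::rnorm(2, 0, 2))
    base <- snr_profile(m, f, "on", gm = gm_on)$snr /
      snr_profile(m, f, "off", gm = gm_off)$snr
    scaled <- snr_profile(m, f, "on", gamma = sc[1], signal_scale = sc[2],
                          gm = gm_on)$snr /
      snr_profile(m, f, "off", gamma = sc[1], signal_scale = sc[2],
                  gm = gm_off)$snr
    expect_equal(scaled, base, tolerance = 1e-10)
  }
})

test_that("narrowband CF-following enhancement peaks in the mid-cochlea", {
  m <- coarse_model()
  nb <- enhancement_profile_narrowband(m, provider = "wkb")
  expect_true(all(nb$enhancement > 0))
  expect_equal(nb$enhancement_db, amplitude_db(nb$enhancement))
  pk <- peak_enhancement(nb)
  expect_gt(pk$enhancement_db, 0)
  expect_true(pk$x > 0.05 * m$length && pk$x < 0.95 * m$length)
  expect_error(enhancement_profile_narrowband(m, frequencies = c(1e3, 10e3)),
               "band")
})

test_that("passive-vs-passive enhancement is identically one", {
  m <- coarse_model()
  f <- 10e3
  off <- snr_profile(m, f, "off", provider = "wkb")
  expect_equal(off$snr / off$snr, rep(1, m$grid))
})

test_that("a single-frequency band reduces the broadband profile to narrowband", {
  m <- coarse_model()
  f <- 10e3
  bb1 <- enhancement_profile_broadband(m, band = c(f * 0.999, f * 1.001),
                                       num_freqs = 1, provider = "wkb")
  on <- snr_profile(m, mean(c(f * 0.999, f * 1.001)), "on", provider = "wkb")
  off <- snr_profile(m, mean(c(f * 0.999, f * 1.001)), "off", provider = "wkb")
  expect_equal(bb1$enhancement, on$snr / off$snr, tolerance = 1e-10)
})

test_that("broadband enhancement is bounded by the per-frequency maximum", {
  m <- coarse_model()
  freqs <- exp(seq(log(4e3), log(70e3), length.out = 16))
  n <- m$grid
  sig <- list(on = numeric(n), off = numeric(n))
  noi <- list(on = numeric(n), off = numeric(n))
  per_freq_best <- rep(0, n)
  for (f in freqs) {
    snr_f <- list()
    for (mode in c("on", "off")) {
      gm <- green_matrix(m, f, mode, provider = "wkb")
      k0 <- wavenumber(m, 0, f, mode)
      s <- Mod(2i * k0 * gm$G[, 1])^2
      no <- narrowband_noise_rms(gm)^2
      sig[[mode]] <- sig[[mode]] + s
      noi[[mode]] <- noi[[mode]] + no
      snr_f[[mode]] <- s / no
    }
    per_freq_best <- pmax(per_freq_best, snr_f$on / snr_f$off)
  }
  broadband <- (sig$on / noi$on) / (sig$off / noi$off)
  expect_true(all(broadband <= per_freq_best * (1 + 1e-9)))
})

test_that("broadband quadrature converges as the frequency grid doubles", {
  m <- coarse_model()
  b32 <- enhancement_profile_broadband(m, num_freqs = 32, provider = "wkb")
  b64 <- enhancement_profile_broadband(m, num_freqs = 64, provider = "wkb")
  ok <- !(b64$near_base | b64$near_apex)
  expect_lt(max(abs(b64$enhancement_db[ok] - b32$enhancement_db[ok])), 0.3)
})

test_that("postmortem-normalised curves behave as in the active/passive contrast", {
  m <- coarse_model()
  f <- 10e3
  cur <- normalized_signal_noise_curves(m, f, provider = "wkb")
  xh <- attr(cur, "xhat")
  at <- function(v) stats::approx(cur$x, v, xh)$y
  # the normalisation's definition: postmortem equality at the peak
  expect_equal(at(cur$signal_off), at(cur$noise_off), tolerance = 1e-9)
  # in vivo the signal beats the noise at the characteristic place
  expect_gt(at(cur$signal_on), at(cur$noise_on))
  # moving basally, amplification favours the noise relative to the signal
  ib <- which.min(abs(cur$x - 0.15 * xh))
  rel <- (cur$noise_on / cur$noise_off) / (cur$signal_on / cur$signal_off)
  ih <- which.min(abs(cur$x - xh))
  expect_gt(rel[ib], rel[ih])
})

test_that("the cochlear gain pattern mirrors the discrete optimal-gain chain", {
  m <- coarse_model()
  f <- 10e3
  xh <- characteristic_place(m, f)
  won <- stapes_response_wkb(m, f, "on")
  nodes <- round(seq(1, which.min(abs(m$x - min(1.3 * xh, m$length))),
                     length.out = 25))
  gains <- Mod(won$pressure[nodes[-1]]) / Mod(won$pressure[nodes[-length(nodes)]])
  ch <- amp_chain(length(gains), gain = pmax(gains, 1e-6))
  ce <- chain_enhancement(ch)
  target <- which.min(abs(m$x[nodes] - xh)) - 1L
  expect_gt(ce$enhancement[target + 1L], 1)
  expect_equal(which.max(ce$enhancement) - 1L, target)
  expect_true(any(ce$enhancement < 1))   # no global SNR improvement
})

test_that("removing the apical cut-off weakens the enhancement at the peak", {
  m <- coarse_model()
  f <- 10e3
  ix <- which.min(abs(m$x - characteristic_place(m, f)))
  enh_at <- function(model) {
    on <- snr_profile(model, f, "on", provider = "wkb")
    off <- snr_profile(model, f, "off", provider = "wkb")
    on$snr[ix] / off$snr[ix]
  }
  full <- enh_at(m)
  ablated <- enh_at(ablate_cutoff(m))
  expect_lt(ablated, full)
  # mechanism: the cut-off squelches the apical noise contribution
  apical <- function(model) {
    snr_profile(model, f, "on", provider = "wkb")$apical_noise_power[ix]
  }
  expect_gt(apical(ablate_cutoff(m)), 10 * apical(m))
})
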