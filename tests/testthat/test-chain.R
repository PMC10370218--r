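test_that("one-way signal gain is the plain gain power", {
  expect_equal(one_way_signal_gain(1, 10), 1)
  expect_equal(one_way_signal_gain(2, 3), 8)
  expect_equal(one_way_signal_gain(0.5, 2), 0.25)
  expect_error(one_way_signal_gain(-1, 2), "positive")
  expect_error(one_way_signal_gain(2, -1), "non-negative")
})

test_that("one-way noise rms matches the brute-force power sum", {
  expect_equal(one_way_noise_rms(1, 3, 1), 2)               # sqrt(n+1) branch
  expect_equal(one_way_noise_rms(2, 1, 1), sqrt(5))         # 1 + g^2 = 5
  # closed form vs brute-force partial sums over a parameter sweep
  set.seed(42)
  for (rep in 1:25) {
    g <- exp(stats::runif(1, log(0.1), log(10)))
    n <- sample(0:100, 1)
    expect_equal(one_way_noise_rms(g, n, 1.7), brute_noise_rms(g, n, 1.7),
                 tolerance = 1e-10)
  }
})

test_that("the two branches of the noise-rms series agree near g = 1", {
  expect_equal(one_way_noise_rms(1 + 1e-12, 5, 1),
               one_way_noise_rms(1, 5, 1), tolerance = 1e-6)
  # and just outside the branch switch the closed form is still continuous
  expect_equal(one_way_noise_rms(1 + 1e-7, 50, 1),
               one_way_noise_rms(1, 50, 1), tolerance = 1e-4)
})

test_that("one-way enhancement, noise gain and noise factor are consistent", {
  off <- one_way_enhancement(1, 20)
  expect_equal(off$enhancement, 1)
  expect_equal(off$noise_gain, 1)
  expect_equal(off$noise_factor, 1)
  e <- one_way_enhancement(2, 1)
  expect_equal(e$noise_gain, sqrt(2.5))
  expect_equal(e$enhancement, 2 / sqrt(2.5))
  expect_equal(e$noise_factor, 16 * 0.75 / 15)    # printed-form evaluation
  # noise factor equals (R_n / R_0)^2 from explicit node responses
  g <- 2; n <- 1
  R0 <- 1 / brute_noise_rms(g, 0)
  R1 <- g / brute_noise_rms(g, 1)
  expect_equal(e$noise_factor, (R1 / R0)^2)
  # no overflow in the large-gain regime
  big <- one_way_enhancement(10, 50)
  expect_true(is.finite(big$enhancement) && big$enhancement > 1)
})

test_that("enhancement exceeds 1 iff the chain amplifies, and grows with g and n", {
  for (g in c(1.2, 2, 5)) {
    e <- one_way_enhancement(g, 1:40)
    expect_true(all(e$enhancement > 1))
    expect_true(all(diff(e$enhancement) > 0))       # monotone in n
  }
  for (g in c(0.2, 0.5, 0.9)) {
    expect_true(all(one_way_enhancement(g, 1:40)$enhancement < 1))
  }
  # monotone in g at fixed n
  gs <- c(1.1, 1.5, 2, 3, 5, 8)
  enh <- vapply(gs, function(g) one_way_enhancement(g, 10)$enhancement, 0)
  expect_true(all(diff(enh) > 0))
})

test_that("discrete Green's function is a symmetric inter-node product", {
  expect_equal(discrete_green(rep(1, 7), 2, 5), 1)
  expect_equal(discrete_green(c(2, 3), 0, 2), 6)
  expect_equal(discrete_green(c(2, 3, 4, 5), 4, 4), 1)   # empty product
  set.seed(7)
  gains <- exp(stats::rnorm(9, 0, 0.5))
  for (rep in 1:10) {
    nn <- sample(0:9, 2)
    expect_equal(discrete_green(gains, nn[1], nn[2]),
                 discrete_green(gains, nn[2], nn[1]))
    expect_equal(discrete_green(gains, nn[1], nn[2]),
                 brute_green(gains, nn[1], nn[2]))
  }
  expect_error(discrete_green(gains, 0, 10), "indices")
})

test_that("bidirectional node response sums one incoherent source per node", {
  ch <- amp_chain(10, gain = 1, noise_strength = 1)
  r <- chain_node_response(ch)
  expect_equal(r$noise_rms, rep(sqrt(11), 11))
  expect_equal(r$basal_noise_power + r$apical_noise_power, r$noise_rms^2)
  expect_equal(r$snr, r$signal_rms / r$noise_rms)
  # Fig-1E-style profile: brute-force evaluation of the node-5 response
  gains <- optimal_gain_profile(10, 5)
  ch5 <- amp_chain(10, gain = gains, noise_strength = 1)
  r5 <- chain_node_response(ch5)
  G5 <- vapply(0:10, function(np) brute_green(gains, 5, np), 0)
  expect_equal(r5$signal_rms[6], brute_green(gains, 5, 0))
  expect_equal(r5$noise_rms[6], sqrt(sum(G5^2)))
})

test_that("optimal gain profile maximises SNR at its target node only", {
  expect_equal(optimal_gain_profile(10, 5), c(rep(3, 5), rep(0.1, 5)))
  expect_equal(optimal_gain_profile(10, 0), rep(0.1, 10))
  expect_error(optimal_gain_profile(10, 11), "0..10")
  enh <- chain_enhancement(amp_chain(10, gain = optimal_gain_profile(10, 5)))
  expect_equal(which.max(enh$enhancement) - 1L, 5L)
  expect_gt(enh$enhancement[6], 1)
  # SNR cannot be enhanced everywhere at once in the bidirectional chain
  expect_true(any(enh$enhancement < 1))
  # limit g_hi -> Inf, g_lo -> 0: one-way performance at the target node
  ch_lim <- amp_chain(10, gain = optimal_gain_profile(10, 5, 100, 0.01))
  snr_bidir <- chain_node_response(ch_lim)$snr[6]
  snr_oneway <- one_way_signal_gain(100, 5) / one_way_noise_rms(100, 5)
  expect_equal(snr_bidir, snr_oneway, tolerance = 1e-4)
})

test_that("Monte-Carlo chain reproduces the closed-form noise rms", {
  ch <- amp_chain(3, gain = 1, noise_strength = 1)
  mc <- monte_carlo_chain(ch, num_trials = 1e4, seed = 11)
  expect_true(all(abs(mc$noise_rms - mc$noise_rms_closed_form) <
                    3 * mc$noise_rms_se))
  # arbitrary bidirectional profile
  ch2 <- amp_chain(6, gain = c(2, 3, 0.5, 1.5, 0.2, 1), noise_strength = 0.7)
  mc2 <- monte_carlo_chain(ch2, num_trials = 1e4, seed = 3)
  expect_true(all(abs(mc2$noise_rms - mc2$noise_rms_closed_form) <
                    3 * mc2$noise_rms_se))
  # silent ensemble and determinism
  expect_equal(monte_carlo_chain(amp_chain(4, gain = 2, noise_strength = 0),
                                 100, seed = 1)$noise_rms, rep(0, 5))
  expect_identical(monte_carlo_chain(ch2, 200, seed = 9),
                   monte_carlo_chain(ch2, 200, seed = 9))
})

test_that("chain configuration is validated", {
  expect_error(amp_chain(0), "positive integer")
  expect_error(amp_chain(5, gain = c(1, 2)), "length")
  expect_error(amp_chain(5, gain = -2), "positive")
  expect_error(amp_chain(5, noise_strength = -1), "non-negative")
})
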