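## 2D configurations: a shallow box keeps the fluid in the long-wave regime
## (where the 2D model must reduce to the transmission line) and keeps the
## suite fast; the qualitative behaviour does not depend on the height
shallow_2d <- function(grid = 401L, height = 5e-5, ...) {
  cochlear_model(height = height, grid = grid, ...)
}

test_that("the 2D model reduces to the 1D transmission line for long waves", {
  m <- cochlear_model(height = 1e-5, grid = 771)
  f <- 10e3
  b1 <- solve_fd_1d(m, f, "on", warn_resolution = FALSE)
  b2 <- solve_2d(m, f, "on", ny = 9)
  p1 <- Mod(b1$pressure) / Mod(b1$pressure[1])
  p2 <- Mod(b2$pressure_at_partition) / Mod(b2$pressure_at_partition[1])
  xh <- characteristic_place(m, f)
  sel <- m$x > 0 & m$x < 0.8 * xh
  expect_lt(max(abs(amplitude_db(p2[sel] / p1[sel]))), 1)
})

test_that("active 2D responses are larger, sharper, and tonotopically ordered", {
  m <- shallow_2d()
  pk <- function(b) b$x[which.max(Mod(b$bm_velocity))]
  mx <- function(b) max(Mod(b$bm_velocity))
  width <- function(b) {
    a <- Mod(b$bm_velocity)
    sum(a > max(a) / 2) * (b$x[2] - b$x[1])
  }
  on10 <- solve_2d(m, 10e3, "on", ny = 9)
  off10 <- solve_2d(m, 10e3, "off", ny = 9)
  on30 <- solve_2d(m, 30e3, "on", ny = 9)
  off30 <- solve_2d(m, 30e3, "off", ny = 9)
  expect_gt(mx(on10), mx(off10))
  expect_gt(mx(on30), mx(off30))
  expect_lt(width(on10), width(off10))
  expect_lt(pk(on30), pk(on10))          # 30 kHz peaks basal to 10 kHz
  # admittance relation holds pointwise
  expect_equal(on10$bm_velocity, on10$admittance * on10$pressure_at_partition,
               tolerance = 1e-12)
})

test_that("zero drive produces an identically zero field", {
  m <- shallow_2d(grid = 201)
  z <- solve_2d(m, 10e3, "on", ny = 9, stapes_velocity = 0)
  expect_equal(max(Mod(z$pressure)), 0)
})

test_that("fluid volume is conserved at the boundaries", {
  m <- shallow_2d(area_apex_ratio = 1)
  f <- 10e3; omega <- 2 * pi * f
  Ust <- 1e-3
  b <- solve_2d(m, f, "on", ny = 9, stapes_velocity = Ust)
  dx <- b$x[2] - b$x[1]; dy <- b$y[2] - b$y[1]
  flux_in <- Ust * m$height
  w <- trapz_weights <- rep(dx, length(b$x)); w[c(1, length(w))] <- dx / 2
  flux_bm <- sum(b$bm_velocity * w)
  nx <- length(b$x)
  uxL <- (b$pressure[nx, ] - b$pressure[nx - 1, ]) / dx /
    (-1i * omega * m$fluid_density)
  wy <- rep(dy, length(b$y)); wy[c(1, length(wy))] <- dy / 2
  flux_apex <- sum(uxL * wy)
  expect_lt(Mod(flux_in + flux_bm - flux_apex) / Mod(flux_in), 1e-6)
})

test_that("the 2D solution self-converges under grid refinement", {
  m <- shallow_2d()
  f <- 10e3
  coarse <- solve_2d(m, f, "on", ny = 9)
  fine <- solve_2d(m, f, "on", nx = 801, ny = 17)
  expect_lt(abs(amplitude_db(max(Mod(fine$bm_velocity)) /
                             max(Mod(coarse$bm_velocity)))), 0.5)
})

test_that("2D point-source responses are reciprocal and reject apical sources", {
  m <- shallow_2d()
  f <- 10e3
  x1 <- cf_place(m, 25e3); x2 <- cf_place(m, 14e3)
  g12 <- greens_2d(m, x1, x2, f, "on", nx = 401, ny = 9)
  g21 <- greens_2d(m, x2, x1, f, "on", nx = 401, ny = 9)
  lhs <- area_profile(m, x1) * g12
  rhs <- area_profile(m, x2) * g21
  expect_lt(Mod(lhs - rhs) / Mod(lhs), 0.05)   # solver tolerance
  # a source apical to the receiver's characteristic place contributes far
  # less than an equidistant basal source
  xh <- characteristic_place(m, f)
  d <- 0.8e-3
  gb <- greens_2d(m, xh, xh - d, f, "on", nx = 401, ny = 9)
  ga <- greens_2d(m, xh, xh + d, f, "on", nx = 401, ny = 9)
  expect_gt(Mod(gb) / Mod(ga), 1e3)
})

test_that("a reflective basal boundary produces interference ripple", {
  m <- shallow_2d()
  f <- 10e3
  xh <- characteristic_place(m, f)
  xr <- seq(0.2e-3, 0.8 * xh, length.out = 60)
  g0 <- greens_2d(m, xr, xh, f, "on", stapes_reflectance = 0,
                  nx = 401, ny = 9)
  gr <- greens_2d(m, xr, xh, f, "on", stapes_reflectance = 0.14,
                  nx = 401, ny = 9)
  ratio <- Mod(gr) / Mod(g0)
  expect_gt(max(ratio) - min(ratio), 0.1)
  # and the reflectionless case is smooth by comparison
  expect_lt(stats::sd(Mod(g0[1:30]) / mean(Mod(g0[1:30]))),
            stats::sd(Mod(gr[1:30]) / mean(Mod(gr[1:30]))))
})

test_that("the 2D Green's function matches WKB through the 1D cross-check", {
  # in the shallow (long-wave) box the 2D partition response must track the
  # 1D numeric Green's function, which in turn tracks WKB basal to the peak
  m <- cochlear_model(height = 1e-5, grid = 771)
  f <- 10e3
  xp <- cf_place(m, 40e3)
  gn <- greens_2d(m, NULL, xp, f, "on", nx = 771, ny = 7)
  fd <- solve_fd_1d(m, f, "on", drive = "point", source_position = xp,
                    warn_resolution = FALSE)
  xg <- attr(gn, "x")
  xh <- characteristic_place(m, f)
  sel <- xg > 0.2e-3 & xg < xh & abs(xg - xp) > 0.2e-3
  expect_lt(max(abs(amplitude_db(Mod(gn[sel]) / Mod(fd$pressure[sel])))), 1)
})
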