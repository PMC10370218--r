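## shared fixtures: coarse models keep the suite fast; the acceptance tests
## build the full default model themselves

coarse_model <- function(...) {
  cochlear_model(grid = 321L, ...)
}

## brute-force one-way noise rms: explicit power sum, the oracle for Eq. 2
brute_noise_rms <- function(g, n, gamma = 1) {
  gamma * sqrt(sum(g^(2 * (0:n))))
}

## brute-force discrete Green's function by explicit multiplication
brute_green <- function(gains, n, np) {
  lo <- min(n, np); hi <- max(n, np)
  out <- 1
  m <- lo
  while (m < hi) {
    out <- out * gains[m + 1]
    m <- m + 1
  }
  out
}
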