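# cochlearSNR

Does the cochlear amplifier actually make hearing more sensitive? Outer hair
cells boost sound-evoked traveling waves by tens of dB, but the same
machinery amplifies the mechanical noise generated *inside* the cochlea. A
real gain in sensitivity requires the signal to be amplified more than the
internal noise. `cochlearSNR` implements a quantitative analysis of this
question for researchers in auditory biophysics and computational
neuroscience, as a set of linked linear models:

* **Noisy amplifier chains** — a cascade of `N` gain stages with one
  incoherent noise source per node. One-way: signal `S[n] = g^n S[0]`, noise
  `N[n] = γ √(Σ_{m=0}^{n} g^{2m})`, SNR enhancement
  `R[n] = g^n / √((g^{2(n+1)}−1)/((n+1)(g²−1)))` (the same algebra as the
  noise figure of cascaded electronic amplifiers). Bidirectional: the
  discrete Green's function `G[n,n'] = Π g_m` propagates signal and noise
  both ways; the profile maximising SNR at node `n` is `g ≫ 1` below `n` and
  `g ≪ 1` above it.
* **Active cochlear waveguide (1D)** — the transmission line
  `(1/A)(A P')' + k² P = 0` with an exponential tonotopic map (70 → 4 kHz
  over 5 mm) and a phenomenological partition admittance whose damping is
  negative basal to the characteristic place and positive apical to it, so
  that `Im k > 0` (gain) before the wave peak and `Im k < 0` (sharp cut-off)
  beyond it. Solved by the WKB Green's function
  `G(x,x') ≈ (1/2i) √(A'/A) (k k')^{-1/2} exp(−i∫k)` and by finite
  differences.
* **2D box cochlea** — Laplace fluid over the admittance partition, one
  sparse complex solve per frequency; reduces to the 1D line for long waves.
* **Incoherent noise ensembles** — sinusoidal sources with uniform phases
  and random magnitudes (mean `μ`, sd `σ`); the rms noise at `x` is
  `γ √(∫|G(x,x')|² dx')` with `γ² = μ² + σ²`, validated by Monte Carlo.
* **SNR profiles** — `R(x) ∝ |G(x,0)| / √(∫₀ˣ|G|² + ∫ₓᴸ|G|²)`, amplifier on
  vs off, per frequency (narrowband, CF-following) or summed in power over a
  white 4–70 kHz band (broadband).

All dB values are amplitude dB, `20·log10(ratio)`.

## A worked example

```r
library(cochlearSNR)

m <- cochlear_model()        # calibrated mouse-like defaults
m
#> Cochlear waveguide model
#>   duct: L = 5.00 mm, H = 0.50 mm, 641 grid points (dx = 7.8 um)
#>   tonotopic map: 70 kHz (base) -> 4 kHz (apex), exponential
#>   damping: active -0.30 / passive 0.25, cut-off sharpness 20, resonance at 1.13 CF

characteristic_place(m, 10e3) * 1e3     # where does a 10-kHz wave peak? (mm)
#> [1] 3.398862

solve_fd_1d(m, 10e3, "on")              # stapes-driven tone response
#> Wave field at 10.00 kHz (amplifier on), 641 grid points
#>   |P| peak: 21.5 dB re entrance at x = 3.40 mm

nb <- enhancement_profile_narrowband(m, provider = "fd1d")
peak_enhancement(nb)
#> $enhancement_db
#> [1] 16.60181
#> $x
#> [1] 0.000849...
#> $frequency
#> [1] 42448.97

bb <- enhancement_profile_broadband(m, num_freqs = 64, provider = "fd1d")
peak_enhancement(bb)$enhancement_db
#> [1] 9.257...
```

Reading these numbers: a 10-kHz tone peaks 3.4 mm from the stapes, 21.5 dB
above its entrance level when the amplifier is on. Comparing amplifier-on
against amplifier-off, the narrowband (near-CF) SNR improves by ≈ 16.6 dB at
the most sensitive locations, and by ≈ 9.3 dB when both signal and noise are
white over the full 4–70 kHz range: spatially localised amplification
followed by a sharp cut-off boosts signals more than the internal noise.
`plot()` methods on the returned objects draw the corresponding profiles,
and `run_pipeline()` regenerates all figure-style CSV panels plus a
checksummed JSON manifest from a single (YAML/JSON) configuration.

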