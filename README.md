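# fretscape

Single-molecule FRET conformational-ensemble analysis in R.

Confocal single-molecule FRET watches one labelled protein at a time
diffuse through a femtolitre observation volume, recording a burst of
photons per molecule. For proteins that do not adopt a single
structure — the motivating case being monomeric apolipoprotein E4,
whose folded four-helix bundle coexists with partially structured
tails and at least three long-range arrangements of its C-terminal
domain — the transfer-efficiency histogram is a mixture of
conformational populations, each with its own distance distribution,
stability, and exchange kinetics. fretscape provides the complete
analysis chain for such systems:

* **Burst analysis** — photon-stream burst detection, corrected
  transfer efficiencies `E = nA′/(nA′ + γ·nD′)`, pulsed-interleaved
  stoichiometry filtering (S ∈ [0.3, 0.7] removes donor-only
  molecules), histogram construction, Gaussian mixture decomposition
  with a shot-noise width floor `sqrt(E(1−E)/n̄)`, and burst variance
  analysis against the binomial envelope.
* **Polymer distance models** — the Förster relation
  `E = 1/(1+(r/R0)^6)` and its inverse; rigid, worm-like chain, and
  Gaussian-chain distance distributions; distribution-averaged
  efficiencies by quadrature; donor-lifetime static line
  `τ/τ0 = 1 − E` and the variance-shifted dynamic point
  `(1−⟨E⟩) + Var(E)/(1−⟨E⟩)` that separates rigid conformations from
  dynamic ensembles.
* **Denaturant thermodynamics** — linear free-energy models
  `G_s(c) = ΔG⁰_s + m_s·c` (RT units), Boltzmann state fractions,
  closed-form midpoints `c½ = −ΔG⁰/m`, and global two-/three-state
  titration fits with covariance and bootstrap intervals.
* **Kinetic Monte Carlo photon simulation** — a Markov state model
  with per-state dye distances drives a photon-by-photon simulator
  (state steps every `lag × rescale` ns, Poisson arrivals, binomial
  channel choice), reproducing shot noise and kinetic averaging; plus
  a detailed-balance Markov-model estimator for discrete trajectories
  and an L1 histogram comparator.
* **Ensemble contact analysis** — residue centre-of-mass contacts
  (< 3 Å, ≥ 6 residues apart), persistence across weighted frames,
  contact-set algebra (`"open & !closed"`), distance-pair tables,
  subpopulation boxing, and 2-D correlation maps.
* **Synthetic-data generators** for every input, with embedded ground
  truth, so the full chain is testable without instrument data.

## Worked example

Generate a three-population burst ensemble (the closed/open/extended
scenario: mean efficiencies 0.24/0.59/0.87 at weights 0.3/0.5/0.2,
with 15% donor-only molecules), build the filtered histogram, and
decompose it:

```r
library(fretscape)
library(tibble)

sim <- make_burst_dataset(
  tibble(mean_e = c(0.24, 0.59, 0.87), weight = c(0.3, 0.5, 0.2)),
  n_bursts = 2000, donor_only_fraction = 0.15, seed = 7)

h <- sim$photons |> detect_bursts(threshold = 50) |> build_histogram()
h
#> <e_histogram> 1484 bursts in 50 bins on [-0.10, 1.10]

fit <- fit_mixture(h, k = 3)
tidy(fit)
#> # A tibble: 3 × 5
#>   component  mean  width fraction mean_se
#>       <int> <dbl>  <dbl>    <dbl>   <dbl>
#> 1         1 0.243 0.0492    0.286 0.00244
#> 2         2 0.592 0.0551    0.505 0.00206
#> 3         3 0.873 0.0346    0.209 0.00205
```

The stoichiometry filter has removed the donor-only bursts (1484 of
2000 retained ≈ the double-labelled fraction that clears the 50-photon
threshold), and the three planted populations are recovered within
counting error. `autoplot(fit)` overlays the fitted components on the
histogram.

Fit a three-state folding titration (unfolded → intermediate → folded,
planted stabilities −5.6 and −8.3 RT) from noisy population fractions:

```r
tm <- thermo_model(c("U", "I", "F"),
                   dg0 = c(I = -5.6, F = -8.3),
                   m   = c(I = 3.0,  F = 4.15))
series <- make_titration_dataset(tm, seq(0, 6, length.out = 16),
                                 noise_sd = 0.03, seed = 7)
tfit <- fit_titration(series)
tidy(tfit)
#> # A tibble: 4 × 5
#>   term  estimate std_error conf_low conf_high
#>   <chr>    <dbl>     <dbl>    <dbl>     <dbl>
#> 1 dg0_I    -6.27     0.982    -8.19     -4.34
#> 2 dg0_F    -9.00     0.988   -10.9      -7.07
#> 3 m_I       3.24     0.443     2.37      4.11
#> 4 m_F       4.47     0.460     3.57      5.38
tfit$midpoints
#> # A tibble: 2 × 2
#>   transition c_half_m
#>   <chr>         <dbl>
#> 1 U-I            1.94
#> 2 U-F            2.01
```

Both planted free energies sit inside their 95% intervals and the
unfolding midpoint lands at ≈ 2 M denaturant. Finally, ask whether a
population is rigid or dynamic: a worm-like chain with persistence
length 2.5 nm and contour length 7.7 nm predicts

```r
lifetime_point(distance_model("wlc", lp = 2.5, lc = 7.7), r0 = 5.4)
#> # A tibble: 1 × 4
#>   mean_e rel_lifetime static_line excess
#>    <dbl>        <dbl>       <dbl>  <dbl>
#> 1  0.575        0.557       0.425  0.132
```

— a relative donor lifetime well above the static line (`excess`
0.132), the fingerprint of a dynamic distance ensemble; a rigid model
would sit exactly on the line.

`run_pipeline(config)` chains these stages from a single structured
config and writes CSV/JSON outputs with a manifest that reproduces the
run byte-identically.

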