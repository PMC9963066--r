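---
title: "Models and methods behind fretscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fretscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretscape)
library(tibble)
```

fretscape analyses confocal single-molecule FRET experiments on
conformationally heterogeneous proteins — systems such as monomeric
apolipoprotein E, where a folded core coexists with partially
structured tails and the observable is a mixture of conformational
populations rather than a single structure. This vignette explains the
models the package implements, the parameters that matter, and the
design decisions taken where the underlying methodology leaves choices
open.

## Burst analysis

A freely diffusing labelled molecule crossing the confocal volume
produces a **burst** of photons. Bursts are found by an all-photon
sliding criterion: photons separated by more than `max_gap_s` (default
100 µs) never share a burst, and a cluster is kept only if it contains
at least `threshold` (default 50) donor-excitation photons. These
defaults are conventional for confocal burst analysis; both are
exposed because real instruments vary.

Each burst's transfer efficiency is the corrected acceptor fraction

$$E = \frac{n_A'}{n_A' + \gamma\, n_D'},$$

where primes denote counts after background subtraction (per-channel
rate × burst duration), donor→acceptor crosstalk, and acceptor
direct-excitation corrections, and γ compensates detection-efficiency
and quantum-yield imbalance. All corrections default to neutral
(γ = 1, zero rates), under which E reduces exactly to the raw
proximity ratio $n_A/(n_A+n_D)$; instrument values belong in a
`fret_setup()`. Efficiencies are clipped to the reporting range
[−0.1, 1.1] so background over-subtraction remains visible instead of
crashing the pipeline.

Pulsed interleaved excitation adds acceptor-excitation photons, giving
the stoichiometry ratio $S = (n_D+n_A)/(n_D+n_A+n_{AA})$. Molecules
carrying both dyes sit near S ≈ 0.5; donor-only molecules at S ≈ 1.
The default histogram filter S ∈ [0.3, 0.7] follows standard PIE
practice and removes incompletely labelled species.

**Mixture decomposition.** Efficiency histograms are decomposed into K
Gaussian populations by Poisson maximum likelihood on the binned
counts. The peak width is bounded below by the shot-noise width
$\sqrt{E(1-E)/\bar n}$ at the histogram's mean burst size $\bar n$: a
real population can never appear narrower than photon-counting
statistics allow, and the floor prevents the optimiser from chasing
single-bin spikes. Whether experimental mixture widths should be free
or shot-noise-pinned is analysis-dependent; we pin the floor and leave
the excess width free, which covers both regimes. Components are
reported sorted by ascending mean so output ordering is deterministic.
Means may be fixed across conditions (`fixed_means`) for
condition-linked analyses.

**Burst variance analysis.** Within a burst, consecutive windows of
`window_photons` donor-excitation photons each yield a windowed E; a
static conformation keeps the across-window standard deviation inside
the binomial envelope $\sqrt{E(1-E)/n_\text{win}}$, while
conformational exchange on the burst (millisecond) timescale produces
excess variance. Bursts shorter than two windows are skipped and
counted.

## Distance models and lifetime diagnostics

Transfer efficiency and inter-dye distance are linked by the Förster
relation $E = 1/(1+(r/R_0)^6)$. The default Förster radius is
$R_0 = 5.4$ nm, a standard literature value for the Alexa 488/594
pair; it is a `fret_setup()` field because the calibrated value is
instrument- and solvent-dependent. Distances are label-site distances;
no accessible-volume dye cloud is modelled (a scalar linker offset is
the only hook), which is a known limitation when comparing against
structure-based predictions.

For dynamic populations the observed mean efficiency is the
distance-distribution average $\langle E\rangle = \int P(r)E(r)\,dr$,
computed by adaptive quadrature (`integrate`, rel. tol. 1e-9) and
cross-checked in the test suite against dense Riemann sums at 1e-4.

The **worm-like chain** density uses the standard closed-form
interpolation for a semiflexible chain's radial end-to-end density,

$$P(r) \propto r^2\,\bigl(1-(r/l_c)^2\bigr)^{-9/2}
  \exp\!\Bigl(-\frac{3\,l_c}{4\,l_p\,[1-(r/l_c)^2]}\Bigr),$$

normalised on $(0, l_c)$. It has the right limits — finite support at
the contour length, Gaussian-chain behaviour for $l_c \gg l_p$ — and
its second moment tracks the exact worm-like chain result
$2 l_p l_c[1-(l_p/l_c)(1-e^{-l_c/l_p})]$ to about 1% in the
flexibility range of interest (the suite asserts 4% across a wide
grid). The kernel is evaluated in log space with a constant exponent
shift; otherwise the $(1-x^2)^{-9/2}$ pole against the essential
singularity of the exponential produces Inf × 0 near full extension,
and stiff trial parameters underflow the normalisation constant during
fitting.

With this density, the fitted N-terminal-tail parameters
$l_p = 2.5$ nm, $l_c = 7.7$ nm give

```{r wlc}
mean_efficiency(distance_model("wlc", lp = 2.5, lc = 7.7), r0 = 5.4)
```

i.e. ⟨E⟩ ≈ 0.57 at $R_0 = 5.4$ nm — somewhat below the measured
population mean of ~0.61 such parameters are usually quoted with.
The gap closes at $R_0 \approx 5.6$ nm, so it most plausibly reflects
the calibrated Förster radius (and dye-linker treatment) of the
original analysis rather than the chain model; we report what the
stated inputs actually produce instead of adjusting either. Converting
sequence separation to contour length uses 0.38 nm per residue, the
common polypeptide convention: for the 81-residue segment between
labels at positions 5 and 86, $7.7 / (81 \times 0.38) \approx 25\%$,
the signature of residual structure in that segment.

**Static and dynamic lifetime lines.** The donor lifetime averages
over nanoseconds, the burst efficiency over milliseconds. A rigid
distance satisfies $\tau/\tau_0 = 1 - E$ (the static line); a
fluctuating distance gives
$\tau/\tau_0 = \langle(1-E)^2\rangle/\langle 1-E\rangle =
(1-\langle E\rangle) + \mathrm{Var}(E)/(1-\langle E\rangle)$, which
lies on or above the static line for *every* distribution
(Cauchy–Schwarz). The package computes the model-predicted point;
instrument-response deconvolution of measured lifetimes is out of
scope (lifetime handling is moment-based only).

## Denaturant titrations

State stabilities follow the linear free-energy model
$G_s(c) = \Delta G^0_s + m_s c$ in RT units, with the unfolded state
as reference. We adopt the signed convention ΔG⁰ = G_state − G_U, so
folded-stable states are *negative* (−8.3 RT is "8.3 RT more stable
than unfolded") and m-values are positive when denaturant
destabilises. Populations are Boltzmann weights, evaluated via
log-sum-exp so extreme stabilities cannot overflow. Transition
midpoints are the closed form $c_{1/2} = -\Delta G^0/m$.

`fit_titration()` does weighted least squares on observed fractions.
Because fractions sum to 1 at each condition, the reference state's
rows carry no independent information and are excluded from the
objective — including them double-counts observations and makes the
parameter covariance spuriously tight (we verified coverage of the
Wald intervals degrades from ~99% to ~85% in simulation if they are
kept). Optimisation is multi-start (a data-driven log-ratio start,
a generic folding-scale start, and a damped variant) because the
three-state objective has a degenerate basin in which a state is
expelled and its parameters diverge; solutions with |parameters| >
30 RT are treated as that basin. A weakly identified state — one whose
fitted population never exceeds 10% at any measured concentration — is
flagged. Percentile bootstrap intervals (residual resampling) are
available; the default of 1000 resamples follows common practice and
the seed is recorded.

The model-free companion is the Boltzmann inversion
$\Delta G = -\ln(p_b/p_a)$ from a pair of observed fractions. Note a
60/40 split gives 0.41 RT by this formula; published free-energy gaps
for such splits sometimes derive instead from a fitted zero-denaturant
extrapolation and can differ — the package exposes the direct
log-ratio and the fitted ΔG⁰ separately and does not reconcile them.

## Kinetic Monte Carlo photon simulation

`simulate_photons()` turns a Markov state model into photon streams.
The conformational state advances by the transition matrix once every
$\tau_\text{lag} \times \text{rescale}$ nanoseconds; photon arrivals
are Poisson; each donor-excitation photon goes to the acceptor channel
with the current state's efficiency (per-state distances through the
Förster relation, or fixed-E for controls). Shot noise and kinetic
averaging therefore emerge from the mechanism itself rather than being
added: dwell times ≫ burst duration give one histogram peak per state,
dwell times ≪ burst duration collapse the histogram onto the
population-weighted mean, and the suite asserts both limits
numerically. The default rescale factor of 225 reflects the time
compression commonly needed to map fast-sampled model dynamics onto
experimental photon timescales; it is a tunable configuration value.

Simulation defaults — 10⁵ photons/s during a burst, 1 ms bursts, an
equal acceptor-excitation rate (so simulated stoichiometries pass the
standard filter), 5 ms inter-burst gaps — are documented assumptions
chosen to resemble typical confocal conditions, not fitted values.

`estimate_msm()` builds the reverse path: transition counts at a lag,
symmetrised as $(C + C^\top)/2$ — which enforces detailed balance by
construction — then row-normalised, with the stationary vector from
power iteration. Unvisited states are dropped with a warning, as is a
reducible (block-disconnected) result. Histograms are compared by the
per-bin L1 distance of count-normalised histograms: symmetric, zero
iff identical, at most 2.

## Ensemble contacts and subpopulations

Residue-level conformer ensembles (e.g. from multi-model PDB files,
one MODEL per frame) are analysed with a literal contact definition:
two residues are in contact when their heavy-atom centres of mass are
closer than 3 Å and they are at least six residues apart in sequence,
implemented as $j - i \ge 6$ so the boundary case is *included*, and
with a strict `<` on the distance. Both readings (all-atom COM,
counting intervening residues) are defensible; ours is documented here
and pinned by tests. Contact search uses a cell-list spatial index and
is tested for exact agreement with an all-pairs scan on hundreds of
random frames. Persistence is the weighted frame fraction containing
the contact; frame weights default to uniform and accept Markov-model
stationary populations.

Contact sets support logical set algebra over named sets
(`"open & !closed"`), plus a three-set classifier for the
shared/unique classes used when contrasting closed, open, and extended
subpopulations. Subpopulations themselves are defined by axis-aligned,
non-overlapping boxes in a distance-pair plane; assignment partitions
frames (assigned + unassigned = total) and 2-D distance-pair density
maps have marginals that equal the 1-D histograms to machine
precision.

## Synthetic data and what passing tests mean

Every input the analysis consumes has a generator with embedded ground
truth: burst ensembles (log-normal burst sizes, median 80 photons, a
realistic spread; binomial counts at each population's mean
efficiency; donor-only molecules; acceptor-excitation photons for
stoichiometry), titrations (Gaussian fraction noise truncated to
[0, 1] then renormalised — slightly biased toward the interior near
the boundaries, as any bounded scheme is), toy coordinate ensembles
with planted contacts and planted distance-pair clusters, and
exponential-dwell Markov models with sampled trajectories. Generators
are deterministic in (specification, seed).

The generators emulate shot noise, mixture structure, incomplete
labelling, and kinetic averaging. They do **not** emulate dye
photophysics (blinking, quenching), diffusion-limited transit-time
variation (bursts have fixed duration at constant rate by default),
instrument response functions, or real force-field conformational
ensembles. Passing recovery tests therefore demonstrates correctness
of the estimators under the stated noise models, not robustness to
every artefact of real data.

## Problem sizes and numerical choices

The shipped tests use burst ensembles of 300–5000 bursts, titrations
with 16 concentrations and 100 replicate fits, Markov trajectories of
10⁵ steps, and 200-frame random-geometry checks — sizes chosen so each
property is measured well inside its Monte Carlo error while the whole
suite stays fast. Quadrature tolerances are 1e-9 (relative) with a
1e-4 cross-check against brute-force sums; mixture and titration
optimisers use BFGS with reltol 1e-12 and multi-start; ties in
component labelling are broken by ascending mean. Degenerate inputs
(empty streams, empty retained sets, single-state models, zero-noise
generators) are exercised explicitly and return well-defined objects
rather than errors wherever a valid empty result exists.

## Known limitations

* No full photon-distribution analysis: mixture peaks are Gaussian
  with a shot-noise floor, adequate for population fractions but not
  for extracting dynamics from histogram shape.
* Lifetimes are moment-based; no TCSPC deconvolution.
* Structure-based E predictions anchor on Cβ positions; real dye
  clouds shift distances by several Å.
* The pipeline's stoichiometry correction for direct excitation uses
  raw acceptor-excitation counts, the usual first-order treatment.
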