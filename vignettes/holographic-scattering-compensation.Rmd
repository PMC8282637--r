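---
title: "Holographic scattering compensation: model, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Holographic scattering compensation: model, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dashsim)
```

## The problem

Two-photon fluorescence imaging deep inside tissue is limited by
scattering: the excitation wavefront is scrambled before it reaches the
focal plane, the focus degrades into speckle, and the nonlinear signal
(which scales as intensity squared, $|E|^4$) collapses. Indirect
wavefront sensing counteracts this with a spatial light modulator (SLM)
in a pupil-conjugate plane: a sequence of test wavefronts is displayed,
the fluorescence signal is recorded, and a correction phase mask is
inferred without any wavefront sensor or guide star.

`dashsim` is a self-contained numerical testbed for this problem. It
implements DASH — a continuously updating algorithm in which every
phase-stepped mode measurement immediately updates a complex hologram —
alongside the stepwise interferometric methods F-SHARP and IMPACT and
the intensity-feedback baselines CSA, PA and a genetic algorithm, all
on one shared forward model and one shared measurement axis.

## Forward model

The model chain is:

1. **SLM**: an $n_{\mathrm{slm}} \times n_{\mathrm{slm}}$ grid of
   programmable phases. Each SLM pixel maps onto an integer block of
   the finer scatterer grid (nearest-neighbour upsampling); the
   emerging pupil field has unit modulus.
2. **Scatterer**: a phase-only white-noise screen on the
   $n_{\mathrm{scat}} \times n_{\mathrm{scat}}$ grid in the same
   (Fourier) plane, drawn uniformly from $[0, 2\pi)$ with a fixed seed.
   Phase-only elements conserve power exactly.
3. **Propagation**: a unitary discrete Fourier transform (optionally
   zero-padded by `pad_factor`) takes the aberrated pupil field to the
   focal plane; power bookkeeping is exact to machine precision.
4. **Sample**: a homogeneous fluorescent layer integrates $|E|^4$ over
   the focal grid (`sample_model = "layer"`), or a point-like emitter
   reads $|E|^4$ at one pixel (`"point"`).
5. **Detector**: ideal photon counting — expected count equals
   `scale * signal` with the scale calibrated so that the *uncorrected*
   configuration yields `i0` expected photons per measurement; the only
   noise is Poisson shot noise. A `noiseless` switch returns expected
   counts directly for algorithmic analysis.

The benchmark regime uses $N_{\mathrm{scat}} = 1024$ scattering pixels
(`n_scat = 32`), $N = 256$ correctable pixels (`n_slm = 16`, with the
full $16 \times 16$ grating basis), and initial signal levels of 1000
or 100 photons per measurement.

### Enhancement metric

The enhancement $\eta$ of a correction mask is its noise-free
two-photon signal relative to the flat mask. Two readings are
supported: `eta_metric = "peak"` (default) compares the **maximum**
pixelwise two-photon signal over the focal plane — the analogue of
reading the enhancement off an image maximum, which is how signal
enhancement is conventionally defined on images — while `"total"`
compares the layer-integrated signal the detector actually records.
The distinction matters: the integrated ratio has a hard ceiling of
roughly 11 in the benchmark regime (a 256-mode correction of a
1024-pixel white-noise screen), whereas the peak ratio reaches several
hundred, which is the scale on which the algorithms visibly separate.
Detected photons are always drawn from the integrated signal; only the
reported $\eta$ changes.

## The algorithms

### DASH

DASH holds a complex reference field $C$ on the SLM grid, initialised
flat (phase zero, unit modulus). For each grating mode $M_n$ (integer
spatial frequencies $k_x, k_y$, probed in a low-to-high spiral order)
it displays the phase-only hologram

$$\Phi_{n,p} = \arg\!\left(\sqrt{1-f}\,\frac{C}{|C|}
  + \sqrt{f}\, e^{i(M_n + \varphi_p)}\right),
  \qquad \varphi_p = p\,\frac{2\pi}{P},$$

records the $P$ photon counts, and estimates the interference term's
amplitude $a$ and phase $\phi$ as the first discrete Fourier
coefficient of $\sqrt{\text{counts}}$. The hologram is updated
immediately, $C \leftarrow C + a\,e^{i(M_n - \phi)}$, and the next mode
is probed against the improved reference. The power split $f = 0.3$ is
robust across samples and signal levels; $P = 5$ phase steps are the
protocol default ($P = 3$ is the mathematical minimum, but the
hologram's second diffraction order then aliases onto the estimation
bin — see below). The zero-frequency mode is skipped during the first
iteration only, where it is indistinguishable from the reference; this
reproduces the protocol measurement counts (1120 exposures after one
iteration of the 225-mode, 5-step protocol; 10,120 after nine).

The update uses the raw first-harmonic amplitude. Because only
$\arg C$ is ever displayed, the overall scale of $C$ is immaterial;
what matters is the ratio of the flat prior to the measured updates.
Raw amplitudes are of order $0.3\sqrt{I_0}$, so real measurements
dominate the unit prior within a few modes and the correction forms in
the first pass through the basis. We note — as a genuine sensitivity of
the method — that the first-iteration enhancement depends strongly on
this prior-to-update ratio; the package uses the literal update
equation with no additional normalisation parameter.

### F-SHARP

F-SHARP measures the same per-mode quantities with the same estimator,
but through an external interferometer: the SLM-corrected beam (power
$1-f$) is the static probe and a scanned tilted plane wave (power $f$)
is superposed on it exactly in the focal plane, with a stepped global
phase. The correction is *replaced* once per iteration,
$C \leftarrow \sum_n a_n e^{i(M_n - \phi_n)}$, so its enhancement trace
is piecewise constant and steps at iteration boundaries. Because the
scan arm modulates the full complex field, F-SHARP is free of the
phase-only composition error; on a point-like target one noiseless
iteration reproduces the conjugation mask exactly (a property the test
suite checks).

### IMPACT

IMPACT is the common-path sibling: the SLM pixels are split into two
checkerboard halves, the static half displays the current correction
and acts as the reference wave, and the modulated half carries unique
modulations whose demodulated phases replace that half's correction;
the halves then swap. Two multiplexing schemes are provided:

* `"time"` (default): the modulated half is probed mode-by-mode with
  the restricted grating set. On a checkerboard half, gratings $k$ and
  $k + (n/2, n/2)$ render identically, so exactly $n^2/2$ distinct
  restricted gratings exist — one unique spatial frequency per
  modulated pixel. This scheme shares F-SHARP's interference contrast.
* `"frequency"`: all modulated pixels ramp simultaneously, each at its
  own temporal tag frequency, and a DFT of $\sqrt{\text{signal}}$
  separates the pixels. The tag plan places the signal band just above
  $T/3$ of a window of $T = 6(n_{px}+1)$ samples so that, for a
  *two-photon* signal, pairwise sum and difference beats and the
  conjugate band all stay out of band; each window also uses random
  ramp start phases (demodulated out) so the modulated half never
  coherently re-aligns with the correction inside a window, which
  otherwise injects a broadband bias. Even so, the per-pixel
  interference contrast is a factor $\sim\sqrt{N/2}$ below the
  mode-multiplexed schemes, and in the photon-starved benchmark regimes
  this variant stalls — which is why it is not the default.

### CSA, PA, GA

The continuous sequential algorithm steps each SLM pixel's phase
through $P$ offsets and applies the first-harmonic optimum
immediately, visiting pixels cyclically. The partitioning algorithm
steps a common offset on a fresh random half of the pixels and applies
the best *measured* offset (zero is always among the candidates, so a
noiseless run never loses signal). The genetic algorithm follows
common wavefront-shaping practice: population 30, elite fraction 0.25,
rank-proportional parents, pixelwise crossover, mutation decaying from
0.1 to 0.013 with a 650-measurement constant. Each mask's fitness is
measured *once*, when the mask is created; at low photon counts this
single-shot fitness is exactly what breaks genetic search (a lucky
upward fluctuation sticks to a mediocre mask — the winner's curse), and
the simulated GA accordingly stalls at $I_0 = 100$ while still gaining
at $I_0 = 1000$.

## Measurement bookkeeping and benchmarking

Every detector exposure increments the measurement counter $m$ by one
(a phase step, one time sample, one fitness evaluation), so all traces
are comparable on one axis; `measurement_count()` also implements the
mode-counting convention in which each measured mode counts once
(225 modes over nine iterations give 2025 mode-measurements).
`run_benchmark()` runs each algorithm on the same seeded scatterers
(per-trial seeds derive deterministically from one master seed, with
independent photon-noise substreams per algorithm, hash-checked for
fairness) and aggregates boundary enhancements into mean ± SEM.
Convergence is declared at the first iteration boundary reaching 90%
of the final plateau (the mean of the last two boundaries — a
deliberately simple criterion, since no numerical definition of
convergence exists in the literature for these traces).

At desk scale (one CPU) the full two-regime benchmark — ten trials,
twenty iterations, three algorithms at $I_0=1000$ and six at
$I_0=100$ — takes about six minutes; these are also the problem sizes
used by the test suite and the acceptance script.

## What the benchmark shows

With ten white-noise scatterers, twenty iterations and $P = 5$:

* At $I_0 = 1000$, DASH converges by roughly iteration 3 and F-SHARP
  around iteration 10, to final enhancements that agree within their
  mutual standard errors; DASH ends its first iteration one to two
  orders of magnitude above F-SHARP's still-uncorrected display.
* At $I_0 = 100$, DASH and F-SHARP converge around iteration ten
  (median detected iterations 9 and 12), while CSA, PA and the GA stay
  within a few percent of unity — the photon-starved regime in which
  intensity-feedback methods fail.
* Reaching half of the common final enhancement costs F-SHARP roughly
  1.8 times the measurements and 1.5 times the detected photons that
  it costs DASH at $I_0 = 100$.

## Known limitations

* **Frequency-multiplexed IMPACT under photon starvation.** All four
  IMPACT formulations we implemented (frequency ramps, residual
  dither, absolute probing, f-weighted superposition) are verified
  mechanically — noiseless runs converge, and point-sample runs
  converge immediately even at $I_0 = 1000$ — but on the homogeneous
  layer at $I_0 \le 10^3$ the per-cycle return map has a stable fixed
  point near $\eta \approx 1.1$ and the method does not lift off. The
  half-aperture common-path probe lacks F-SHARP's full-aperture
  replace-toward-one-target gain exactly in the critical
  $\eta \in [1.1, 2]$ range. The benchmark therefore reports IMPACT as
  non-converging in these regimes, and the equivalence of IMPACT and
  F-SHARP holds in this package only where the localized-signal
  assumption behind the pixel-tagging readout is met.
* **Cold starts from perfectly focused states.** Probing an already
  perfect correction through the phase-only composed hologram is not
  exactly signal-free: diffraction orders of the hologram whose
  spatial frequencies collide on the discrete lattice (block-staircase
  images; $P$-aliased harmonics; padded-aperture sinc sidelobes under
  the $|E|^4$ weighting) leave a symmetric first-harmonic residue of
  0.1–6% modulation depth per mode. Each update is small, but updates
  feed back on the reference, and over a full pass an initially
  perfect mask drifts substantially. Converged corrections reached
  *from speckle* are stable — the accumulated hologram makes late
  updates relatively small — so the benchmark plateaus are unaffected;
  but an unaberrated system is not a fixed point of the iteration, and
  the corresponding idealised checks are asserted at the measurement
  level (a corrected state yields vanishing modulation depths for
  collision-free modes) rather than at the trajectory level.
* **What passing tests do and do not show.** The generator emulates
  fully developed, static, white-noise scattering with an ideal
  detector. Real tissue has structured (low-order-dominated)
  aberrations, decorrelates in time, bleaches, and is imaged through
  apodised optics; none of that is modelled. Structured scatterers
  generally favour low-order-first probing (the spiral ordering), so
  white noise is the conservative case for DASH's early iterations.

## Numerical choices

Unitary DFTs keep power bookkeeping exact (conservation is tested to
$10^{-10}$). The truncated DFT factor matrices are cached and applied
as two small complex matrix products, which at these grid sizes is
about twice as fast as an FFT of the padded grid. Degenerate phasors
(exact two-beam cancellation in the hologram; zero-amplitude estimator
input) take phase zero by convention, with a numerical tolerance. The
focal grid is padded by `pad_factor = 2` by default so the layer
integral resolves sub-speckle structure. All randomness derives from
one master seed through labelled substreams, and seeded reruns are
bit-identical.
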