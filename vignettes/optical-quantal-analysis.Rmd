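---
title: "Optical quantal analysis of neuromodulator release: models and methods"
author: "fluoQuanta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optical quantal analysis of neuromodulator release}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluoQuanta)
```

## The measurement problem

Genetically encoded transmitter indicators (GEIs) such as the GRAB
serotonin and oxytocin sensors convert the extracellular concentration of
a neuromodulator into fluorescence. Imaged at 10 Hz with wide-field
optics, electrically evoked release appears as punctate dF/F0 hotspots on
the somatic membrane. From such movies this package estimates, per release
site and per neuron:

* the **spatial spread length constant** λ of the single-exponential
  radial decay of peak dF/F0 around a release center (micrometers);
* the **quantal size** q (dF/F0 per released vesicle), **release
  probability** Pr, and **quantal content** from low-frequency (0.1 Hz)
  trial trains;
* the **readily releasable pool** (RRP) and **vesicular refilling rate**
  from long (1,920-pulse, 16 Hz) trains, after removing the slow sensor
  off-rate (τ_off = 8.96 s for the 5-HT sensor, 3.15 s for the OXT
  sensor).

Because raw movies of this kind are rarely shared, the package carries a
full forward model (`simulateReleaseTrain()`, `renderMovie()`) whose
ground truth exercises every estimator by parameter recovery.

## The forward model

Release at hotspot *e* with center *c* and spread constant λ contributes

F(p, t) = F0(p) · [1 + Σ_e k_e · q · exp(−d(p, c_e)/λ) · h(t − t_e)]

with h the unit-peak sensor impulse response
h(t) = (1 − e^{−t/τ_rise}) e^{−t/τ_off}, which peaks at
t\* = τ_rise · ln(1 + τ_off/τ_rise) (0.451 s for τ_rise = 0.1 s,
τ_off = 8.96 s). The frame is then multiplied by a two-term-exponential
bleaching factor, blurred by an isotropic Gaussian PSF, shifted by
per-frame drift, and degraded by Poisson photon noise (gain-scaled) plus
Gaussian read noise before 16-bit quantization.

Defaults and the reasoning behind them:

* **Pixel size 0.1625 µm** — a 40× objective with 6.5 µm camera pixels.
* **PSF σ = 0.25 µm** — wide-field blur is instrument-specific; σ is a
  configuration knob and every recovery test states the value it used.
* **τ_rise = 0.1 s** — real sensors rise quickly but not instantly; the
  off-rate correction deliberately ignores the rise (see below), and the
  simulator's non-zero rise quantifies the resulting bias, which the
  tests show is negligible at 10 Hz sampling.
* **Basal fluorescence** F0 is spatially heterogeneous (CV 0.3 by
  default), emulating variable sensor expression.

### Vesicle pool dynamics

Per stimulus, release succeeds with probability Pr; on success the number
of quanta is drawn from a configurable distribution truncated to the
integer pool available. The pool then refills. Two refill models are
provided:

* **deterministic** (default): refill accrues continuously at
  `refillRate` per stimulus into a recruitment accumulator; each time the
  accumulator crosses one, a whole vesicle joins the pool (capped at the
  RRP). The accumulator starts at a uniformly random phase so that
  recruitment cycles are desynchronized across synapses, as they would be
  in a stationary preparation. With a zero phase the conservation bound
  released(n) ≤ RRP + n · refillRate is exact; the random phase can relax
  it by at most one vesicle.
* **stochastic**: memoryless Bernoulli recruitment at the same mean rate.

The deterministic-with-random-phase default matters for the RRP
back-extrapolation. If every synapse's refill clock restarts at zero when
its pool drains (phase 0), the first recruited vesicle arrives a full
period late at every synapse and the back-extrapolated intercept
underestimates the true pool by about half a vesicle per synapse — a
bookkeeping artifact, not physiology. A random phase (or memoryless
recruitment) restores the stationary picture in which the late-phase line
extrapolates back to the full pool. The tiny refill variance reported for
real neurons favors near-deterministic recruitment over a Poisson model,
which is why deterministic-with-random-phase is the default.

Whole-cell simulations distribute the configured cell RRP over synapses
as integer vesicle counts (at least one per synapse, the remainder
multinomially with heterogeneous weights); vesicle pools are integers in
nature, and fractional per-synapse pools would strand unreleased residue
that no estimator could see.

## The processing chain

`preprocessMovie()` applies, in this fixed order: **alignment** →
**deconvolution** → **baseline correction** → **denoising** →
**background subtraction**, then computes dF/F0. The order is recorded in
every result.

* **Alignment** minimizes the mean squared intensity difference over
  translations (coarse-to-fine grid, then golden-section sub-pixel
  refinement; at most 200 iterations per frame). Frames whose
  post-alignment correlation with the reference is poor are flagged, not
  dropped. Movement diagnostics use a demons-style dense displacement
  field (3 scales, 20 iterations per scale); the AMMS statistic is the
  maximal change of the mean per-pixel displacement during stimulation.
* **Landweber deconvolution** iterates
  x ← max(0, x + α Hᵀ(y − Hx)) against the PSF with reflective
  boundaries. The step α defaults to 1/L (L estimated by power
  iteration), which guarantees a monotone residual; 50 iterations is the
  default operating point. Deconvolution amplifies pixel noise; the
  denoising stage that follows is what keeps maximal-projection maps
  usable (see below).
* **Baseline correction** fits a two-term exponential to the first and
  last control windows of every pixel's trace and multiplies the whole
  sequence by F_base(t₁)/F_base(t); mid-movie frames are corrected by
  evaluating the fitted curve at their times. Divergent fits fall back to
  a single exponential, then to a flat baseline, with the fallback mode
  recorded per pixel.
* **Denoising** is LOWESS along time, per pixel (default span 15
  frames); a locally linear and a locally exponential model are both
  evaluated and the lower-residual one kept.
* **Background** is the per-frame mean over a non-responsive ROI,
  subtracted uniformly.
* **dF/F0** uses the per-pixel pre-stimulus mean as F0 and masks pixels
  with F0 below 5% of the median — those contain essentially no sensor.

## Hotspot detection and spread fitting

`maxDffMap()` projects the per-pixel maximum dF/F0 over the analysis
window; `detectHotspots()` thresholds it (default 5× the pre-stimulus
pixel-noise SD), clusters supra-threshold pixels with DBSCAN (eps 3 px,
minPts 5 — the clustering parameters are exposed, as no canonical values
exist), and takes each cluster's argmax pixel as a release center.
Overlapping clusters are split by iteratively subtracting the dominant
site's fitted exponential footprint and re-examining the residual.

`radialProfile()` averages the map over full annuli (1-pixel bins);
a directional-sector restriction is available for anisotropic
neighborhoods, and profiles that would run into a neighboring center are
truncated at half the inter-center distance and flagged.
`fitSpread()` fits A·exp(−r/λ) by nonlinear least squares.

Three estimator choices deserve comment, because the maximal projection
of noisy traces is a biased statistic:

* **Bin weighting.** Annuli at larger radii contain more pixels; the fit
  weights each bin by its pixel count so that every pixel carries equal
  information. Unweighted fits over-weight the few central bins, where
  residual PSF blur concentrates, and inflate λ.
* **Offset freeing.** The maximum over W frames of zero-mean noise is
  positive on average, adding a nearly uniform floor to the profile. The
  package's default fit pins the offset at zero (fits of clean profiles
  decay to zero); for max-projection maps the recovery workflows free the
  offset so the floor is absorbed rather than soaked into λ. A profile
  radius of ~3.5 µm gives the fit enough tail to separate the offset
  from the decay.
* **Sub-pixel centers.** The argmax pixel is up to half a pixel away
  from the true center, which flattens the profile apex;
  `radialProfile(refineCenter = TRUE)` refines the center by an
  intensity-weighted centroid over a 2-pixel disk before computing
  distances.

With 50 Landweber iterations the blur is not fully inverted — the
exponential cusp carries high frequencies that converge slowly — so a
small upward bias in λ remains (about 1–3% at the defaults, versus
~25–65% without deconvolution). The recovery tests quantify exactly
this: a fixture with λ = 0.74 µm, σ_PSF = 0.25 µm and peak SNR 10 is
recovered to within a few percent after deconvolution, and
λ̂(deconvolved) ≤ λ̂(raw) on every blurred fixture.

## Quantal analysis

`extractTrialAmplitudes()` measures, per 0.1 Hz trial, the post-stimulus
peak minus the local pre-stimulus baseline; trial independence holds
because the inter-stimulus interval (10 s) exceeds the slowest sensor
decay. Failures are classified in two passes: first against 2× the noise
SD, then — once a quantal size exists — against q/2.

`fitQuantalPeaks()` fits a Gaussian mixture whose component means are
pinned to 0, q, 2q, …, Kq: q is grid-searched (1% of the amplitude range)
and refined by EM under the spacing constraint; K is chosen by BIC over
1..5 with ties going to the smaller K; component variances follow
σ_k² = σ0² + k·σ1² (σ1 estimable or pinned to zero). Fitting always uses
raw amplitudes; histograms are for display only.

Because "quanta per response" is ambiguous between per-stimulus and
per-success conventions, `summarizeQuantal()` reports both: mean quanta
over successes, and quantal content per stimulus (Pr × mean quanta). The
recovery targets use the per-success convention, and the output metadata
records it.

## Pool analysis

The measured train trace is modeled as Σ r_i · h(t − t_i) and the
per-pulse amplitudes r_i recovered by nonnegative least squares on the
bank of shifted impulse responses (`correctOffRate()`). At 16 Hz
stimulation sampled at 10 Hz the bank has more columns than frames, so
the solver adds a small ridge (10⁻⁶) and runs a projected-gradient
(FISTA) iteration warm-started from the frame-difference release
estimate; sub-frame apportionment of release between the 1.6 stimuli per
frame is not identifiable, but the cumulative curve — the quantity the
method consumes — is. Well-determined banks are solved exactly by the
active-set method, and the noiseless roundtrip is an identity to machine
precision. The correction deliberately ignores the sensor rise time, as
the trace model does; with τ_rise = 0.1 s and 10 Hz sampling the
resulting bias is within the recovery tolerances.

`cumulativeCurve()` accumulates r_i against stimulus number; the late
phase defaults to the final third of stimuli, with final-quarter and
final-half fits reported as window-sensitivity diagnostics.
`fitRRPRefill()` back-extrapolates the late-phase line: intercept = RRP
(dF/F0), slope = refill per stimulus; late-phase R² < 0.9 and negative
intercepts are flagged, never hidden. `toVesicles()` divides by q.

A caveat the simulations make explicit: at very low refilling rates
(~1 vesicle per 1,000 pulses) the late window contains only a handful of
recruitment events, so per-cell slope estimates are intrinsically noisy —
the same spread visible in published per-neuron refill values for such
conditions.

## Statistics

`mannWhitneyEffect()` and `kruskalEffect()` wrap the standard
nonparametric tests and add the field's effect sizes with bootstrap CIs.
The rank-biserial correlation is r = 1 − 2U/(n₁n₂) with U the statistic
for the first group (positive when the first group tends to lie below the
second — the convention is stated because published legends are not
consistent about sign). For Kruskal–Wallis, two epsilon-squared variants
are reported: (H − k + 1)/(n − k), labeled publication-compatible because
published values of this statistic reproduce under it, and the textbook
H/(n − 1). `epsilonSquaredFromP()` inverts a printed p value to recompute
the former from a legend's n, k and p alone.

## What the synthetic data do and do not show

The generator reproduces quantized release, pool depletion and refilling,
slow sensor kinetics, heterogeneous F0, bleaching, PSF blur, drift, and
shot/read noise. It does not model axial (3-D) optics, stimulus
artifacts, receptor saturation, non-rigid tissue deformation, or
multi-pool vesicle trafficking. Passing recovery tests therefore
demonstrate that the estimators invert the stated forward model at
realistic noise — not that every systematic error of a physical
microscope is corrected. In particular, real out-of-focus fluorescence
can broaden apparent spread constants in ways a 2-D PSF cannot capture.

## Problem sizes used in validation

The test suite runs scaled versions of the recovery studies (8 hotspots
per spread condition; 4 simulated cells per pool condition, 12 for the
near-zero-refill condition whose estimator variance demands the full
cohort); the acceptance script (`scripts/acceptance.R`) runs the
full-size versions: 20–25 hotspots per spread condition, 10 hotspots ×
100 trials for quantal recovery, and 13 + 12 cells × 1,920 pulses for
pool recovery.

```{r example, eval = FALSE}
## one synthetic hotspot, end to end
hs <- hotspotSpec(center = c(3.9, 3.9), lambda = 0.74, q = 0.5,
                  releaseProb = 1)
cfg <- simulationConfig(c(48, 48), nFrames = 40, stimTimes = 2,
                        hotspots = list(hs), psfSigma = 0.25,
                        gain = 3.3, readNoise = 10, seed = 1)
ev <- simulateReleaseTrain(hs, 2, seed = 1)
mov <- renderMovie(ev, cfg)$movie
pre <- preprocessMovie(mov, psf = gaussianPSF(0.25, 0.1625),
                       stages = c("deconvolve", "denoise"),
                       f0Window = c(1, 19))
m <- maxDffMap(pre$dff, c(21, 32), pixelSize = 0.1625)
roi <- detectHotspots(m, ampThreshold = 0.1)[[1]]
prof <- radialProfile(m, roi, maxRadius = 3.5, pixelSize = 0.1625,
                      refineCenter = TRUE)
fitSpread(prof, freeOffset = TRUE)
```
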