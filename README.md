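# fluoQuanta

Optical quantal analysis of neuromodulator release from fluorescence
imaging with genetically encoded indicators (GEIs).

Wide-field movies of GRAB-style transmitter sensors show evoked
serotonin, oxytocin or glutamate release as punctate dF/F0 hotspots.
`fluoQuanta` turns such movies — or synthetic movies with known ground
truth — into presynaptic physiology:

* **Spatial precision**: the spread length constant λ of the
  single-exponential radial decay `dF/F0(r) = A·exp(−r/λ)` around each
  release center (typically 0.6–0.8 µm), after Landweber deconvolution
  of the measured point spread function.
* **Quantal parameters**: quantal size q (dF/F0 per vesicle), release
  probability Pr = 1 − failures/trials, and quantal content, from 0.1 Hz
  trial trains via an equal-spacing Gaussian-mixture fit (components at
  0, q, 2q, …, Kq; K by BIC).
* **Vesicle pool dynamics**: readily releasable pool (RRP) and
  refilling rate from 1,920-pulse 16 Hz trains. The slow sensor decay
  (τ_off = 8.96 s for the 5-HT sensor, 3.15 s for the OXT sensor) is
  removed by nonnegative least squares on shifted impulse-response
  templates; the cumulative corrected release versus stimulus number is
  fit linearly over its late phase, whose back-extrapolated intercept is
  the RRP (in dF/F0, divided by q for vesicles) and whose slope is the
  refilling rate.

A full forward model (`simulateReleaseTrain()`, `renderMovie()`)
generates movies with stochastic quantized release, pool
depletion/refilling, sensor kinetics, photobleaching, PSF blur, drift
and shot/read noise, plus a ground-truth sidecar — every estimator in
the package is validated by parameter recovery against it.

## Worked example

One synthetic hotspot (λ = 0.74 µm, q = 0.5 dF/F0, PSF σ = 0.25 µm,
peak SNR ≈ 10), recovered end to end:

```r
library(fluoQuanta)

hs  <- hotspotSpec(center = c(3.9, 3.9), lambda = 0.74, q = 0.5,
                   releaseProb = 1)
cfg <- simulationConfig(c(48, 48), nFrames = 40, stimTimes = 2,
                        hotspots = list(hs), psfSigma = 0.25,
                        gain = 3.3, readNoise = 10, seed = 1)
ev  <- simulateReleaseTrain(hs, 2, seed = 1)
mov <- renderMovie(ev, cfg)$movie

pre <- preprocessMovie(mov, psf = gaussianPSF(0.25, 0.1625),
                       stages = c("deconvolve", "denoise"),
                       f0Window = c(1, 19))
m   <- maxDffMap(pre$dff, c(21, 32), pixelSize = 0.1625)
roi <- detectHotspots(m, ampThreshold = 0.1)[[1]]
prof <- radialProfile(m, roi, maxRadius = 3.5, pixelSize = 0.1625,
                      refineCenter = TRUE)
fitSpread(prof, freeOffset = TRUE)
#> SpreadFit: lambda = 0.7328 um (95% CI 0.6563-0.8093), A = 0.4323, R2 = 0.965
```

The generating constant 0.74 µm is recovered as 0.733 µm: the blur that
would otherwise inflate λ by ~30% has been deconvolved away.

Quantal analysis of simulated 0.1 Hz trials (q = 0.4, trial noise 0.08):

```r
set.seed(2)
k   <- sample(0:3, 100, TRUE, prob = c(0.21, 0.59, 0.16, 0.04))
amp <- k * 0.4 + rnorm(100, 0, 0.08)
fit <- fitQuantalPeaks(amp[k > 0])
fit
#> QuantalFit: q = 0.4061 dF/F0, K = 3, sigma0 = 0.0922 (n = 85, BIC = -22.5)

tab <- classifyFailures(data.frame(stim = 1:100, amplitude = amp),
                        noiseSd = 0.08, q = quantalSize(fit))
summarizeQuantal(tab, fit)[c("releaseProb", "meanQuanta", "maxQuanta")]
#> Pr = 0.85, mean quanta = 1.35, max = 3
```

`runPipeline()` chains preprocessing, hotspot detection, spread fitting
and the protocol-appropriate analysis (quantal or pool) into one result
bundle; `renderReport()` writes the CSV tables, heatmaps, per-hotspot 3-D
surfaces and a markdown summary. A thin command-line wrapper lives in
`inst/scripts/fluoquanta.R` (`simulate` and `pipeline` subcommands).

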