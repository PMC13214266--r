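# Shared fixture builders. Everything is generated in code at test time;
# no stored data.

PX <- 0.1625  # um per pixel (40x objective, 6.5 um camera pixels)

# One isolated hotspot movie: 2 s baseline, single release at t = 2 s,
# imaged at 10 Hz. Default optics/noise follow the recovery fixtures
# (Gaussian PSF sigma 0.25 um, Poisson noise at peak SNR ~ 10).
makeHotspotMovie <- function(lambda = 0.74, seed = 1, q = 0.5,
                             n = 48, noise = TRUE, psfSigma = 0.25,
                             centerPx = NULL, f0CV = 0.3) {
  set.seed(seed + 7000)
  if (is.null(centerPx)) centerPx <- c(n / 2 - 0.5, n / 2 - 0.5) +
    stats::runif(2, -0.5, 0.5)
  hs <- hotspotSpec(centerPx * PX, lambda, q, releaseProb = 1)
  cfg <- simulationConfig(c(n, n), nFrames = 40, stimTimes = 2,
                          hotspots = list(hs), pixelSize = PX,
                          frameRate = 10, f0Mean = 2000, f0CV = f0CV,
                          tauRise = 0.1, tauOff = 8.96,
                          psfSigma = psfSigma,
                          gain = if (noise) 3.3 else 0,
                          readNoise = if (noise) 10 else 0, seed = seed)
  ev <- data.frame(hotspot = 1, stim = 1, time = 2, success = TRUE,
                   quanta = 1L, amplitude = q, poolRemaining = Inf)
  out <- renderMovie(ev, cfg, keepClean = TRUE)
  out$centerPx <- centerPx
  out$lambda <- lambda
  out
}

# Spread constant recovered through the deconvolution chain (and, when
# rawToo, without it) from a single-hotspot movie.
recoverSpread <- function(mov, nIter = 50, rawToo = FALSE) {
  psf <- gaussianPSF(0.25, PX)
  fitFrom <- function(stages) {
    pre <- preprocessMovie(mov, psf = psf, stages = stages, nIter = nIter,
                           f0Window = c(1, 19))
    m <- maxDffMap(pre$dff, c(21, 32), pixelSize = PX)
    rois <- detectHotspots(m, ampThreshold = 0.1, pixelSize = PX)
    ctr <- if (length(rois)) {
      rois[[which.max(vapply(rois, function(r) r@peakDff, numeric(1)))]]@center
    } else which(m == max(m, na.rm = TRUE), arr.ind = TRUE)[1, ]
    prof <- radialProfile(m, ctr, maxRadius = 3.5, pixelSize = PX,
                          refineCenter = TRUE)
    spreadConstant(fitSpread(prof, freeOffset = TRUE))
  }
  out <- c(dec = fitFrom(c("deconvolve", "denoise")))
  if (rawToo) out <- c(out, raw = fitFrom("denoise"))
  out
}

# Whole-cell 16 Hz train trace: integer per-hotspot RRP allocation with
# heterogeneous refill shares, summed sensor-convolved hotspot traces plus
# Gaussian trace noise.
makePoolTrace <- function(seed, rrpCell = 19.93, refillCell = 0.022,
                          pr = 0.8, q = 0.4, tauOff = 8.96,
                          nStim = 1920, frameRate = 10, baseline = 10,
                          tail = 20, nHotspots = 10, noiseSd = 0.05) {
  st <- baseline + (seq_len(nStim) - 1) / 16
  nF <- round((baseline + nStim / 16 + tail) * frameRate)
  times <- (seq_len(nF) - 1) / frameRate
  set.seed(seed)
  tot <- floor(rrpCell) + stats::rbinom(1, 1, rrpCell - floor(rrpCell))
  w <- 0.5 + stats::runif(nHotspots); w <- w / sum(w)
  alloc <- rep(1L, nHotspots) +
    as.vector(stats::rmultinom(1, max(tot - nHotspots, 0), w))
  tr <- numeric(nF)
  rTrue <- numeric(nStim)
  for (h in seq_len(nHotspots)) {
    hs <- hotspotSpec(c(1, 1), 0.74, q, releaseProb = pr,
                      quantaDist = c(0.75, 0.2, 0.05), rrp = alloc[h],
                      refillRate = refillCell * w[h])
    ev <- simulateReleaseTrain(hs, st, seed = seed * 1000 + h)
    tr <- tr + sensorTrace(ev, times, 0, tauOff)
    rTrue <- rTrue + ev$amplitude
  }
  if (noiseSd > 0) {
    set.seed(seed * 1000 + 999)
    tr <- tr + stats::rnorm(nF, 0, noiseSd)
  }
  list(trace = tr, times = times, stimTimes = st, rTrue = rTrue,
       rrpTrue = tot, q = q)
}

# Trial amplitudes for the 0.1 Hz quantal protocol (amplitude level, no
# movie): k * q quantal amplitudes with Gaussian trial noise.
makeQuantalTrials <- function(seed, n = 100, q = 0.4, pr = 0.79,
                              weights = c(0.75, 0.2, 0.05),
                              noiseFrac = 0.2) {
  set.seed(seed)
  succ <- stats::runif(n) < pr
  k <- integer(n)
  k[succ] <- sample(seq_along(weights), sum(succ), TRUE, prob = weights)
  amp <- k * q + stats::rnorm(n, 0, noiseFrac * q)
  list(table = data.frame(stim = seq_len(n), amplitude = amp),
       k = k, noiseSd = noiseFrac * q)
}

# Smooth textured reference image for registration / movement tests.
texturedImage <- function(seed = 1, n = 40) {
  set.seed(seed)
  img <- matrix(stats::runif(n * n, 100, 200), n, n)
  fluoQuanta:::.convolve2d(img, gaussianPSF(0.3, 0.16))
}
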