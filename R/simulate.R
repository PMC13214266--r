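# Synthetic-movie generator: forward model of quantal neuromodulator release
# viewed through a slow fluorescence sensor, with optics and noise. Every
# downstream stage is validated by parameter recovery against the ground
# truth this module writes.

#' Specify one release hotspot
#'
#' Defines the generative parameters of a single release site: its position,
#' spatial spread constant, quantal size, release probability, the
#' distribution of quanta per successful stimulus, and the vesicle pool
#' (readily releasable pool size and refilling rate).
#'
#' @param center numeric(2), hotspot center in micrometers (row, col) from
#'   the image origin.
#' @param lambda spatial spread length constant (um) of the single-
#'   exponential dF/F0 decay around the center.
#' @param q quantal size: dF/F0 produced by one vesicle.
#' @param releaseProb probability that a stimulus triggers release.
#' @param quantaDist numeric vector of weights over 1..K quanta released per
#'   successful stimulus (normalized internally).
#' @param rrp readily releasable pool size in vesicles (may be \code{Inf};
#'   fractional values are allowed, released quanta are integers).
#' @param refillRate vesicles returned to the pool per stimulus.
#' @param refillMode \code{"deterministic"} (default): refill accrues
#'   continuously at \code{refillRate} per stimulus into a recruitment
#'   accumulator; each time the accumulator reaches one, a whole vesicle
#'   is transferred to the pool (capped at \code{rrp}). Or
#'   \code{"stochastic"}: whole vesicles are recruited as Bernoulli events
#'   at rate \code{refillRate} per stimulus (memoryless recruitment). Both
#'   modes have the same mean refilling rate.
#' @param refillPhase initial accumulator phase in [0, 1) for the
#'   deterministic mode; \code{NA} (default) draws it uniformly at train
#'   time so recruitment cycles are desynchronized across synapses, as in
#'   a stationary preparation. With \code{refillPhase = 0} the
#'   conservation bound \code{released(n) <= rrp + n * refillRate} is
#'   exact; a random phase can relax it by at most one vesicle.
#' @return A list of class \code{"HotspotSpec"}.
#' @examples
#' hs <- hotspotSpec(c(4, 4), lambda = 0.74, q = 0.004, releaseProb = 0.79)
#' @export
hotspotSpec <- function(center, lambda, q, releaseProb,
                        quantaDist = 1, rrp = Inf, refillRate = 0,
                        refillMode = c("deterministic", "stochastic"),
                        refillPhase = NA_real_) {
  refillMode <- match.arg(refillMode)
  stopifnot(length(center) == 2L, lambda > 0, q > 0,
            releaseProb >= 0, releaseProb <= 1,
            all(quantaDist >= 0), sum(quantaDist) > 0,
            rrp >= 0, refillRate >= 0,
            is.na(refillPhase) || (refillPhase >= 0 && refillPhase < 1))
  structure(list(center = as.numeric(center), lambda = lambda, q = q,
                 releaseProb = releaseProb,
                 quantaDist = quantaDist / sum(quantaDist),
                 rrp = rrp, refillRate = refillRate,
                 refillMode = refillMode, refillPhase = refillPhase),
            class = "HotspotSpec")
}

#' Assemble a simulation configuration
#'
#' Collects the imaging geometry, stimulus protocol, sensor kinetics, optics
#' and noise model for \code{\link{renderMovie}}. Defaults reflect a 40x /
#' 6.5-um-camera-pixel wide-field setup imaged at 10 Hz with a slow
#' serotonin sensor (tau_off = 8.96 s).
#'
#' @param imageShape integer(2), rows and columns in pixels.
#' @param nFrames number of frames.
#' @param stimTimes stimulus onset times (s), strictly increasing, within
#'   the movie duration.
#' @param hotspots list of \code{\link{hotspotSpec}} objects.
#' @param pixelSize micrometers per pixel.
#' @param frameRate frames per second.
#' @param f0Mean mean basal fluorescence (counts).
#' @param f0CV coefficient of variation of the spatially heterogeneous basal
#'   fluorescence map.
#' @param tauRise,tauOff sensor impulse-response time constants (s);
#'   \code{tauOff > tauRise >= 0}.
#' @param bleach optional numeric(4) \code{c(a, b, c, d)} two-term
#'   exponential bleaching multiplier \code{a*exp(b*t) + c*exp(d*t)}
#'   (decay: b, d <= 0); \code{NULL} disables bleaching.
#' @param psfSigma Gaussian PSF SD (um); 0 disables blurring.
#' @param gain photon gain, counts per photon (Poisson noise scale); 0
#'   disables photon noise.
#' @param readNoise Gaussian read-noise SD in counts.
#' @param driftAmp per-frame random drift SD in pixels.
#' @param seed integer seed for all randomness in the renderer.
#' @return A validated list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(imageShape, nFrames, stimTimes, hotspots,
                             pixelSize = 0.1625, frameRate = 10,
                             f0Mean = 2000, f0CV = 0.3,
                             tauRise = 0.1, tauOff = 8.96, bleach = NULL,
                             psfSigma = 0.25, gain = 1, readNoise = 10,
                             driftAmp = 0, seed = 1L) {
  stopifnot(length(imageShape) == 2L, all(imageShape >= 1),
            pixelSize > 0, frameRate > 0, nFrames >= 1,
            tauRise >= 0, tauOff > tauRise, psfSigma >= 0,
            f0Mean > 0, f0CV >= 0, gain >= 0, readNoise >= 0, driftAmp >= 0)
  dur <- nFrames / frameRate
  if (length(stimTimes) && (any(stimTimes < 0) || any(stimTimes > dur)))
    stop("all 'stimTimes' must lie within the movie duration")
  if (!is.null(bleach) && length(bleach) != 4L)
    stop("'bleach' must be c(a, b, c, d) or NULL")
  if (!all(vapply(hotspots, inherits, logical(1), "HotspotSpec")))
    stop("'hotspots' must be a list of hotspotSpec() objects")
  structure(list(imageShape = as.integer(imageShape), nFrames = as.integer(nFrames),
                 stimTimes = as.numeric(stimTimes), hotspots = hotspots,
                 pixelSize = pixelSize, frameRate = frameRate,
                 f0Mean = f0Mean, f0CV = f0CV, tauRise = tauRise,
                 tauOff = tauOff, bleach = bleach, psfSigma = psfSigma,
                 gain = gain, readNoise = readNoise, driftAmp = driftAmp,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' Sensor impulse response
#'
#' Unit-peak fluorescence response of the indicator to an instantaneous
#' transmitter release at t = 0:
#' \code{h(t) = (1 - exp(-t/tauRise)) * exp(-t/tauOff)} normalized so its
#' maximum is 1 (pure exponential decay when \code{tauRise = 0}). The peak
#' occurs at \code{t* = tauRise * log(1 + tauOff/tauRise)}.
#'
#' @param t times (s); values before 0 return 0.
#' @param tauRise rise time constant (s), may be 0.
#' @param tauOff decay time constant (s), must exceed \code{tauRise}.
#' @return Numeric vector of the same length as \code{t}.
#' @examples
#' tPeak <- 0.1 * log(1 + 8.96 / 0.1)   # about 0.451 s
#' sensorImpulse(tPeak, 0.1, 8.96)      # 1 at the peak
#' @export
sensorImpulse <- function(t, tauRise, tauOff) {
  stopifnot(tauRise >= 0, tauOff > tauRise)
  h <- function(x) {
    out <- numeric(length(x))
    pos <- x >= 0
    if (tauRise == 0) {
      out[pos] <- exp(-x[pos] / tauOff)
    } else {
      out[pos] <- (1 - exp(-x[pos] / tauRise)) * exp(-x[pos] / tauOff)
    }
    out
  }
  if (tauRise == 0) return(h(t))
  tPeak <- tauRise * log(1 + tauOff / tauRise)
  h(t) / h(tPeak)
}

#' Simulate a stochastic release train at one hotspot
#'
#' Forward model of vesicle-pool dynamics: at each stimulus, release succeeds
#' with probability \code{releaseProb}; on success the number of quanta k is
#' drawn from \code{quantaDist} truncated to the integer part of the pool
#' currently available. The pool then decrements by k and accrues
#' \code{refillRate} vesicles, capped at \code{rrp}. Fractional pool levels
#' are carried internally; released quanta are always integers.
#'
#' @param spec a \code{\link{hotspotSpec}}.
#' @param stimTimes stimulus onset times (s), strictly increasing.
#' @param seed integer seed.
#' @param hotspotId identifier copied into the output table.
#' @return data.frame (release event table) with one row per stimulus:
#'   \code{hotspot, stim, time, success, quanta, amplitude} (= quanta * q,
#'   dF/F0) and \code{poolRemaining}.
#' @examples
#' hs <- hotspotSpec(c(2, 2), 0.74, 0.004, releaseProb = 1,
#'                   rrp = 2, refillRate = 0)
#' ev <- simulateReleaseTrain(hs, stimTimes = seq(0, 9), seed = 1)
#' sum(ev$quanta)  # pool-limited: 2
#' @export
simulateReleaseTrain <- function(spec, stimTimes, seed = 1L, hotspotId = 1L) {
  stopifnot(inherits(spec, "HotspotSpec"))
  if (!length(stimTimes)) stop("no stimuli")
  if (length(stimTimes) > 1 && any(diff(stimTimes) <= 0))
    stop("'stimTimes' must be strictly increasing")
  n <- length(stimTimes)
  set.seed(seed)
  kSupport <- seq_along(spec$quantaDist)
  pool <- spec$rrp
  deterministic <- identical(spec$refillMode, "deterministic")
  acc <- if (is.na(spec$refillPhase)) stats::runif(1) else spec$refillPhase
  success <- stats::runif(n) < spec$releaseProb
  quanta <- integer(n)
  poolRem <- numeric(n)
  for (i in seq_len(n)) {
    if (success[i]) {
      avail <- if (is.finite(pool)) floor(pool) else Inf
      if (avail >= 1) {
        w <- spec$quantaDist
        keep <- kSupport <= avail
        w[!keep] <- 0
        if (sum(w) > 0) {
          k <- sample(kSupport, 1L, prob = w)
        } else {
          k <- min(avail, max(kSupport))  # all support above pool: take floor
        }
        quanta[i] <- as.integer(k)
        if (is.finite(pool)) pool <- pool - k
      }
    }
    if (is.finite(pool) && spec$refillRate > 0) {
      if (deterministic) {
        acc <- acc + spec$refillRate
        while (acc >= 1 && pool + 1 <= spec$rrp) {
          pool <- pool + 1
          acc <- acc - 1
        }
        if (pool + 1 > spec$rrp) acc <- min(acc, 1 - 1e-12)
      } else {
        rr <- spec$refillRate
        gain <- floor(rr) + (stats::runif(1) < rr - floor(rr))
        pool <- min(spec$rrp, pool + gain)
      }
    }
    poolRem[i] <- pool
  }
  data.frame(hotspot = hotspotId, stim = seq_len(n), time = stimTimes,
             success = success, quanta = quanta,
             amplitude = quanta * spec$q, poolRemaining = poolRem)
}

#' Noise-free dF/F0 trace implied by a release event table
#'
#' Convolves per-stimulus release amplitudes with the sensor impulse
#' response: \code{trace(t) = sum_e amplitude_e * h(t - t_e)}. This is the
#' trace-level forward model used for protocol-scale simulations where the
#' full movie is not needed.
#'
#' @param events release event table from \code{\link{simulateReleaseTrain}}
#'   (or any data.frame with \code{time} and \code{amplitude}).
#' @param times frame times (s).
#' @param tauRise,tauOff sensor time constants (s).
#' @return Numeric dF/F0 trace at \code{times}.
#' @export
sensorTrace <- function(events, times, tauRise, tauOff) {
  keep <- events$amplitude > 0
  tr <- numeric(length(times))
  for (i in which(keep)) {
    tr <- tr + events$amplitude[i] *
      sensorImpulse(times - events$time[i], tauRise, tauOff)
  }
  tr
}

#' Render a synthetic fluorescence movie from release events
#'
#' Full forward model of the measured signal. Per pixel p and frame t:
#' \deqn{F(p,t) = F_0(p) [1 + \sum_e k_e q \exp(-d(p,c_e)/\lambda) h(t-t_e)]}
#' multiplied by the two-term-exponential bleaching factor, blurred by the
#' Gaussian PSF, shifted by per-frame drift, then degraded by Poisson photon
#' noise (scaled by \code{gain}) and Gaussian read noise, and quantized to
#' 16-bit integer counts.
#'
#' @param events release event table covering all hotspots in \code{config}
#'   (column \code{hotspot} indexes \code{config$hotspots}).
#' @param config a \code{\link{simulationConfig}}.
#' @param keepClean if TRUE, the noiseless, unblurred dF/F0 array is
#'   returned as \code{clean} for oracle tests.
#' @return list with \code{movie} (\linkS4class{FluorescenceMovie}),
#'   \code{truth} (\linkS4class{GroundTruth}) and optionally \code{clean}.
#' @export
renderMovie <- function(events, config, keepClean = FALSE) {
  stopifnot(inherits(config, "SimulationConfig"))
  nr <- config$imageShape[1]; nc <- config$imageShape[2]
  nf <- config$nFrames
  fieldUm <- c(nr, nc) * config$pixelSize
  for (hs in config$hotspots) {
    if (any(hs$center < 0) || any(hs$center > fieldUm))
      stop("hotspot center outside field")
  }
  set.seed(config$seed)
  # basal fluorescence map with spatial heterogeneity (clipped Gaussian)
  f0 <- matrix(stats::rnorm(nr * nc, config$f0Mean,
                            config$f0CV * config$f0Mean), nr, nc)
  f0 <- pmax(f0, 0.05 * config$f0Mean)

  times <- (seq_len(nf) - 1) / config$frameRate
  rowUm <- ((seq_len(nr)) - 0.5) * config$pixelSize
  colUm <- ((seq_len(nc)) - 0.5) * config$pixelSize

  dff <- array(0, dim = c(nr, nc, nf))
  for (h in seq_along(config$hotspots)) {
    hs <- config$hotspots[[h]]
    ev <- events[events$hotspot == h & events$amplitude > 0, , drop = FALSE]
    if (!nrow(ev)) next
    d <- sqrt(outer((rowUm - hs$center[1])^2, (colUm - hs$center[2])^2, "+"))
    spatial <- exp(-d / hs$lambda)
    temporal <- numeric(nf)
    for (i in seq_len(nrow(ev))) {
      temporal <- temporal + ev$amplitude[i] *
        sensorImpulse(times - ev$time[i], config$tauRise, config$tauOff)
    }
    dff <- dff + outer(spatial, temporal)
  }

  bleachF <- if (is.null(config$bleach)) rep(1, nf) else
    config$bleach[1] * exp(config$bleach[2] * times) +
    config$bleach[3] * exp(config$bleach[4] * times)

  psf <- if (config$psfSigma > 0)
    gaussianPSF(config$psfSigma, config$pixelSize) else NULL

  frames <- array(0, dim = c(nr, nc, nf))
  drift <- if (config$driftAmp > 0)
    matrix(stats::rnorm(2 * nf, 0, config$driftAmp), nf, 2) else
    matrix(0, nf, 2)
  for (t in seq_len(nf)) {
    fr <- f0 * (1 + dff[, , t]) * bleachF[t]
    if (!is.null(psf)) fr <- .convolve2d(fr, psf)
    if (any(drift[t, ] != 0)) fr <- .shiftImage(fr, drift[t, 1], drift[t, 2])
    if (config$gain > 0)
      fr <- stats::rpois(length(fr), pmax(fr, 0) / config$gain) * config$gain
    if (config$readNoise > 0)
      fr <- fr + stats::rnorm(length(fr), 0, config$readNoise)
    frames[, , t] <- pmin(pmax(round(fr), 0), 65535)
  }

  hsTab <- if (!length(config$hotspots)) {
    data.frame(hotspot = integer(), centerRowUm = numeric(),
               centerColUm = numeric(), lambda = numeric(), q = numeric(),
               releaseProb = numeric(), rrp = numeric(),
               refillRate = numeric())
  } else do.call(rbind, lapply(seq_along(config$hotspots), function(h) {
    hs <- config$hotspots[[h]]
    data.frame(hotspot = h, centerRowUm = hs$center[1],
               centerColUm = hs$center[2], lambda = hs$lambda, q = hs$q,
               releaseProb = hs$releaseProb, rrp = hs$rrp,
               refillRate = hs$refillRate)
  }))
  truth <- new("GroundTruth", config = unclass(config), hotspots = hsTab,
               events = events)
  out <- list(movie = FluorescenceMovie(frames, config$pixelSize,
                                        config$frameRate, config$stimTimes),
              truth = truth)
  if (keepClean) out$clean <- dff
  out
}

#' Write / read a synthetic fixture (movie + ground truth)
#'
#' The movie is stored as a 16-bit multi-page TIFF and the ground truth as a
#' JSON sidecar (\code{truth.json}, schema version 1). Reading back
#' reproduces pixel values exactly.
#'
#' @param movie a \linkS4class{FluorescenceMovie}.
#' @param truth a \linkS4class{GroundTruth}.
#' @param path output directory (created if missing).
#' @return (invisibly) the two file paths.
#' @export
writeFixture <- function(movie, truth, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  tifPath <- file.path(path, "movie.tif")
  jsonPath <- file.path(path, "truth.json")
  fr <- movieData(movie)
  pages <- lapply(seq_len(dim(fr)[3]), function(t) fr[, , t] / 65535)
  tiff::writeTIFF(pages, tifPath, bits.per.sample = 16L, compression = "none")
  cfg <- truth@config
  cfg$hotspots <- lapply(cfg$hotspots, unclass)
  payload <- list(schema = 1L,
                  pixelSize = pixelSize(movie), frameRate = frameRate(movie),
                  stimTimes = stimTimes(movie), config = cfg,
                  hotspots = truth@hotspots, events = truth@events)
  writeLines(jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE,
                              null = "null", na = "null"), jsonPath)
  invisible(c(movie = tifPath, truth = jsonPath))
}

#' @rdname writeFixture
#' @export
readFixture <- function(path) {
  tifPath <- file.path(path, "movie.tif")
  jsonPath <- file.path(path, "truth.json")
  pages <- tiff::readTIFF(tifPath, all = TRUE, as.is = TRUE)
  frames <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (t in seq_along(pages)) frames[, , t] <- pages[[t]]
  txt <- readLines(jsonPath)
  meta <- jsonlite::fromJSON(txt)
  metaRaw <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  hs <- lapply(metaRaw$config$hotspots, function(x)
    hotspotSpec(unlist(x$center), x$lambda, x$q, x$releaseProb,
                unlist(x$quantaDist),
                if (is.null(x$rrp)) Inf else x$rrp, x$refillRate,
                if (is.null(x$refillMode)) "deterministic" else x$refillMode,
                if (is.null(x$refillPhase) || is.na(x$refillPhase))
                  NA_real_ else x$refillPhase))
  cfg <- meta$config
  cfg$hotspots <- hs
  class(cfg) <- "SimulationConfig"
  truth <- new("GroundTruth", config = unclass(cfg),
               hotspots = as.data.frame(meta$hotspots),
               events = as.data.frame(meta$events))
  list(movie = FluorescenceMovie(frames, meta$pixelSize, meta$frameRate,
                                 meta$stimTimes),
       truth = truth)
}
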