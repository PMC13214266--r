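test_that("release trains honor deterministic limits and pool exhaustion", {
  st <- seq(0, 90, by = 10)
  # Pr = 1, one quantum per success, unlimited pool
  hs <- hotspotSpec(c(2, 2), 0.74, 0.4, releaseProb = 1)
  ev <- simulateReleaseTrain(hs, st, seed = 1)
  expect_true(all(ev$quanta == 1L))
  expect_true(all(ev$amplitude == 0.4))
  # Pr = 0: all failures, pool untouched
  hs0 <- hotspotSpec(c(2, 2), 0.74, 0.4, releaseProb = 0, rrp = 5)
  ev0 <- simulateReleaseTrain(hs0, st, seed = 2)
  expect_true(all(!ev0$success))
  expect_true(all(ev0$quanta == 0L))
  expect_true(all(ev0$poolRemaining == 5))
  # pool exhaustion: rrp 2, no refill
  hs2 <- hotspotSpec(c(2, 2), 0.74, 0.4, releaseProb = 1, rrp = 2,
                     refillRate = 0)
  ev2 <- simulateReleaseTrain(hs2, st, seed = 3)
  expect_identical(sum(ev2$quanta), 2L)
  expect_true(all(ev2$quanta[3:10] == 0L))  # one quantum per success
  expect_error(simulateReleaseTrain(hs, numeric(0)), "no stimuli")
})

test_that("long-run release balances the refilling rate", {
  # rrp 20, refill 0.022/stimulus, Pr 1: after depletion the mean release
  # per stimulus must settle at the refill rate (independent long-run
  # bookkeeping check against the generator)
  st <- (0:1919) / 16
  lateMeans <- vapply(1:30, function(s) {
    hs <- hotspotSpec(c(1, 1), 0.74, 0.4, releaseProb = 1,
                      rrp = 20, refillRate = 0.022)
    ev <- simulateReleaseTrain(hs, st, seed = s)
    mean(ev$quanta[641:1920])
  }, numeric(1))
  expect_lt(abs(mean(lateMeans) - 0.022), 0.004)
})

test_that("sensor impulse response peaks where the closed form says", {
  tauRise <- 0.1; tauOff <- 8.96
  tStar <- tauRise * log(1 + tauOff / tauRise)
  expect_equal(tStar, 0.4506454, tolerance = 1e-6)
  expect_equal(sensorImpulse(tStar, tauRise, tauOff), 1, tolerance = 1e-12)
  tt <- seq(0, 5, by = 1e-3)
  h <- sensorImpulse(tt, tauRise, tauOff)
  expect_equal(tt[which.max(h)], tStar, tolerance = 1e-3)
  expect_true(all(sensorImpulse(c(-1, -0.01), tauRise, tauOff) == 0))
  # tauRise = 0: pure unit-peak exponential decay
  expect_equal(sensorImpulse(0, 0, 3.15), 1)
  expect_equal(sensorImpulse(3.15, 0, 3.15), exp(-1))
})

test_that("rendered movies reduce to the F0 map with no events or noise", {
  cfg <- simulationConfig(c(12, 12), nFrames = 5, stimTimes = numeric(),
                          hotspots = list(), f0Mean = 1000, f0CV = 0,
                          psfSigma = 0, gain = 0, readNoise = 0, seed = 1)
  ev <- data.frame(hotspot = integer(), stim = integer(), time = numeric(),
                   success = logical(), quanta = integer(),
                   amplitude = numeric(), poolRemaining = numeric())
  out <- renderMovie(ev, cfg)
  fr <- movieData(out$movie)
  expect_true(all(fr == 1000))
})

test_that("a single clean event produces peak dF/F0 = k*q at the impulse peak", {
  q <- 0.3
  hs <- hotspotSpec(c(1, 1) * 6 * 0.1625 - 0.5 * 0.1625, 0.6, q,
                    releaseProb = 1)
  cfg <- simulationConfig(c(12, 12), nFrames = 60, stimTimes = 1,
                          hotspots = list(hs), frameRate = 20,
                          f0Mean = 5000, f0CV = 0, tauRise = 0.1,
                          tauOff = 8.96, psfSigma = 0, gain = 0,
                          readNoise = 0, seed = 1)
  ev <- data.frame(hotspot = 1, stim = 1, time = 1, success = TRUE,
                   quanta = 2L, amplitude = 2 * q, poolRemaining = Inf)
  out <- renderMovie(ev, cfg)
  fr <- movieData(out$movie)
  f0 <- fr[, , 1]
  dff <- sweep(fr, c(1, 2), f0, "/") - 1
  # frame nearest the impulse peak at 1 + 0.4506 s
  tPeakFrame <- round((1 + 0.4506) * 20) + 1
  peak <- max(dff[, , tPeakFrame])
  hAtFrame <- sensorImpulse((tPeakFrame - 1) / 20 - 1, 0.1, 8.96)
  expect_equal(peak, 2 * q * hAtFrame, tolerance = 2e-3)  # count rounding
})

test_that("noiseless dF/F0 is linear in quantal size", {
  mk <- function(q) {
    hs <- hotspotSpec(c(1.3, 1.3), 0.74, q, releaseProb = 1)
    cfg <- simulationConfig(c(16, 16), nFrames = 30, stimTimes = 1,
                            hotspots = list(hs), f0Mean = 1000, f0CV = 0.3,
                            psfSigma = 0, gain = 0, readNoise = 0, seed = 5)
    ev <- data.frame(hotspot = 1, stim = 1, time = 1, success = TRUE,
                     quanta = 1L, amplitude = q, poolRemaining = Inf)
    renderMovie(ev, cfg, keepClean = TRUE)$clean
  }
  expect_equal(mk(0.8), 2 * mk(0.4), tolerance = 1e-12)
})

test_that("empirical release probability matches the generator over 1e4 stimuli", {
  st <- seq_len(10000)
  pr <- 0.79
  hs <- hotspotSpec(c(1, 1), 0.74, 0.4, releaseProb = pr)
  ev <- simulateReleaseTrain(hs, st, seed = 11)
  se <- sqrt(pr * (1 - pr) / 10000)
  expect_lt(abs(mean(ev$success) - pr), 3 * se)
})

test_that("pool accounting never exceeds rrp + n * refill", {
  st <- seq_len(400)
  set.seed(42)
  for (case in 1:8) {
    rrp <- sample(1:25, 1)
    refill <- stats::runif(1, 0, 0.2)
    pr <- stats::runif(1, 0.3, 1)
    hs <- hotspotSpec(c(1, 1), 0.7, 0.4, releaseProb = pr,
                      quantaDist = c(0.6, 0.3, 0.1), rrp = rrp,
                      refillRate = refill, refillPhase = 0)
    ev <- simulateReleaseTrain(hs, st, seed = case)
    cumRel <- cumsum(ev$quanta)
    expect_true(all(cumRel <= rrp + seq_along(st) * refill + 1e-9))
    expect_true(all(ev$poolRemaining >= 0 & ev$poolRemaining <= rrp))
    expect_true(all(ev$quanta[!ev$success] == 0L))
  }
})

test_that("identical config and seed give identical movies", {
  mk <- function() {
    hs <- hotspotSpec(c(1.3, 1.3), 0.7, 0.4, releaseProb = 0.8)
    cfg <- simulationConfig(c(16, 16), nFrames = 20, stimTimes = c(1, 1.5),
                            hotspots = list(hs), gain = 2, readNoise = 8,
                            driftAmp = 0.2, seed = 99)
    ev <- simulateReleaseTrain(hs, c(1, 1.5), seed = 7)
    renderMovie(ev, cfg)
  }
  a <- mk(); b <- mk()
  expect_identical(movieData(a$movie), movieData(b$movie))
})

test_that("fixtures roundtrip exactly through TIFF + JSON", {
  hs <- hotspotSpec(c(1.3, 1.3), 0.7, 0.4, releaseProb = 0.8, rrp = 10,
                    refillRate = 0.05)
  cfg <- simulationConfig(c(16, 16), nFrames = 10, stimTimes = 1,
                          hotspots = list(hs), gain = 2, readNoise = 5,
                          seed = 3)
  ev <- simulateReleaseTrain(hs, 1, seed = 3)
  out <- renderMovie(ev, cfg)
  d1 <- file.path(tempdir(), "fix1"); d2 <- file.path(tempdir(), "fix2")
  writeFixture(out$movie, out$truth, d1)
  writeFixture(out$movie, out$truth, d2)
  expect_identical(readBin(file.path(d1, "movie.tif"), "raw", 1e6),
                   readBin(file.path(d2, "movie.tif"), "raw", 1e6))
  back <- readFixture(d1)
  expect_identical(movieData(back$movie), movieData(out$movie))
  expect_equal(pixelSize(back$movie), pixelSize(out$movie))
  expect_equal(back$truth@events$quanta, out$truth@events$quanta)
  expect_equal(back$truth@hotspots$lambda, out$truth@hotspots$lambda)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("hotspot centers outside the field are rejected", {
  hs <- hotspotSpec(c(100, 100), 0.7, 0.4, releaseProb = 1)
  cfg <- simulationConfig(c(16, 16), nFrames = 20, stimTimes = 1,
                          hotspots = list(hs), seed = 1)
  ev <- data.frame(hotspot = 1, stim = 1, time = 1, success = TRUE,
                   quanta = 1L, amplitude = 0.4, poolRemaining = Inf)
  expect_error(renderMovie(ev, cfg), "outside field")
})
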