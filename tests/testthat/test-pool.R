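test_that("off-rate correction inverts the sensor model exactly when well posed", {
  # single pulse: corrected amplitude equals the measured peak
  times <- seq(0, 20, by = 0.1)
  tr1 <- 0.7 * sensorImpulse(times - 5, 0, 8.96)
  ser1 <- correctOffRate(tr1, times, 5, 8.96)
  expect_equal(ser1$r, 0.7, tolerance = 1e-9)
  # 50 pulses at 16 Hz, noiseless roundtrip at machine precision
  times50 <- seq(0, 15, by = 0.02)
  st50 <- 1 + (0:49) / 16
  set.seed(14)
  rTrue <- stats::runif(50, 0, 1)
  tr50 <- sensorTrace(data.frame(time = st50, amplitude = rTrue),
                      times50, 0, 8.96)
  ser50 <- correctOffRate(tr50, times50, st50, 8.96)
  expect_lt(max(abs(ser50$r - rTrue)), 1e-6)
})

test_that("the tauOff -> 0 limit returns the raw per-stimulus peaks", {
  times <- seq(0, 10, by = 0.01)
  st <- 1:8
  set.seed(15)
  rTrue <- stats::runif(8, 0.2, 1)
  tr <- sensorTrace(data.frame(time = st, amplitude = rTrue), times, 0, 0.02)
  ser <- correctOffRate(tr, times, st, 0.02)
  peaks <- vapply(st, function(s) max(tr[abs(times - s) < 0.5]), numeric(1))
  expect_equal(ser$r, peaks, tolerance = 1e-6)
  sub <- seq(1, 1001, 50)
  expect_warning(correctOffRate(tr[sub], times[sub], st, 0.02),
                 "ill-conditioned")
})

test_that("cumulative release curves are running sums with a late window", {
  cv <- cumulativeCurve(list(r = c(1, 1, 1)))
  expect_equal(cv$cumulative, c(1, 2, 3))
  set.seed(16)
  cv2 <- cumulativeCurve(list(r = stats::rnorm(300)))  # clipped at 0
  expect_true(all(diff(cv2$cumulative) >= 0))
  expect_equal(cv2$lateWindow, c(201, 300))
})

test_that("back-extrapolation reads an exact line and flags bad fits", {
  nStim <- 600
  cum <- 5 + 0.02 * seq_len(nStim)
  curve <- list(stim = seq_len(nStim), cumulative = cum,
                lateWindow = c(401, nStim), lateFraction = 1 / 3)
  est <- fitRRPRefill(curve)
  expect_equal(est@rrpDff, 5, tolerance = 1e-9)
  expect_equal(est@refillPerStimDff, 0.02, tolerance = 1e-12)
  expect_length(est@flags, 0L)
  # negative intercept flagged, not hidden
  curveNeg <- list(stim = seq_len(nStim), cumulative = 0.02 * seq_len(nStim) - 3,
                   lateWindow = c(401, nStim))
  expect_true("rrp_not_resolvable" %in% fitRRPRefill(curveNeg)@flags)
  expect_error(fitRRPRefill(list(stim = 1:50, cumulative = 1:50,
                                 lateWindow = c(34, 50))), "late window")
})

test_that("a zero-refill train yields slope ~ 0 and intercept ~ total release", {
  pool <- makePoolTrace(seed = 17, rrpCell = 8 * 0.4 / 0.4, refillCell = 0,
                        nStim = 600, tail = 10, nHotspots = 4, noiseSd = 0.02)
  ser <- correctOffRate(pool$trace, pool$times, pool$stimTimes, 8.96)
  est <- fitRRPRefill(cumulativeCurve(ser))
  expect_lt(abs(est@refillPerStimDff) * 1000, 1.5)     # ~0 per 1,000 pulses
  expect_equal(est@rrpDff, sum(pool$rTrue), tolerance = 0.15)
})

test_that("corrected totals conserve the released dF/F0", {
  pool <- makePoolTrace(seed = 18, nStim = 480, tail = 10, noiseSd = 0.02)
  ser <- correctOffRate(pool$trace, pool$times, pool$stimTimes, 8.96)
  expect_lt(abs(sum(ser$r) - sum(pool$rTrue)) / sum(pool$rTrue), 0.02)
})

test_that("RRP and refill are recovered from full forward simulations", {
  res <- t(vapply(1:4, function(s) {
    pool <- makePoolTrace(seed = 30 + s)
    ser <- correctOffRate(pool$trace, pool$times, pool$stimTimes, 8.96)
    est <- toVesicles(fitRRPRefill(cumulativeCurve(ser)), pool$q)
    c(rrp = rrpVesicles(est), refill = refillPer1000(est), r2 = est@r2)
  }, numeric(3)))
  expect_lt(abs(mean(res[, "rrp"]) - 19.93) / 19.93, 0.15)
  expect_lt(abs(mean(res[, "refill"]) - 22) / 22, 0.20)
  expect_true(all(res[, "r2"] >= 0.9))
})

test_that("ten-fold refill differences yield non-overlapping slope CIs", {
  slopeCI <- function(refill, seeds, tauOff, q) {
    sl <- vapply(seeds, function(s) {
      pool <- makePoolTrace(seed = s, rrpCell = 30, refillCell = refill,
                            pr = 1, q = q, tauOff = tauOff, nStim = 960,
                            tail = 10, noiseSd = 0.02)
      ser <- correctOffRate(pool$trace, pool$times, pool$stimTimes, tauOff)
      est <- toVesicles(fitRRPRefill(cumulativeCurve(ser)), q)
      refillPer1000(est)
    }, numeric(1))
    mean(sl) + c(-1.96, 1.96) * stats::sd(sl) / sqrt(length(sl))
  }
  ciHigh <- slopeCI(0.0186, 41:44, 3.15, 2.26)  # PVN-like, ~18.6/1,000
  ciLow <- slopeCI(0.00112, 45:48, 3.15, 1.65)  # VTA-like, ~1.12/1,000
  expect_gt(ciHigh[1], ciLow[2])
})

test_that("lower refilling produces stronger late-train rundown", {
  rundown <- vapply(c(0.001, 0.005, 0.02, 0.08), function(refill) {
    pool <- makePoolTrace(seed = 50, rrpCell = 30, refillCell = refill,
                          pr = 1, nStim = 960, tail = 10, noiseSd = 0)
    early <- mean(pool$rTrue[1:60])
    late <- mean(pool$rTrue[641:960])
    1 - late / early
  }, numeric(1))
  expect_lt(stats::cor(c(0.001, 0.005, 0.02, 0.08), rundown,
                       method = "spearman"), 0)
})

test_that("vesicle conversion divides by q with the stated equivariance", {
  est <- new("PoolEstimate", rrpDff = 8, refillPerStimDff = 0.0088,
             rrpVesicles = NA_real_, refillPer1000 = NA_real_,
             q = NA_real_, scope = "whole_cell", ci = rep(NA_real_, 4),
             r2 = 1, flags = character(), diagnostics = list())
  v <- toVesicles(est, 0.4)
  expect_equal(rrpVesicles(v), 20)
  expect_equal(refillPer1000(v), 22)
  v2 <- toVesicles(est, 0.8)
  expect_equal(rrpVesicles(v2), 10)
  expect_equal(refillPer1000(v2), 11)
  expect_error(toVesicles(est, 0), "positive")
})
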