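test_that("maximal dF/F0 maps take per-pixel maxima over the window", {
  d <- array(0.2, c(6, 6, 10))
  expect_true(all(maxDffMap(d) == 0.2))
  d[3, 4, 7] <- 0.9
  m <- maxDffMap(d, c(5, 10))
  expect_equal(m[3, 4], 0.9)
  expect_equal(m[1, 1], 0.2)
  expect_error(maxDffMap(d, c(5, 11)), "window")
})

test_that("DBSCAN detection finds planted hotspots without spurious sites", {
  mkSpot <- function(m, ctr, amp, lam = 2.5) {
    d <- sqrt(outer((seq_len(nrow(m)) - ctr[1])^2,
                    (seq_len(ncol(m)) - ctr[2])^2, "+"))
    m + amp * exp(-d / lam)
  }
  # two spots 10 px apart
  m <- matrix(0, 40, 40)
  m <- mkSpot(m, c(15, 15), 0.5); m <- mkSpot(m, c(15, 25), 0.4)
  rois <- detectHotspots(m, ampThreshold = 0.05, pixelSize = 0.1625)
  expect_length(rois, 2L)
  ctrs <- t(vapply(rois, function(r) r@center, numeric(2)))
  expect_true(any(rowSums(abs(sweep(ctrs, 2, c(15, 15)))) <= 2))
  expect_true(any(rowSums(abs(sweep(ctrs, 2, c(15, 25)))) <= 2))
  # blank map: none
  expect_length(detectHotspots(matrix(0, 20, 20), ampThreshold = 0.05),
                0L)
  # ten planted spots, min separation 2 um (>12 px at 0.1625 um/px)
  set.seed(8)
  m10 <- matrix(0, 80, 80)
  centers <- expand.grid(r = c(12, 27, 42, 57, 72), c = c(20, 55))
  for (i in seq_len(10))
    m10 <- mkSpot(m10, c(centers$r[i], centers$c[i]),
                  stats::runif(1, 0.3, 0.8), lam = 3)
  rois10 <- detectHotspots(m10, ampThreshold = 0.05, pixelSize = 0.1625)
  expect_length(rois10, 10L)
})

test_that("detection is translation-equivariant and order-invariant", {
  mkSpot <- function(m, ctr, amp) {
    d <- sqrt(outer((seq_len(nrow(m)) - ctr[1])^2,
                    (seq_len(ncol(m)) - ctr[2])^2, "+"))
    m + amp * exp(-d / 2.5)
  }
  m <- mkSpot(mkSpot(matrix(0, 50, 50), c(20, 20), 0.5), c(20, 35), 0.3)
  mShift <- mkSpot(mkSpot(matrix(0, 50, 50), c(25, 22), 0.5), c(25, 37), 0.3)
  r1 <- detectHotspots(m, ampThreshold = 0.05)
  r2 <- detectHotspots(mShift, ampThreshold = 0.05)
  c1 <- t(vapply(r1, function(r) r@center, numeric(2)))
  c2 <- t(vapply(r2, function(r) r@center, numeric(2)))
  expect_equal(nrow(c1), nrow(c2))
  expect_equal(c2[order(c2[, 2]), ] - c1[order(c1[, 2]), ],
               matrix(rep(c(5, 2), each = 2), 2, 2), tolerance = 1e-9)
})

test_that("radial profiles reproduce exponential maps and respect symmetry", {
  n <- 41; lam <- 0.7; px <- 0.1625
  d <- sqrt(outer((1:n - 21)^2, (1:n - 21)^2, "+")) * px
  m <- exp(-d / lam)
  prof <- radialProfile(m, c(21, 21), maxRadius = 2.5, pixelSize = px)
  expect_equal(prof$meanDff[1], 1)  # value at r = 0 equals peak
  pred <- exp(-prof$distUm / lam)
  expect_lt(max(abs(prof$meanDff - pred) / pred), 0.05)
  # isotropy: rotating the map by 90 degrees leaves the profile unchanged
  mRot <- t(m)[, n:1]
  profRot <- radialProfile(mRot, c(21, 21), maxRadius = 2.5, pixelSize = px)
  expect_equal(prof$meanDff, profRot$meanDff, tolerance = 1e-12)
  # neighbor contamination truncates and flags
  prof2 <- radialProfile(m, c(21, 21), maxRadius = 2.5, pixelSize = px,
                         neighborCenters = matrix(c(21, 27), 1, 2))
  expect_true(prof2$truncated)
  expect_lt(max(prof2$distUm), 6 * px / 2 + px)
})

test_that("single-exponential spread fits are exact on noiseless profiles", {
  r <- seq(0, 3, by = 0.1625)
  prof <- list(distUm = r, meanDff = 2 * exp(-r / 0.5))
  fit <- fitSpread(prof)
  expect_equal(spreadConstant(fit), 0.5, tolerance = 1e-6)
  expect_equal(fit@amplitude, 2, tolerance = 1e-6)
  expect_gt(fit@r2, 1 - 1e-10)
  # amplitude scale invariance
  fit3 <- fitSpread(list(distUm = r, meanDff = 6 * exp(-r / 0.5)))
  expect_equal(spreadConstant(fit3), 0.5, tolerance = 1e-6)
  # non-decaying profile rejected
  expect_error(fitSpread(list(distUm = r, meanDff = r * 0.1)), "no decay")
  expect_error(fitSpread(list(distUm = r[1:3], meanDff = r[1:3])), "bins")
})

test_that("deconvolution tightens the apparent spread constant toward truth", {
  res <- t(vapply(1:3, function(s) {
    out <- makeHotspotMovie(lambda = 0.74, seed = s)
    recoverSpread(out$movie, rawToo = TRUE)
  }, numeric(2)))
  # direction: lambda(deconvolved) <= lambda(raw) on every blurred fixture
  expect_true(all(res[, "dec"] <= res[, "raw"]))
  # and nearer the generating constant
  expect_true(all(abs(res[, "dec"] - 0.74) < abs(res[, "raw"] - 0.74)))
})

test_that("spread estimates converge as noise vanishes and pixels shrink", {
  lam <- 0.74
  errAt <- function(px, n) {
    d <- sqrt(outer((1:n - (n + 1) / 2)^2, (1:n - (n + 1) / 2)^2, "+")) * px
    m <- 0.5 * exp(-d / lam)
    prof <- radialProfile(m, c((n + 1) / 2, (n + 1) / 2), maxRadius = 2.5,
                          pixelSize = px)
    abs(spreadConstant(fitSpread(prof)) - lam) / lam
  }
  errs <- c(errAt(0.3, 25), errAt(0.1625, 47), errAt(0.08, 91))
  expect_true(all(diff(errs) < 0))       # refinement ladder improves
  expect_lt(errs[3], 0.01)
})

test_that("ROI coefficient of variation follows its definition", {
  expect_equal(roiCV(c(5, 5, 5, 5)), 0)
  expect_equal(roiCV(c(1, 3)), sqrt(2) / 2, tolerance = 1e-12)
  expect_equal(roiCV(c(2, 4, 6)), 0.5, tolerance = 1e-12)
  expect_error(roiCV(c(3)), "2 pixels")
  expect_error(roiCV(c(-1, 1)), "mean is zero")
})

test_that("dF/F0 versus F0 correlation behaves at the constructed extremes", {
  set.seed(9)
  f0 <- matrix(stats::runif(900, 500, 1500), 30, 30)
  propor <- f0 * 2e-4
  cc <- dffF0Correlation(propor, f0, nBoot = 200)
  expect_gt(cc$r, 0.99)
  anti <- max(f0) * 2e-4 - propor
  expect_lt(dffF0Correlation(anti, f0, nBoot = 200)$r, -0.99)
  indep <- matrix(stats::runif(900), 30, 30)
  expect_lt(abs(dffF0Correlation(indep, f0, nBoot = 200)$r), 0.2)
  flagged <- dffF0Correlation(indep, matrix(1, 30, 30), nBoot = 50)
  expect_true(flagged$flagged)
})
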