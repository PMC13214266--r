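test_that("translational registration recovers known shifts", {
  base <- texturedImage(1)
  shifted <- fluoQuanta:::.shiftImage(base, 3, -2)
  stk <- array(c(base, shifted), c(40, 40, 2))
  reg <- registerTranslation(stk)
  # correcting shift is the negative of the applied content shift
  expect_lt(abs(reg$shifts[2, "dy"] + 3), 0.1)
  expect_lt(abs(reg$shifts[2, "dx"] - 2), 0.1)
  expect_equal(unname(reg$shifts[1, ]), c(0, 0))
  # sub-pixel
  shifted2 <- fluoQuanta:::.shiftImage(base, 0.6, -0.4)
  reg2 <- registerTranslation(array(c(base, shifted2), c(40, 40, 2)))
  expect_lt(abs(reg2$shifts[2, "dy"] + 0.6), 0.1)
  expect_lt(abs(reg2$shifts[2, "dx"] - 0.4), 0.1)
})

test_that("registration is a no-op on identical frames and idempotent", {
  base <- texturedImage(2)
  stk <- array(rep(base, 3), c(40, 40, 3))
  reg <- registerTranslation(stk)
  expect_true(all(abs(reg$shifts) < 1e-9))
  # idempotence on an already-aligned stack
  shifted <- fluoQuanta:::.shiftImage(base, 2, 1)
  reg1 <- registerTranslation(array(c(base, shifted), c(40, 40, 2)))
  reg2 <- registerTranslation(reg1$aligned)
  expect_true(all(abs(reg2$shifts) <= 0.05))
})

test_that("noise-only frames are flagged by the similarity metric", {
  set.seed(3)
  a <- matrix(stats::rnorm(1600), 40, 40)
  b <- matrix(stats::rnorm(1600), 40, 40)
  reg <- registerTranslation(array(c(a, b), c(40, 40, 2)))
  expect_true(reg$flagged[2])
})

test_that("movement scores track displacement magnitude and AMMS", {
  base <- texturedImage(4)
  # static movie
  stat <- array(rep(base, 3), c(40, 40, 3))
  ms0 <- movementScores(stat, stimWindow = c(2, 3))
  expect_true(all(ms0$scores == 0))
  expect_equal(ms0$amms, 0)
  # rigid 2 px shift on one frame
  stk <- array(c(base, base, fluoQuanta:::.shiftImage(base, 2, 0), base),
               c(40, 40, 4))
  ms <- movementScores(stk, stimWindow = c(3, 4))
  expect_lt(abs(ms$scores[3] - 2), 0.5)
  expect_lt(abs(ms$amms - 2), 0.5)
  # ~1 px jitter confined to the stim window
  j <- sqrt(2) / 2
  stk2 <- array(c(base, base, fluoQuanta:::.shiftImage(base, j, j),
                  fluoQuanta:::.shiftImage(base, -j, -j)), c(40, 40, 4))
  ms2 <- movementScores(stk2, stimWindow = c(3, 4))
  expect_lt(abs(ms2$amms - 1), 0.35)
  expect_error(movementScores(stk, stimWindow = c(5, 9)), "empty")
})

test_that("Landweber deconvolution is a fixed point under a delta PSF", {
  set.seed(5)
  img <- matrix(stats::runif(400, 0, 100), 20, 20)
  delta <- matrix(0, 3, 3); delta[2, 2] <- 1
  dec <- landweberDeconvolve(img, delta, nIter = 10)
  expect_equal(dec$deconvolved, img, tolerance = 1e-8)
})

test_that("Landweber residual decreases monotonically and sharpens a blurred point", {
  psf <- gaussianPSF(0.25, 0.1625)
  src <- matrix(0, 32, 32); src[16, 16] <- 100
  blurred <- fluoQuanta:::.convolve2d(src, psf)
  dec <- landweberDeconvolve(blurred, psf, nIter = 50)
  expect_true(all(diff(dec$residualMSE) <= 1e-12))
  expect_gt(max(dec$deconvolved), max(blurred))
  expect_true(all(dec$deconvolved >= 0))
  expect_error(landweberDeconvolve(blurred, matrix(0, 3, 3)), "zero")
  expect_error(landweberDeconvolve(blurred, psf, step = 1e6), "stable range")
})

test_that("baseline fitting flattens exponential bleaching", {
  # flat trace: factors 1
  flat <- array(500, c(2, 2, 120))
  bl <- fitBaseline(flat, c(1, 30), c(91, 120), frameRate = 10)
  expect_equal(bl$factors, array(1, c(2, 2, 120)), tolerance = 1e-9)
  # single exponential decay over 200 s, tau 50 s
  tt <- seq(0, 199.9, by = 0.1)[seq(1, 2000, by = 10)]  # 1 Hz, 200 frames
  tr <- 800 * exp(-tt / 50)
  stk <- array(rep(tr, each = 4), c(2, 2, 200))
  bl1 <- fitBaseline(stk, c(1, 40), c(161, 200), frameRate = 1)
  v <- bl1$corrected[1, 1, ]
  ctrl <- c(1:40, 161:200)
  slope <- stats::coef(stats::lm(v[ctrl] ~ ctrl))[2]
  # corrected control slope below 1% of F0 per 100 s
  expect_lt(abs(slope) * 100, 0.01 * 800)
  # two-term decay recovered within 1% RMS on the control windows
  tr2 <- 1000 * (0.8 * exp(-tt / 30) + 0.2 * exp(-tt / 300))
  stk2 <- array(rep(tr2, each = 4), c(2, 2, 200))
  bl2 <- fitBaseline(stk2, c(1, 40), c(161, 200), frameRate = 1)
  co <- bl2$coef[1, 1, ]
  pred <- co[1] * exp(co[2] * tt[ctrl]) + co[3] * exp(co[4] * tt[ctrl])
  expect_lt(sqrt(mean((pred - tr2[ctrl])^2)) / mean(tr2[ctrl]), 0.01)
})

test_that("temporal denoising suppresses noise and keeps stimulus peaks", {
  # constant trace untouched
  const <- array(100, c(2, 2, 60))
  expect_equal(denoiseTraces(const, span = 15), const)
  # white noise on a flat signal: SD reduced below sigma / 2
  set.seed(6)
  sig <- 5
  noisy <- array(200 + stats::rnorm(4 * 200, 0, sig), c(2, 2, 200))
  den <- denoiseTraces(noisy, span = 15)
  expect_lt(stats::sd(den[1, 1, ] - 200), sig / 2)
  # sensor-shaped transient: smoothed peak at least 80% of the true peak
  tt <- (0:199) / 10
  tr <- 100 * (1 + 0.5 * sensorImpulse(tt - 5, 0.1, 8.96))
  stk <- array(rep(tr, each = 4), c(2, 2, 200))
  den2 <- denoiseTraces(stk, span = 15)
  expect_gt(max(den2[1, 1, ]) - 100, 0.8 * 50)
  expect_error(denoiseTraces(noisy, span = 2), "span")
})

test_that("background subtraction removes uniform offsets exactly", {
  set.seed(7)
  stk <- array(stats::runif(16 * 16 * 5, 100, 200), c(16, 16, 5))
  roi <- matrix(FALSE, 16, 16); roi[1:4, 1:4] <- TRUE
  # constant offset invariance
  out1 <- subtractBackground(stk, roi)
  out2 <- subtractBackground(stk + 100, roi)
  expect_equal(out1, out2, tolerance = 1e-10)
  # time-varying background removed exactly in the noiseless case
  b <- c(10, 20, 30, 40, 50)
  stkB <- sweep(stk, 3, b, "+")
  expect_equal(subtractBackground(stkB, roi), out1, tolerance = 1e-10)
  expect_error(subtractBackground(stk, matrix(FALSE, 16, 16)), "empty")
})

test_that("dF/F0 arithmetic and masking are exact", {
  stk <- array(200, c(4, 4, 10))
  stk[, , 6:10] <- 400
  d <- computeDFF(stk, c(1, 5))
  expect_true(all(d$dff[, , 1:5] == 0))
  expect_true(all(d$dff[, , 6:10] == 1))
  stk[1, 1, ] <- c(rep(200, 5), 201, rep(200, 4))
  d2 <- computeDFF(stk, c(1, 5))
  expect_equal(d2$dff[1, 1, 6], 0.005)
  # F0 floor masking
  stk[2, 2, ] <- 1
  d3 <- computeDFF(stk, c(1, 5))
  expect_true(all(is.na(d3$dff[2, 2, ])))
  expect_error(computeDFF(array(0, c(2, 2, 4)), c(1, 2)), "all-zero")
})

test_that("the preprocessing chain applies stages in the documented order", {
  out <- makeHotspotMovie(seed = 21, noise = FALSE, psfSigma = 0.25)
  pre <- preprocessMovie(out$movie, psf = gaussianPSF(0.25, PX),
                         stages = c("deconvolve", "denoise"),
                         f0Window = c(1, 19))
  expect_identical(pre$appliedOrder, c("deconvolve", "denoise"))
  expect_true(!is.null(pre$diagnostics$deconvolution))
  expect_error(preprocessMovie(out$movie, stages = "deconvolve"),
               "no PSF")
})
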