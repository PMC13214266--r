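# Image-processing chain applied to raw movies before any physiology is
# quantified, in this fixed order: translational alignment, Landweber
# deconvolution against the measured PSF, per-pixel photobleaching
# (baseline) correction, temporal denoising, background subtraction, and
# finally dF/F0 computation.

# ---- registration -----------------------------------------------------

.mseAt <- function(moving, reference, dy, dx) {
  mean((.shiftImage(moving, dy, dx) - reference)^2)
}

.goldenRefine <- function(f, lo, hi, tol = 0.01, maxIter = 40L) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c_ <- b - gr * (b - a); d <- a + gr * (b - a)
  fc <- f(c_); fd <- f(d); it <- 2L
  while (abs(b - a) > tol && it < maxIter) {
    if (fc < fd) { b <- d; d <- c_; fd <- fc; c_ <- b - gr * (b - a); fc <- f(c_) }
    else { a <- c_; c_ <- d; fc <- fd; d <- a + gr * (b - a); fd <- f(d) }
    it <- it + 1L
  }
  list(x = (a + b) / 2, iter = it)
}

#' Translational intensity-based registration of an image stack
#'
#' Aligns every frame to a reference frame by minimizing the mean squared
#' intensity difference over translations, using a coarse-to-fine integer
#' grid search followed by golden-section sub-pixel refinement on each axis
#' (bilinear interpolation). Iteration stops at diminishing returns or after
#' \code{maxIter} refinement steps per frame.
#'
#' @param stack 3-D array or \linkS4class{FluorescenceMovie}.
#' @param referenceIndex frame used as the fixed reference.
#' @param maxShift largest shift searched, pixels.
#' @param maxIter refinement iteration cap per frame (<= 200).
#' @param flagThreshold frames whose post-alignment normalized correlation
#'   with the reference falls below this are flagged (not dropped).
#' @return list (registration result): \code{aligned} (array),
#'   \code{shifts} (frames x 2, \code{dy}, \code{dx}; reference row is 0,0),
#'   \code{metric} (per-frame MSE after alignment), \code{iterations},
#'   \code{flagged} (logical per frame).
#' @export
registerTranslation <- function(stack, referenceIndex = 1L, maxShift = NULL,
                                maxIter = 200L, flagThreshold = 0.3) {
  x <- .asStack(stack)
  stopifnot(length(dim(x)) == 3L, dim(x)[3] >= 2L)
  nf <- dim(x)[3]
  if (is.null(maxShift)) maxShift <- floor(min(dim(x)[1:2]) / 4)
  ref <- x[, , referenceIndex]
  shifts <- matrix(0, nf, 2, dimnames = list(NULL, c("dy", "dx")))
  metric <- numeric(nf)
  iters <- integer(nf)
  flagged <- logical(nf)
  aligned <- x
  refSd <- stats::sd(ref)
  for (t in seq_len(nf)) {
    if (t == referenceIndex) { metric[t] <- 0; next }
    fr <- x[, , t]
    # coarse-to-fine integer grid
    best <- c(0, 0); bestVal <- .mseAt(fr, ref, 0, 0); it <- 0L
    for (stepPx in unique(pmax(1, c(floor(maxShift / 4), 2, 1)))) {
      improved <- TRUE
      while (improved && it < maxIter) {
        improved <- FALSE
        for (d in list(c(stepPx, 0), c(-stepPx, 0), c(0, stepPx), c(0, -stepPx))) {
          cand <- best + d
          if (any(abs(cand) > maxShift)) next
          v <- .mseAt(fr, ref, cand[1], cand[2]); it <- it + 1L
          if (v < bestVal * (1 - 1e-9)) { bestVal <- v; best <- cand; improved <- TRUE }
        }
      }
    }
    # golden-section sub-pixel refinement, alternating axes
    for (rep in 1:2) {
      gy <- .goldenRefine(function(dy) .mseAt(fr, ref, dy, best[2]),
                          best[1] - 1, best[1] + 1)
      best[1] <- gy$x; it <- it + gy$iter
      gx <- .goldenRefine(function(dx) .mseAt(fr, ref, best[1], dx),
                          best[2] - 1, best[2] + 1)
      best[2] <- gx$x; it <- it + gx$iter
      if (it >= maxIter) break
    }
    shifts[t, ] <- best
    aligned[, , t] <- .shiftImage(fr, best[1], best[2])
    metric[t] <- .mseAt(fr, ref, best[1], best[2])
    iters[t] <- min(it, maxIter)
    cc <- suppressWarnings(stats::cor(as.vector(aligned[, , t]), as.vector(ref)))
    flagged[t] <- !is.finite(cc) || cc < flagThreshold || refSd == 0
  }
  list(aligned = aligned, shifts = shifts, metric = metric,
       iterations = iters, flagged = flagged,
       referenceIndex = referenceIndex)
}

# ---- movement diagnostics ---------------------------------------------

# Demons-style dense displacement field between two frames: gradient-driven
# force smoothed by a Gaussian, run over 3 resolution scales.
.demonsField <- function(moving, fixed, nScales = 3L, itersPerScale = 20L,
                         smoothSigma = 1.5) {
  down <- function(m, f) {
    if (f == 1L) return(m)
    nr <- floor(nrow(m) / f) * f; nc <- floor(ncol(m) / f) * f
    m <- m[seq_len(nr), seq_len(nc), drop = FALSE]
    ri <- (seq_len(nr) - 1L) %/% f + 1L
    ci <- (seq_len(nc) - 1L) %/% f + 1L
    rowsum(t(rowsum(m, ri)), ci) / (f * f)
  }
  smooth2 <- function(m, sigma) {
    k <- .gauss1d(sigma)
    kk <- outer(k, k)
    .convolve2d(m, kk)
  }
  warpBy <- function(img, uy, ux) {
    # per-pixel backward warp via bilinear sampling
    nr <- nrow(img); nc <- ncol(img)
    yi <- pmin(pmax(matrix(seq_len(nr), nr, nc) - uy, 1), nr)
    xi <- pmin(pmax(matrix(seq_len(nc), nr, nc, byrow = TRUE) - ux, 1), nc)
    y0 <- pmin(floor(yi), nr - 1); x0 <- pmin(floor(xi), nc - 1)
    wy <- yi - y0; wx <- xi - x0
    idx <- function(r, c) img[cbind(as.vector(r), as.vector(c))]
    out <- idx(y0, x0) * (1 - wy) * (1 - wx) + idx(y0 + 1, x0) * wy * (1 - wx) +
      idx(y0, x0 + 1) * (1 - wy) * wx + idx(y0 + 1, x0 + 1) * wy * wx
    matrix(out, nr, nc)
  }
  scales <- rev(2^(seq_len(nScales) - 1L))  # e.g. 4, 2, 1
  uy <- NULL; ux <- NULL
  for (f in scales) {
    M <- down(moving, f); F_ <- down(fixed, f)
    if (is.null(uy)) {
      uy <- matrix(0, nrow(F_), ncol(F_)); ux <- uy
    } else {
      # upsample previous field (nearest, scaled)
      ri <- pmin((seq_len(nrow(F_)) - 1L) %/% 2 + 1L, nrow(uy))
      ci <- pmin((seq_len(ncol(F_)) - 1L) %/% 2 + 1L, ncol(ux))
      uy <- 2 * uy[ri, ci, drop = FALSE]; ux <- 2 * ux[ri, ci, drop = FALSE]
    }
    gy <- (rbind(F_[-1, , drop = FALSE], F_[nrow(F_), , drop = FALSE]) -
           rbind(F_[1, , drop = FALSE], F_[-nrow(F_), , drop = FALSE])) / 2
    gx <- (cbind(F_[, -1, drop = FALSE], F_[, ncol(F_), drop = FALSE]) -
           cbind(F_[, 1, drop = FALSE], F_[, -ncol(F_), drop = FALSE])) / 2
    g2 <- gy^2 + gx^2
    for (i in seq_len(itersPerScale)) {
      W <- warpBy(M, uy, ux)
      diffI <- W - F_
      denom <- g2 + diffI^2
      ok <- denom > 1e-12
      fy <- matrix(0, nrow(F_), ncol(F_)); fx <- fy
      fy[ok] <- diffI[ok] * gy[ok] / denom[ok]
      fx[ok] <- diffI[ok] * gx[ok] / denom[ok]
      uy <- smooth2(uy + fy, smoothSigma)
      ux <- smooth2(ux + fx, smoothSigma)
    }
  }
  list(uy = uy, ux = ux)
}

#' Per-frame movement scores and the AMMS motion diagnostic
#'
#' Computes, for every frame, the mean per-pixel displacement magnitude
#' (pixels) of a dense displacement field estimated against the reference
#' frame by a diffeomorphic-demons-style iteration (3 scales, 20 iterations
#' per scale). The adjusted maximum movement displacement score (AMMS) is
#' the maximum absolute deviation of the movement score during the
#' stimulation window from its pre-stimulus mean.
#'
#' @param stack 3-D array or \linkS4class{FluorescenceMovie}.
#' @param stimWindow integer(2), first and last frame of the stimulation
#'   window.
#' @param referenceIndex reference frame index.
#' @return list: \code{scores} (per frame, pixels), \code{amms} (pixels).
#' @export
movementScores <- function(stack, stimWindow, referenceIndex = 1L) {
  x <- .asStack(stack)
  nf <- dim(x)[3]
  if (length(stimWindow) != 2L || stimWindow[1] > stimWindow[2])
    stop("'stimWindow' must be c(first, last)")
  if (stimWindow[1] < 1L || stimWindow[2] > nf) stop("stim window empty")
  ref <- x[, , referenceIndex]
  scores <- numeric(nf)
  for (t in seq_len(nf)) {
    if (t == referenceIndex || identical(x[, , t], ref)) { scores[t] <- 0; next }
    fld <- .demonsField(x[, , t], ref)
    scores[t] <- mean(sqrt(fld$uy^2 + fld$ux^2))
  }
  pre <- seq_len(max(1L, stimWindow[1] - 1L))
  preMean <- mean(scores[pre])
  amms <- max(abs(scores[stimWindow[1]:stimWindow[2]] - preMean))
  list(scores = scores, amms = amms, preStimMean = preMean)
}

# ---- Landweber deconvolution ------------------------------------------

.powerIterL <- function(psf, dims, nIter = 30L, seed = 1L) {
  set.seed(seed)
  v <- matrix(stats::rnorm(prod(dims)), dims[1], dims[2])
  flipped <- psf[rev(seq_len(nrow(psf))), rev(seq_len(ncol(psf))), drop = FALSE]
  L <- 1
  for (i in seq_len(nIter)) {
    w <- .convolve2d(.convolve2d(v, psf), flipped)
    L <- sqrt(sum(w^2)) / sqrt(sum(v^2))
    v <- w / sqrt(sum(w^2))
  }
  L
}

#' Landweber deconvolution with non-negativity constraint
#'
#' Iterative gradient descent on the least-squares cost
#' \code{||H x - y||^2} for the blur operator H (convolution with the PSF,
#' reflective boundaries), with projection onto the non-negative orthant at
#' each step:
#' \code{x_{k+1} = max(0, x_k + alpha * H^T (y - H x_k))}.
#' The default step \code{alpha = 1/L}, with L the largest eigenvalue of
#' \code{H^T H} estimated by power iteration, guarantees a monotone
#' non-increasing residual. Applied independently to each frame of a stack.
#'
#' @param stack 2-D matrix, 3-D array or \linkS4class{FluorescenceMovie}.
#' @param psf PSF kernel, non-negative, normalized to unit sum.
#' @param nIter iterations (default 50).
#' @param step step size alpha; NULL for 1/L. Must lie in (0, 2/L).
#' @return list (deconvolution result): \code{deconvolved} (same shape as
#'   input), \code{residualMSE} (per iteration, averaged over frames),
#'   \code{snr} (per-iteration peak-signal / residual-RMS estimate),
#'   \code{iterations}, \code{step}, \code{L}.
#' @export
landweberDeconvolve <- function(stack, psf, nIter = 50L, step = NULL) {
  x <- .asStack(stack)
  if (all(psf == 0)) stop("psf must not be all zeros")
  if (any(psf < 0)) stop("psf must be non-negative")
  psf <- psf / sum(psf)
  twoD <- length(dim(x)) == 2L || is.null(dim(x))
  if (twoD) x <- array(x, dim = c(dim(as.matrix(x)), 1L))
  dims <- dim(x)[1:2]
  L <- .powerIterL(psf, dims)
  if (is.null(step)) step <- 1 / L
  if (step <= 0 || step >= 2 / L) stop("step size outside stable range (0, 2/L)")
  flipped <- psf[rev(seq_len(nrow(psf))), rev(seq_len(ncol(psf))), drop = FALSE]
  nf <- dim(x)[3]
  out <- x
  resMSE <- matrix(0, nIter, nf)
  snr <- matrix(0, nIter, nf)
  for (t in seq_len(nf)) {
    y <- x[, , t]
    xk <- pmax(y, 0)
    for (k in seq_len(nIter)) {
      r <- y - .convolve2d(xk, psf)
      xk <- pmax(xk + step * .convolve2d(r, flipped), 0)
      resMSE[k, t] <- mean(r^2)
      rsd <- stats::sd(r)
      snr[k, t] <- if (rsd > 0) max(xk) / rsd else Inf
    }
    out[, , t] <- xk
  }
  list(deconvolved = if (twoD) out[, , 1] else out,
       residualMSE = rowMeans(resMSE), snr = rowMeans(snr),
       iterations = nIter, step = step, L = L)
}

# ---- baseline (photobleaching) correction ------------------------------

.fitPixelBaseline <- function(tt, vv) {
  # two-term exponential, then single-exponential, then flat fallback
  m0 <- mean(vv)
  fit2 <- tryCatch({
    f <- minpack.lm::nlsLM(vv ~ a * exp(b * tt) + c_ * exp(d * tt),
                           start = list(a = 0.7 * m0, b = -1 / max(tt),
                                        c_ = 0.3 * m0, d = -1 / (10 * max(tt))),
                           control = minpack.lm::nls.lm.control(maxiter = 100))
    co <- stats::coef(f)
    list(coef = c(co[["a"]], co[["b"]], co[["c_"]], co[["d"]]), mode = 0L)
  }, error = function(e) NULL)
  if (!is.null(fit2)) {
    pred <- fit2$coef[1] * exp(fit2$coef[2] * tt) + fit2$coef[3] * exp(fit2$coef[4] * tt)
    if (all(is.finite(pred)) && all(pred > 0)) return(fit2)
  }
  fit1 <- tryCatch({
    f <- minpack.lm::nlsLM(vv ~ a * exp(b * tt),
                           start = list(a = m0, b = -1 / max(tt)),
                           control = minpack.lm::nls.lm.control(maxiter = 100))
    co <- stats::coef(f)
    list(coef = c(co[["a"]], co[["b"]], 0, 0), mode = 1L)
  }, error = function(e) NULL)
  if (!is.null(fit1)) {
    pred <- fit1$coef[1] * exp(fit1$coef[2] * tt)
    if (all(is.finite(pred)) && all(pred > 0)) return(fit1)
  }
  list(coef = c(m0, 0, 0, 0), mode = 2L)
}

#' Fit and flatten the slow fluorescence baseline, pixel by pixel
#'
#' Fits a two-term exponential \code{F_base(t) = a e^{bt} + c e^{dt}} to the
#' control windows (typically the first and last 10 s of the movie) of every
#' pixel's trace, independently per pixel, and derives per-frame
#' multiplication factors \code{F_base(t_1) / F_base(t)} that flatten the
#' baseline when applied to the whole sequence. Pixels where the two-term
#' fit diverges fall back to a single exponential, then to a flat baseline;
#' the fallback mode is recorded per pixel.
#'
#' @param stack 3-D array or \linkS4class{FluorescenceMovie}.
#' @param preWindow,postWindow integer(2) frame ranges of the two control
#'   windows (must not overlap the stimulation period).
#' @param frameRate frames per second (taken from the movie if given one).
#' @return list (baseline model): \code{coef} (rows x cols x 4),
#'   \code{factors} (same shape as stack), \code{fallback} (matrix, 0 =
#'   two-term, 1 = single, 2 = flat), plus \code{corrected} = stack *
#'   factors.
#' @export
fitBaseline <- function(stack, preWindow, postWindow, frameRate = NULL) {
  if (is(stack, "FluorescenceMovie") && is.null(frameRate))
    frameRate <- frameRate(stack)
  x <- .asStack(stack)
  if (is.null(frameRate)) frameRate <- 1
  nf <- dim(x)[3]
  stopifnot(preWindow[1] >= 1, postWindow[2] <= nf,
            preWindow[2] < postWindow[1])
  ctrlIdx <- c(preWindow[1]:preWindow[2], postWindow[1]:postWindow[2])
  tt <- (ctrlIdx - 1) / frameRate
  tAll <- (seq_len(nf) - 1) / frameRate
  nr <- dim(x)[1]; nc <- dim(x)[2]
  coefArr <- array(0, dim = c(nr, nc, 4))
  fallback <- matrix(0L, nr, nc)
  factors <- array(1, dim = dim(x))
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    vv <- x[i, j, ctrlIdx]
    if (stats::sd(vv) == 0) {
      coefArr[i, j, ] <- c(mean(vv), 0, 0, 0); fallback[i, j] <- 2L
      next
    }
    ft <- .fitPixelBaseline(tt, vv)
    coefArr[i, j, ] <- ft$coef
    fallback[i, j] <- ft$mode
    base <- ft$coef[1] * exp(ft$coef[2] * tAll) + ft$coef[3] * exp(ft$coef[4] * tAll)
    base[!is.finite(base) | base <= 0] <- mean(vv)
    factors[i, j, ] <- base[1] / base
  }
  list(coef = coefArr, factors = factors, fallback = fallback,
       corrected = x * factors)
}

# ---- denoising ---------------------------------------------------------

#' Temporal denoising by locally weighted smoothing, pixel by pixel
#'
#' Smooths each pixel's time course with tricube-weighted local regression
#' (LOWESS). Two local models are evaluated per pixel -- linear on the raw
#' trace and linear on the log trace (i.e. locally exponential) -- and the
#' one with the lower residual sum of squares is kept.
#'
#' @param stack 3-D array or \linkS4class{FluorescenceMovie}.
#' @param span smoothing window in frames (default 15); must be >= 3 and
#'   less than the number of frames.
#' @return Smoothed array of the same shape.
#' @export
denoiseTraces <- function(stack, span = 15L) {
  x <- .asStack(stack)
  nf <- dim(x)[3]
  if (span < 3L) stop("span too small for smoothing window")
  if (span >= nf) stop("span must be smaller than the number of frames")
  f <- span / nf
  tt <- seq_len(nf)
  nr <- dim(x)[1]; nc <- dim(x)[2]
  out <- x
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    v <- x[i, j, ]
    if (stats::sd(v) == 0) next
    sLin <- stats::lowess(tt, v, f = f)$y
    rLin <- sum((v - sLin)^2)
    if (all(v > 0)) {
      sExp <- exp(stats::lowess(tt, log(v), f = f)$y)
      rExp <- sum((v - sExp)^2)
      out[i, j, ] <- if (rExp < rLin) sExp else sLin
    } else out[i, j, ] <- sLin
  }
  out
}

# ---- background subtraction --------------------------------------------

#' Subtract the background level estimated from a non-responsive region
#'
#' For each frame, the mean over the background ROI is subtracted uniformly
#' from the whole frame, removing time-varying ambient background exactly in
#' the noiseless case.
#'
#' @param stack 3-D array or \linkS4class{FluorescenceMovie}.
#' @param backgroundROI logical matrix (rows x cols) marking background
#'   pixels, disjoint from the cell ROI.
#' @return Background-corrected array.
#' @export
subtractBackground <- function(stack, backgroundROI) {
  x <- .asStack(stack)
  stopifnot(is.logical(backgroundROI),
            all(dim(backgroundROI) == dim(x)[1:2]))
  if (!any(backgroundROI)) stop("background ROI is empty")
  for (t in seq_len(dim(x)[3])) {
    fr <- x[, , t]
    x[, , t] <- fr - mean(fr[backgroundROI])
  }
  x
}

# ---- dF/F0 -------------------------------------------------------------

#' Compute the dF/F0 stack and the basal fluorescence map
#'
#' \code{dF/F0 = (F - F0) / F0} with F0 the per-pixel mean over the
#' pre-stimulus window. Pixels whose F0 falls below \code{floorFrac} of the
#' median F0 are masked (NA) to avoid dividing by sensor-free background.
#'
#' @param stack 3-D array or \linkS4class{FluorescenceMovie}.
#' @param f0Window integer(2), frame range preceding the first stimulus.
#' @param floorFrac F0 floor as a fraction of the median F0 (default 0.05).
#' @return list: \code{dff} (array), \code{f0} (matrix), \code{mask}
#'   (logical matrix of analyzable pixels).
#' @export
computeDFF <- function(stack, f0Window, floorFrac = 0.05) {
  x <- .asStack(stack)
  stopifnot(f0Window[1] >= 1, f0Window[2] <= dim(x)[3],
            f0Window[1] <= f0Window[2])
  f0 <- apply(x[, , f0Window[1]:f0Window[2], drop = FALSE], c(1, 2), mean)
  if (all(f0 == 0)) stop("all-zero F0")
  floorVal <- floorFrac * stats::median(f0[f0 > 0])
  mask <- f0 >= floorVal
  dff <- array(NA_real_, dim = dim(x))
  for (t in seq_len(dim(x)[3])) {
    fr <- (x[, , t] - f0) / f0
    fr[!mask] <- NA_real_
    dff[, , t] <- fr
  }
  list(dff = dff, f0 = f0, mask = mask)
}

# ---- chained pipeline ---------------------------------------------------

#' Run the ordered preprocessing chain on a movie
#'
#' Applies, in the fixed order, the stages enabled in \code{stages}:
#' alignment, deconvolution, baseline correction, denoising, background
#' subtraction; then computes dF/F0. The applied order and stage parameters
#' are echoed in the result.
#'
#' @param movie a \linkS4class{FluorescenceMovie}.
#' @param psf PSF kernel for deconvolution (required if that stage is on).
#' @param f0Window frame range for F0 (default: all frames before the first
#'   stimulus).
#' @param stages character subset of
#'   \code{c("align", "deconvolve", "baseline", "denoise", "background")}.
#' @param backgroundROI logical matrix for the background stage.
#' @param preWindow,postWindow control windows for the baseline stage.
#' @param nIter Landweber iterations.
#' @param span denoiser window (frames).
#' @return list: \code{corrected} (array after the enabled stages),
#'   \code{dff}, \code{f0}, \code{mask}, \code{diagnostics} (per-stage
#'   outputs), \code{appliedOrder}.
#' @export
preprocessMovie <- function(movie, psf = NULL,
                            f0Window = NULL,
                            stages = c("align", "deconvolve"),
                            backgroundROI = NULL,
                            preWindow = NULL, postWindow = NULL,
                            nIter = 50L, span = 15L) {
  stopifnot(is(movie, "FluorescenceMovie"))
  x <- movieData(movie)
  diag <- list()
  order <- character()
  if ("align" %in% stages) {
    reg <- registerTranslation(x)
    x <- reg$aligned
    diag$registration <- reg[c("shifts", "metric", "iterations", "flagged")]
    order <- c(order, "align")
  }
  if ("deconvolve" %in% stages) {
    if (is.null(psf)) stop("deconvolution requested but no PSF given")
    dec <- landweberDeconvolve(x, psf, nIter = nIter)
    x <- dec$deconvolved
    diag$deconvolution <- dec[c("residualMSE", "snr", "iterations", "step")]
    order <- c(order, "deconvolve")
  }
  if ("baseline" %in% stages) {
    if (is.null(preWindow) || is.null(postWindow))
      stop("baseline stage needs preWindow and postWindow")
    bl <- fitBaseline(x, preWindow, postWindow, frameRate = frameRate(movie))
    x <- bl$corrected
    diag$baseline <- bl[c("coef", "fallback")]
    order <- c(order, "baseline")
  }
  if ("denoise" %in% stages) {
    x <- denoiseTraces(x, span = span)
    order <- c(order, "denoise")
  }
  if ("background" %in% stages) {
    if (is.null(backgroundROI)) stop("background stage needs a background ROI")
    x <- subtractBackground(x, backgroundROI)
    order <- c(order, "background")
  }
  if (is.null(f0Window)) {
    firstStim <- if (length(stimTimes(movie)))
      max(2L, floor(min(stimTimes(movie)) * frameRate(movie))) else dim(x)[3]
    f0Window <- c(1L, firstStim)
  }
  d <- computeDFF(x, f0Window)
  list(corrected = x, dff = d$dff, f0 = d$f0, mask = d$mask,
       diagnostics = diag, appliedOrder = order, f0Window = f0Window)
}
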