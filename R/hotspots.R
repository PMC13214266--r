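# Release-site detection on pixel-wise maximal dF/F0 maps, radial profile
# extraction, and single-exponential spatial spread fitting.

#' Pixel-wise maximal dF/F0 map
#'
#' @param dff 3-D dF/F0 array (NA pixels allowed).
#' @param window integer(2) frame range of the analysis window.
#' @param pixelSize micrometers per pixel, attached as an attribute.
#' @return matrix of per-pixel maxima over the window, with attributes
#'   \code{pixelSize} and \code{window}.
#' @export
maxDffMap <- function(dff, window = NULL, pixelSize = NULL) {
  stopifnot(length(dim(dff)) == 3L)
  nf <- dim(dff)[3]
  if (is.null(window)) window <- c(1L, nf)
  if (window[1] < 1L || window[2] > nf || window[1] > window[2])
    stop("analysis window outside stack")
  m <- apply(dff[, , window[1]:window[2], drop = FALSE], c(1, 2),
             function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
  attr(m, "pixelSize") <- pixelSize
  attr(m, "window") <- window
  m
}

# Textbook DBSCAN on integer pixel coordinates (Euclidean eps, minPts
# including the point itself). Returns cluster labels; 0 = noise.
.dbscanPixels <- function(coords, eps, minPts) {
  n <- nrow(coords)
  if (n == 0L) return(integer(0))
  d <- as.matrix(stats::dist(coords))
  neighbors <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  labels <- integer(n)        # 0 = unvisited/noise
  visited <- logical(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (visited[i]) next
    visited[i] <- TRUE
    nb <- neighbors[[i]]
    if (length(nb) < minPts) next   # noise (may be claimed later)
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(nb, i)
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      if (!visited[j]) {
        visited[j] <- TRUE
        nbj <- neighbors[[j]]
        if (length(nbj) >= minPts) queue <- c(queue, setdiff(nbj, which(visited)))
      }
      if (labels[j] == 0L) labels[j] <- cl
    }
  }
  labels
}

.quickLambda <- function(map, center, pixelSize, maxRadiusPx = 12L) {
  # crude spread estimate from the radius where the profile drops to 1/e
  prof <- radialProfile(map, center, maxRadius = maxRadiusPx * pixelSize,
                        pixelSize = pixelSize)
  y <- prof$meanDff; r <- prof$distUm
  peak <- y[1]
  if (!is.finite(peak) || peak <= 0) return(NA_real_)
  below <- which(y <= peak / exp(1))
  if (!length(below)) return(max(r))
  r[below[1]]
}

#' Detect release hotspots on a maximal dF/F0 map
#'
#' Thresholds the map, clusters supra-threshold pixels with DBSCAN, and
#' takes each cluster's argmax pixel as a release center. Clusters that
#' harbor several release sites are split iteratively: the dominant
#' hotspot's fitted exponential footprint is subtracted from the map and
#' the cluster's remaining supra-threshold pixels are re-clustered, until
#' no secondary peak survives. Each ROI carries an isolation flag (no other
#' center within \code{isolationFactor} times its rough spread estimate).
#'
#' @param map matrix from \code{\link{maxDffMap}}.
#' @param epsPx DBSCAN neighborhood radius, pixels.
#' @param minPts DBSCAN core-point minimum.
#' @param ampThreshold minimum dF/F0 for a pixel to enter clustering.
#' @param pixelSize micrometers per pixel (falls back to the map attribute).
#' @param isolationFactor isolation radius in units of the rough spread
#'   estimate (default 3).
#' @param maxSplit cap on the peeling iterations per cluster.
#' @return list of \linkS4class{HotspotROI} objects.
#' @export
detectHotspots <- function(map, epsPx = 3, minPts = 5, ampThreshold,
                           pixelSize = NULL, isolationFactor = 3,
                           maxSplit = 5L) {
  stopifnot(epsPx > 0, minPts > 0, ampThreshold > 0)
  if (is.null(pixelSize)) pixelSize <- attr(map, "pixelSize")
  if (is.null(pixelSize)) pixelSize <- 1
  work <- map
  work[is.na(work)] <- -Inf
  supra <- which(work >= ampThreshold, arr.ind = TRUE)
  if (!nrow(supra)) return(list())
  labels <- .dbscanPixels(supra, epsPx, minPts)
  rois <- list()
  nextId <- 1L
  for (cl in setdiff(unique(labels), 0L)) {
    cpix <- supra[labels == cl, , drop = FALSE]
    sub <- work
    centers <- list()
    for (iter in seq_len(maxSplit)) {
      far <- if (!length(centers)) rep(TRUE, nrow(cpix)) else
        vapply(seq_len(nrow(cpix)), function(k) {
          all(vapply(centers, function(ce)
            sqrt(sum((cpix[k, ] - ce$center)^2)) > 2 * epsPx, logical(1)))
        }, logical(1))
      cand <- cpix[far & sub[cpix] >= ampThreshold, , drop = FALSE]
      if (!nrow(cand)) break
      if (length(centers)) {
        # a surviving secondary peak must itself be a dense residual blob
        lab2 <- .dbscanPixels(cand, epsPx, max(3L, ceiling(minPts / 2)))
        if (!any(lab2 > 0L)) break
        cand <- cand[lab2 > 0L, , drop = FALSE]
      }
      ctr <- cand[which.max(sub[cand]), ]
      peak <- map[ctr[1], ctr[2]]
      lam <- .quickLambda(sub, ctr, pixelSize)
      centers[[length(centers) + 1L]] <-
        list(center = as.numeric(ctr), peak = peak,
             lambdaPx = lam / pixelSize)
      if (!is.finite(lam) || lam <= 0) break
      # subtract the fitted exponential footprint before re-examining
      rr <- outer(seq_len(nrow(map)) - ctr[1], rep(1, ncol(map))) ^ 2
      cc <- outer(rep(1, nrow(map)), seq_len(ncol(map)) - ctr[2]) ^ 2
      dUm <- sqrt(rr + cc) * pixelSize
      foot <- sub[ctr[1], ctr[2]] * exp(-dUm / lam)
      sub <- sub - foot
    }
    allPix <- supra[labels == cl, , drop = FALSE]
    for (ce in centers) {
      # assign cluster pixels to the nearest center
      if (length(centers) > 1L) {
        dmine <- sqrt((allPix[, 1] - ce$center[1])^2 + (allPix[, 2] - ce$center[2])^2)
        dother <- sapply(centers, function(o)
          sqrt((allPix[, 1] - o$center[1])^2 + (allPix[, 2] - o$center[2])^2))
        mine <- dmine <= apply(dother, 1, min) + 1e-9
        pix <- allPix[mine, , drop = FALSE]
      } else pix <- allPix
      rois[[nextId]] <- new("HotspotROI", id = nextId,
                            pixels = unname(as.matrix(pix)),
                            center = ce$center,
                            centerUm = (ce$center - 1) * pixelSize,
                            peakDff = ce$peak, isolated = TRUE)
      nextId <- nextId + 1L
    }
  }
  # isolation flags across all detected centers
  if (length(rois) > 1L) {
    ctrs <- t(vapply(rois, function(r) r@center, numeric(2)))
    for (i in seq_along(rois)) {
      lamPx <- .quickLambda(work, rois[[i]]@center, pixelSize) / pixelSize
      if (!is.finite(lamPx)) lamPx <- epsPx
      dd <- sqrt(rowSums((ctrs - matrix(ctrs[i, ], nrow(ctrs), 2,
                                        byrow = TRUE))^2))
      dd[i] <- Inf
      rois[[i]]@isolated <- all(dd > isolationFactor * lamPx)
    }
  }
  rois
}

#' Radial dF/F0 profile around a hotspot center
#'
#' Averages map values in concentric distance bins (default width one
#' pixel) around the center, i.e. over all directions of the transmitter
#' diffusion gradient. If another center lies within \code{maxRadius}, the
#' profile is truncated at half the inter-center distance and flagged.
#'
#' @param map matrix (maximal dF/F0 map).
#' @param center numeric(2) or \linkS4class{HotspotROI}: center pixel
#'   (row, col).
#' @param maxRadius largest distance (um) included.
#' @param pixelSize micrometers per pixel (falls back to map attribute).
#' @param binWidthPx bin width in pixels.
#' @param neighborCenters optional matrix (n x 2) of other centers (pixels).
#' @param refineCenter if TRUE, the center is refined to sub-pixel
#'   precision by an intensity-weighted centroid over the 2-pixel disk
#'   around the argmax pixel before distances are computed, removing the
#'   up-to-half-pixel center quantization from the profile.
#' @return list (radial profile): \code{distUm}, \code{meanDff}, \code{sem},
#'   \code{n} per bin, and \code{truncated} flag. With
#'   \code{refineCenter = FALSE} the first bin is the center pixel itself,
#'   so \code{meanDff[1]} equals the peak.
#' @export
radialProfile <- function(map, center, maxRadius, pixelSize = NULL,
                          binWidthPx = 1, neighborCenters = NULL,
                          refineCenter = FALSE) {
  if (is(center, "HotspotROI")) center <- center@center
  if (is.null(pixelSize)) pixelSize <- attr(map, "pixelSize")
  if (is.null(pixelSize)) pixelSize <- 1
  if (refineCenter) {
    nr0 <- nrow(map); nc0 <- ncol(map)
    dC <- sqrt(outer((seq_len(nr0) - center[1])^2,
                     (seq_len(nc0) - center[2])^2, "+"))
    sel <- dC <= 2 & is.finite(map) & map > 0
    if (sum(sel) >= 3) {
      rows <- matrix(seq_len(nr0), nr0, nc0)
      cols <- matrix(seq_len(nc0), nr0, nc0, byrow = TRUE)
      w <- map[sel]
      center <- c(sum(rows[sel] * w), sum(cols[sel] * w)) / sum(w)
    }
  }
  truncated <- FALSE
  if (!is.null(neighborCenters) && nrow(neighborCenters)) {
    dNb <- sqrt((neighborCenters[, 1] - center[1])^2 +
                (neighborCenters[, 2] - center[2])^2) * pixelSize
    if (any(dNb <= 2 * maxRadius)) {
      maxRadius <- min(maxRadius, min(dNb) / 2)
      truncated <- TRUE
    }
  }
  nr <- nrow(map); nc <- ncol(map)
  dPx <- sqrt(outer((seq_len(nr) - center[1])^2,
                    (seq_len(nc) - center[2])^2, "+"))
  dUm <- dPx * pixelSize
  keep <- dUm <= maxRadius & !is.na(map)
  binUm <- binWidthPx * pixelSize
  # bin 0 is the center pixel; bin k covers ((k-1/2), (k+1/2)] * binUm
  bins <- pmax(0, round(dUm[keep] / binUm))
  vals <- map[keep]
  agg <- tapply(vals, bins, function(v)
    c(mean(v), stats::sd(v) / sqrt(length(v)), length(v)))
  b <- as.integer(names(agg))
  m <- t(vapply(agg, identity, numeric(3)))
  list(distUm = b * binUm, meanDff = unname(m[, 1]),
       sem = unname(m[, 2]), n = as.integer(m[, 3]), truncated = truncated,
       pixelSize = pixelSize)
}

#' Fit a single-exponential spatial decay to a radial profile
#'
#' Nonlinear least squares fit of \code{dFF(r) = A exp(-r / lambda)}
#' (offset fixed at 0 by default) to the binned radial profile; lambda is
#' the spatial spread length constant in micrometers. The 95% CI on lambda
#' comes from the fit covariance.
#'
#' @param profile radial profile from \code{\link{radialProfile}}.
#' @param freeOffset if TRUE, fit \code{A exp(-r/lambda) + c}. The offset
#'   absorbs the positive floor that a max-over-time projection of noisy
#'   traces adds uniformly to the profile.
#' @param weightByCount weight each distance bin by its pixel count (every
#'   pixel carries equal information; annuli at larger radii hold more
#'   pixels). Set FALSE for an unweighted fit.
#' @return A \linkS4class{SpreadFit}.
#' @export
fitSpread <- function(profile, freeOffset = FALSE, weightByCount = TRUE) {
  r <- profile$distUm; y <- profile$meanDff
  w <- if (weightByCount && !is.null(profile$n)) profile$n else rep(1, length(r))
  ok <- is.finite(r) & is.finite(y)
  r <- r[ok]; y <- y[ok]; w <- w[ok]
  if (length(r) < 5L) stop("need at least 5 distance bins")
  if (stats::cor(r, y) >= 0) stop("no decay")
  A0 <- unname(max(y))
  half <- which(y <= A0 / exp(1))
  lam0 <- if (length(half)) max(r[half[1]], 1e-3) else max(r) / 2
  ctl <- minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                    ptol = 1e-12)
  fit <- tryCatch({
    if (freeOffset) {
      minpack.lm::nlsLM(y ~ A * exp(-r / lambda) + c_,
                        start = list(A = A0, lambda = lam0, c_ = 0),
                        lower = c(0, 1e-6, -Inf), weights = w,
                        control = ctl)
    } else {
      minpack.lm::nlsLM(y ~ A * exp(-r / lambda),
                        start = list(A = A0, lambda = lam0),
                        lower = c(0, 1e-6), weights = w, control = ctl)
    }
  }, error = function(e) NULL)
  if (is.null(fit)) {
    return(new("SpreadFit", amplitude = NA_real_, lambda = NA_real_,
               offset = NA_real_, r2 = NA_real_,
               lambdaCI = c(NA_real_, NA_real_), converged = FALSE))
  }
  co <- stats::coef(fit)
  pred <- stats::predict(fit)
  r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  se <- tryCatch(sqrt(diag(stats::vcov(fit)))[["lambda"]],
                 error = function(e) NA_real_)
  ci <- co[["lambda"]] + c(-1, 1) * 1.96 * se
  new("SpreadFit", amplitude = unname(co[["A"]]),
      lambda = unname(co[["lambda"]]),
      offset = if (freeOffset) unname(co[["c_"]]) else 0,
      r2 = r2, lambdaCI = ci, converged = TRUE)
}

#' Coefficient of variation of ROI pixel values
#'
#' Sample standard deviation divided by the mean of all pixel values within
#' the ROI; the spatial-heterogeneity metric used for basal fluorescence.
#'
#' @param map matrix of pixel values.
#' @param roiPixels optional integer matrix (n x 2) of pixel coordinates;
#'   by default all non-NA pixels are used. A plain numeric vector of
#'   values is also accepted.
#' @return CV (numeric).
#' @export
roiCV <- function(map, roiPixels = NULL) {
  vals <- if (is.matrix(map) && !is.null(roiPixels)) map[roiPixels]
          else if (is.matrix(map)) map[!is.na(map)]
          else map
  if (length(vals) < 2L) stop("need at least 2 pixels")
  m <- mean(vals)
  if (m == 0) stop("mean is zero; CV undefined")
  stats::sd(vals) / m
}

#' Rank correlation between maximal dF/F0 and basal fluorescence
#'
#' Spearman correlation across ROI pixels between the response map and the
#' F0 map, with a bootstrap percentile CI. Near-zero values support the
#' interpretation that response localization reflects release rather than
#' sensor expression.
#'
#' @param maxMap maximal dF/F0 map (matrix).
#' @param f0Map basal fluorescence map (matrix, same shape).
#' @param roiPixels optional integer matrix (n x 2); default all pixels
#'   finite in both maps.
#' @param nBoot bootstrap replicates.
#' @param seed RNG seed for the bootstrap.
#' @return list: \code{r}, \code{ci} (2), \code{n}, \code{flagged} (TRUE
#'   when F0 is constant and the correlation undefined).
#' @export
dffF0Correlation <- function(maxMap, f0Map, roiPixels = NULL, nBoot = 1000L,
                             seed = 1L) {
  if (is.null(roiPixels)) {
    keep <- which(is.finite(maxMap) & is.finite(f0Map), arr.ind = TRUE)
  } else keep <- roiPixels
  a <- maxMap[keep]; b <- f0Map[keep]
  if (length(a) < 10L) stop("need at least 10 pixels")
  if (stats::sd(b) == 0)
    return(list(r = NA_real_, ci = c(NA_real_, NA_real_), n = length(a),
                flagged = TRUE))
  r <- stats::cor(a, b, method = "spearman")
  set.seed(seed)
  bs <- replicate(nBoot, {
    idx <- sample.int(length(a), replace = TRUE)
    suppressWarnings(stats::cor(a[idx], b[idx], method = "spearman"))
  })
  list(r = r, ci = unname(stats::quantile(bs, c(0.025, 0.975), na.rm = TRUE)),
       n = length(a), flagged = FALSE)
}
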