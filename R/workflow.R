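# End-to-end orchestration: stimulus/config file formats, the full
# preprocess -> hotspots -> (quantal | pool) pipeline, and report rendering.

#' Write / read a stimulus timing file
#'
#' JSON with explicit onset times; the derived pulse count and frequency
#' are validated against the onsets on read.
#'
#' @param stimTimes onset times (s), sorted.
#' @param path file path.
#' @param protocol label, e.g. "quantal_0.1Hz" or "pool_16Hz".
#' @return (read) list: \code{stimTimes}, \code{count}, \code{frequency},
#'   \code{protocol}.
#' @export
writeStimulusFile <- function(stimTimes, path, protocol = "") {
  stopifnot(!is.unsorted(stimTimes))
  freq <- if (length(stimTimes) > 1) 1 / stats::median(diff(stimTimes)) else NA
  payload <- list(onsets = stimTimes, count = length(stimTimes),
                  frequency = freq, protocol = protocol)
  writeLines(jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE), path)
  invisible(path)
}

#' @rdname writeStimulusFile
#' @export
readStimulusFile <- function(path) {
  x <- jsonlite::fromJSON(readLines(path))
  st <- as.numeric(x$onsets)
  if (is.unsorted(st)) stop("stimulus onsets not sorted")
  if (!is.null(x$count) && x$count != length(st))
    stop("stimulus count does not match onsets")
  if (length(st) > 1 && !is.null(x$frequency) && is.finite(x$frequency)) {
    f <- 1 / stats::median(diff(st))
    if (abs(f - x$frequency) > 0.05 * f)
      stop("stimulus frequency does not match onsets")
  }
  list(stimTimes = st, count = length(st),
       frequency = if (length(st) > 1) 1 / stats::median(diff(st)) else NA,
       protocol = x$protocol)
}

#' Write / read a run configuration as YAML
#'
#' Every analysis run echoes its full parameter set; storing it as YAML
#' beside the outputs makes a run reproducible from the directory alone.
#'
#' @param config named list of parameters.
#' @param path file path.
#' @return (read) the parameter list.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  yaml::read_yaml(path)
}

# deterministic hash of a configuration (provenance column in every output)
.configHash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(config, tf, version = 2, compress = FALSE)
  unname(tools::md5sum(tf))
}

#' Run the full analysis pipeline on one movie
#'
#' Chains preprocessing, maximal-map hotspot detection, spread fitting and
#' -- depending on the protocol -- quantal analysis (low-frequency trains)
#' or pool analysis (long high-frequency trains), and collects all tables
#' in a result bundle. Deterministic given the config seed; every table
#' carries the hash of the config that produced it.
#'
#' @param movie a \linkS4class{FluorescenceMovie} (stimulus times set).
#' @param protocol \code{"quantal"} (inter-stimulus interval must be >= 2 s)
#'   or \code{"pool"}.
#' @param psf PSF kernel; NULL skips deconvolution.
#' @param tauOff sensor decay constant for the pool protocol (s).
#' @param q quantal size for vesicle conversion (pool protocol); NULL
#'   leaves pool output in dF/F0 units.
#' @param stages preprocessing stages (see \code{\link{preprocessMovie}}).
#' @param ampThreshold hotspot detection threshold; NULL uses 5x the
#'   pre-stimulus pixel-noise SD.
#' @param maxRadius radial profile extent (um).
#' @param epsPx,minPts DBSCAN parameters.
#' @param seed seed for bootstrap CIs.
#' @return list (result bundle): \code{hotspots} (data.frame),
#'   \code{spreadFits}, \code{quantal} (per-hotspot table; quantal
#'   protocol), \code{pool} (pool table and curves; pool protocol),
#'   \code{configHash}, \code{protocol}, \code{params}.
#' @export
runPipeline <- function(movie, protocol = c("quantal", "pool"), psf = NULL,
                        tauOff = 8.96, q = NULL,
                        stages = c("deconvolve"), ampThreshold = NULL,
                        maxRadius = 2.5, epsPx = 3, minPts = 5, seed = 1L) {
  protocol <- match.arg(protocol)
  st <- stimTimes(movie)
  if (!length(st)) stop("movie has no stimulus times")
  isi <- if (length(st) > 1) stats::median(diff(st)) else Inf
  if (protocol == "pool" && isi > 1)
    stop("pool analysis requires a high-frequency train; this protocol ",
         "has an inter-stimulus interval of ", signif(isi, 3),
         " s (use protocol = 'quantal')")
  if (protocol == "quantal" && isi < 2)
    stop("quantal analysis requires low-frequency trials (>= 2 s apart)")
  params <- list(protocol = protocol, tauOff = tauOff, q = q,
                 stages = stages, maxRadius = maxRadius, epsPx = epsPx,
                 minPts = minPts, seed = seed)
  cfgHash <- .configHash(list(params = params, dim = dim(movieData(movie)),
                              stim = st))
  if ("deconvolve" %in% stages && is.null(psf))
    stages <- setdiff(stages, "deconvolve")
  pre <- preprocessMovie(movie, psf = psf, stages = stages)
  frameTimes <- (seq_len(nFrames(movie)) - 1) / frameRate(movie)
  # pixel-noise SD over the pre-stimulus window
  preWin <- pre$f0Window
  f0Block <- pre$dff[, , preWin[1]:preWin[2], drop = FALSE]
  noiseSd <- stats::sd(f0Block[is.finite(f0Block)])
  if (is.null(ampThreshold)) ampThreshold <- 5 * noiseSd
  analysisWin <- c(preWin[2] + 1L, nFrames(movie))
  mmap <- maxDffMap(pre$dff, analysisWin, pixelSize = pixelSize(movie))
  rois <- detectHotspots(mmap, epsPx = epsPx, minPts = minPts,
                         ampThreshold = ampThreshold)
  spreadFits <- list()
  hsRows <- list()
  ctrs <- if (length(rois))
    t(vapply(rois, function(r) r@center, numeric(2))) else NULL
  for (i in seq_along(rois)) {
    roi <- rois[[i]]
    nb <- if (length(rois) > 1) ctrs[-i, , drop = FALSE] else NULL
    prof <- radialProfile(mmap, roi, maxRadius = maxRadius,
                          pixelSize = pixelSize(movie), neighborCenters = nb)
    fit <- tryCatch(fitSpread(prof), error = function(e)
      new("SpreadFit", amplitude = NA_real_, lambda = NA_real_,
          offset = NA_real_, r2 = NA_real_,
          lambdaCI = c(NA_real_, NA_real_), converged = FALSE))
    spreadFits[[i]] <- fit
    hsRows[[i]] <- data.frame(
      id = roi@id, rowPx = roi@center[1], colPx = roi@center[2],
      rowUm = roi@centerUm[1], colUm = roi@centerUm[2],
      peakDff = roi@peakDff, lambdaUm = fit@lambda,
      lambdaCiLo = fit@lambdaCI[1], lambdaCiHi = fit@lambdaCI[2],
      r2 = fit@r2, isolated = roi@isolated, truncated = prof$truncated,
      configHash = cfgHash)
  }
  hsTab <- if (length(hsRows)) do.call(rbind, hsRows) else
    data.frame(id = integer(), rowPx = numeric(), colPx = numeric(),
               rowUm = numeric(), colUm = numeric(), peakDff = numeric(),
               lambdaUm = numeric(), lambdaCiLo = numeric(),
               lambdaCiHi = numeric(), r2 = numeric(), isolated = logical(),
               truncated = logical(), configHash = character())
  bundle <- list(hotspots = hsTab, spreadFits = spreadFits,
                 maxMap = mmap, f0 = pre$f0, preprocess = pre$diagnostics,
                 configHash = cfgHash, protocol = protocol, params = params)

  hotspotTrace <- function(roi) {
    px <- roi@pixels
    tr <- numeric(nFrames(movie))
    for (t in seq_len(nFrames(movie))) {
      fr <- pre$dff[, , t]
      tr[t] <- mean(fr[px], na.rm = TRUE)
    }
    tr
  }

  if (protocol == "quantal") {
    qRows <- list()
    for (i in seq_along(rois)) {
      tr <- hotspotTrace(rois[[i]])
      tab <- extractTrialAmplitudes(tr, frameTimes, st,
                                    peakWindow = c(0, min(3, isi / 2)),
                                    baseWindow = c(-min(2, isi / 3), -0.1))
      tab <- classifyFailures(tab)
      fit <- tryCatch(fitQuantalPeaks(tab$amplitude[!tab$failurePass1]),
                      error = function(e) NULL)
      if (is.null(fit)) next
      tab <- classifyFailures(tab, q = quantalSize(fit))
      sm <- summarizeQuantal(tab, fit)
      qRows[[i]] <- data.frame(
        hotspotId = rois[[i]]@id, q = quantalSize(fit), K = fit@K,
        releaseProb = sm$releaseProb, meanQuantaSuccess = sm$meanQuanta,
        quantalContentPerStim = sm$quantalContentPerStim,
        maxQuanta = sm$maxQuanta, nTrials = sm$nTrials,
        nFailures = sm$nFailures, configHash = cfgHash)
    }
    bundle$quantal <- if (length(qRows)) do.call(rbind, qRows) else NULL
  } else {
    tmpl <- offRateTemplates(frameTimes, st, tauOff)
    poolRows <- list()
    curves <- list()
    cellR <- numeric(length(st))
    for (i in seq_along(rois)) {
      tr <- hotspotTrace(rois[[i]])
      ser <- correctOffRate(tr, templates = tmpl, tauOff = tauOff)
      cellR <- cellR + ser$r
      cv <- cumulativeCurve(ser)
      est <- tryCatch(fitRRPRefill(cv, scope = "single_hotspot"),
                      error = function(e) NULL)
      if (is.null(est)) next
      if (!is.null(q)) est <- toVesicles(est, q)
      curves[[i]] <- cv
      poolRows[[i]] <- data.frame(
        scope = "single_hotspot", hotspotId = rois[[i]]@id,
        rrpDff = est@rrpDff, rrpVesicles = est@rrpVesicles,
        refillPer1000 = est@refillPer1000, r2 = est@r2,
        flags = paste(est@flags, collapse = ";"), configHash = cfgHash)
    }
    if (length(rois)) {
      cellCurve <- cumulativeCurve(list(r = cellR))
      cellEst <- tryCatch(fitRRPRefill(cellCurve, scope = "whole_cell"),
                          error = function(e) NULL)
      if (!is.null(cellEst)) {
        if (!is.null(q)) cellEst <- toVesicles(cellEst, q)
        poolRows[[length(poolRows) + 1L]] <- data.frame(
          scope = "whole_cell", hotspotId = NA_integer_,
          rrpDff = cellEst@rrpDff, rrpVesicles = cellEst@rrpVesicles,
          refillPer1000 = cellEst@refillPer1000, r2 = cellEst@r2,
          flags = paste(cellEst@flags, collapse = ";"),
          configHash = cfgHash)
        curves$wholeCell <- cellCurve
      }
    }
    bundle$pool <- if (length(poolRows)) do.call(rbind, poolRows) else NULL
    bundle$curves <- curves
  }
  bundle
}

#' Render figures and a summary from a result bundle
#'
#' Writes the hotspot/quantal/pool tables as CSV, a maximal dF/F0 heatmap
#' PNG, one 3-D surface render per hotspot, per-hotspot spread-fit plots,
#' and a markdown summary listing every parameter actually used. Missing
#' optional stages are marked "skipped" in the summary.
#'
#' @param bundle result bundle from \code{\link{runPipeline}}.
#' @param dir output directory.
#' @return (invisibly) the paths written.
#' @export
renderReport <- function(bundle, dir) {
  if (is.null(bundle$hotspots)) stop("empty bundle")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  w <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  w(bundle$hotspots, "hotspots.csv")
  if (!is.null(bundle$quantal)) w(bundle$quantal, "quantal.csv")
  if (!is.null(bundle$pool)) w(bundle$pool, "pool.csv")
  hp <- file.path(dir, "max_dff_heatmap.png")
  grDevices::png(hp, width = 600, height = 600)
  m <- bundle$maxMap; m[!is.finite(m)] <- 0
  graphics::image(t(m)[, nrow(m):1], col = grDevices::hcl.colors(64, "Inferno"),
                  axes = FALSE, main = "maximal dF/F0")
  grDevices::dev.off()
  paths <- c(paths, hp)
  for (i in seq_len(nrow(bundle$hotspots))) {
    ctr <- c(bundle$hotspots$rowPx[i], bundle$hotspots$colPx[i])
    r0 <- max(1, ctr[1] - 10); r1 <- min(nrow(m), ctr[1] + 10)
    c0 <- max(1, ctr[2] - 10); c1 <- min(ncol(m), ctr[2] + 10)
    sp <- file.path(dir, sprintf("hotspot_%02d_surface.png",
                                 bundle$hotspots$id[i]))
    grDevices::png(sp, width = 500, height = 500)
    graphics::persp(m[r0:r1, c0:c1], theta = 30, phi = 30,
                    col = "lightblue", xlab = "x", ylab = "y",
                    zlab = "max dF/F0")
    grDevices::dev.off()
    paths <- c(paths, sp)
  }
  md <- file.path(dir, "summary.md")
  lines <- c("# Analysis summary", "",
             sprintf("- protocol: %s", bundle$protocol),
             sprintf("- config hash: %s", bundle$configHash),
             sprintf("- hotspots detected: %d", nrow(bundle$hotspots)),
             "", "## Parameters", "",
             vapply(names(bundle$params), function(nm)
               sprintf("- %s: %s", nm,
                       paste(format(bundle$params[[nm]]), collapse = ", ")),
               character(1)),
             "", "## Stages",
             sprintf("- quantal table: %s",
                     if (is.null(bundle$quantal)) "skipped" else "written"),
             sprintf("- pool table: %s",
                     if (is.null(bundle$pool)) "skipped" else "written"))
  writeLines(lines, md)
  paths <- c(paths, md)
  invisible(paths)
}
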