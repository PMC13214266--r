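# Optical quantal analysis of low-frequency (0.1 Hz) trial trains at single
# release sites: per-trial amplitudes, failure classification, the
# equal-spacing Gaussian mixture fit for quantal size, and summary release
# statistics.

#' Extract per-stimulus peak amplitudes at a hotspot
#'
#' For each stimulus, the amplitude is the maximum of the dF/F0 trace in
#' the post-stimulus peak window minus the mean over the local pre-stimulus
#' baseline window. Trials must be independent: the windows may not overlap
#' the neighboring stimuli (satisfied at 0.1 Hz for sensor off-rates up to
#' ~9 s). The noise SD is estimated from the pooled, per-trial-demeaned
#' pre-stimulus segments.
#'
#' @param trace numeric dF/F0 trace at the hotspot.
#' @param times frame times (s) of the trace.
#' @param stimTimes stimulus onset times (s).
#' @param peakWindow numeric(2), window after each stimulus (s) searched for
#'   the peak.
#' @param baseWindow numeric(2), window relative to each stimulus (s, both
#'   usually negative) averaged as local baseline.
#' @return data.frame (trial amplitude table): \code{stim, time, amplitude,
#'   failure} (NA until classified), with attribute \code{noiseSd}.
#' @export
extractTrialAmplitudes <- function(trace, times, stimTimes,
                                   peakWindow = c(0, 3),
                                   baseWindow = c(-2, -0.1)) {
  stopifnot(length(trace) == length(times), length(stimTimes) >= 1)
  isi <- if (length(stimTimes) > 1) min(diff(stimTimes)) else Inf
  if (peakWindow[2] > isi || -baseWindow[1] > isi)
    stop("peak/base windows overlap the adjacent stimulus")
  n <- length(stimTimes)
  amp <- numeric(n)
  baseResid <- list()
  for (i in seq_len(n)) {
    s <- stimTimes[i]
    pk <- trace[times >= s + peakWindow[1] & times <= s + peakWindow[2]]
    bs <- trace[times >= s + baseWindow[1] & times <= s + baseWindow[2]]
    if (!length(pk) || !length(bs)) stop("windows contain no frames")
    amp[i] <- max(pk) - mean(bs)
    baseResid[[i]] <- bs - mean(bs)
  }
  noiseSd <- stats::sd(unlist(baseResid))
  out <- data.frame(stim = seq_len(n), time = stimTimes, amplitude = amp,
                    failure = NA)
  attr(out, "noiseSd") <- noiseSd
  out
}

#' Classify release failures in a trial amplitude table
#'
#' Two-pass rule. Pass 1 (noise-based): a trial is a failure when its
#' amplitude is below \code{2 * noiseSd}. Pass 2 (quantal, applied when a
#' quantal size estimate is available): failure when the amplitude is below
#' \code{q / 2}. Both flags are recorded; the \code{failure} column carries
#' the final classification (pass 2 when q is given, otherwise pass 1).
#'
#' @param table trial amplitude table from
#'   \code{\link{extractTrialAmplitudes}} (or any data.frame with an
#'   \code{amplitude} column).
#' @param noiseSd noise SD; defaults to the table's \code{noiseSd}
#'   attribute.
#' @param q optional quantal size estimate.
#' @return The table with columns \code{failurePass1}, \code{failurePass2}
#'   (NA when q not given) and \code{failure}.
#' @export
classifyFailures <- function(table, noiseSd = NULL, q = NULL) {
  if (is.null(noiseSd)) noiseSd <- attr(table, "noiseSd")
  if (is.null(noiseSd)) stop("no noise SD available")
  table$failurePass1 <- table$amplitude < 2 * noiseSd
  if (!is.null(q)) {
    stopifnot(q > 0)
    table$failurePass2 <- table$amplitude < q / 2
    table$failure <- table$failurePass2
  } else {
    table$failurePass2 <- NA
    table$failure <- table$failurePass1
  }
  table
}

# log-likelihood of the equal-spacing mixture at one parameter set
.qmixLogLik <- function(a, q, K, weights, sigma0, sigma1) {
  dens <- 0
  for (k in 0:K) {
    sdk <- sqrt(sigma0^2 + k * sigma1^2)
    dens <- dens + weights[k + 1] * stats::dnorm(a, k * q, sdk)
  }
  sum(log(pmax(dens, 1e-300)))
}

.qmixEM <- function(a, q0, K, sigma1Free, maxIter = 200L, tol = 1e-10) {
  n <- length(a)
  q <- q0
  sigFloor <- max(1e-6 * q0, 1e-9)
  sigma0 <- max(stats::sd(a - round(a / q) * q), sigFloor)
  sigma1 <- 0
  weights <- rep(1 / (K + 1), K + 1)
  ll <- -Inf
  for (it in seq_len(maxIter)) {
    comp <- vapply(0:K, function(k) {
      sdk <- sqrt(sigma0^2 + k * sigma1^2)
      weights[k + 1] * stats::dnorm(a, k * q, sdk)
    }, numeric(n))
    comp <- matrix(comp, n, K + 1)
    tot <- rowSums(comp)
    tot[tot < 1e-300] <- 1e-300
    g <- comp / tot
    weights <- colMeans(g)
    ks <- 0:K
    sig2 <- sigma0^2 + ks * sigma1^2
    num <- sum(g %*% diag(ks / sig2, K + 1, K + 1) * a)
    den <- sum(t(g) * (ks^2 / sig2))
    if (den > 0) q <- num / den
    if (sigma1Free) {
      obj <- function(p) {
        s0 <- exp(p[1]); s1 <- exp(p[2])
        -sum(g * vapply(ks, function(k)
          stats::dnorm(a, k * q, sqrt(s0^2 + k * s1^2), log = TRUE),
          numeric(n)))
      }
      op <- stats::optim(c(log(max(sigma0, sigFloor)),
                           log(max(sigma1, sigFloor))), obj,
                         method = "Nelder-Mead",
                         control = list(maxit = 60))
      sigma0 <- max(exp(op$par[1]), sigFloor)
      sigma1 <- exp(op$par[2])
      if (sigma1 < sigFloor) sigma1 <- 0
    } else {
      resid2 <- vapply(ks, function(k) (a - k * q)^2, numeric(n))
      sigma0 <- max(sqrt(sum(g * resid2) / n), sigFloor)
    }
    llNew <- .qmixLogLik(a, q, K, weights, sigma0, sigma1)
    if (is.finite(ll) && abs(llNew - ll) < tol * (abs(ll) + 1)) { ll <- llNew; break }
    ll <- llNew
  }
  list(q = q, K = K, weights = weights, sigma0 = sigma0, sigma1 = sigma1,
       logLik = ll)
}

#' Fit the equal-spacing quantal mixture to trial amplitudes
#'
#' Maximum-likelihood Gaussian mixture whose component means are constrained
#' to \code{0, q, 2q, ..., Kq}: failures populate the zero component and
#' k-vesicle releases the k-th. The quantal size q is first searched on a
#' grid (resolution 1% of the amplitude range) and then refined by EM under
#' the spacing constraint; the number of components K is selected by BIC
#' over 1..\code{maxK}, with ties resolved toward the smallest K. Component
#' variances follow \code{sigma_k^2 = sigma0^2 + k sigma1^2}; set
#' \code{sigma1Free = FALSE} to pin the per-quantum term to zero. Fitting is
#' done on the raw amplitudes, never on a binned histogram.
#'
#' @param amplitudes numeric trial amplitudes (failures may be included;
#'   they are absorbed by the zero component).
#' @param maxK largest number of quantal components considered.
#' @param sigma1Free estimate the per-quantum variance term.
#' @return A \linkS4class{QuantalFit}.
#' @export
fitQuantalPeaks <- function(amplitudes, maxK = 5L, sigma1Free = FALSE) {
  a <- amplitudes[is.finite(amplitudes)]
  if (length(a) < 2L) stop("need at least 2 amplitudes")
  if (max(a) <= 0) stop("all failures")
  rng <- max(a) - min(a)
  if (rng == 0) {
    # all amplitudes identical: one component at q = c
    return(new("QuantalFit", q = a[1], K = 1L, weights = c(0, 1),
               sigma0 = max(1e-6 * abs(a[1]), 1e-9), sigma1 = 0,
               logLik = Inf, bic = -Inf, n = length(a)))
  }
  best <- NULL
  for (K in seq_len(maxK)) {
    # q must place the largest amplitudes near component K
    qc <- max(a) / K
    grid <- seq(qc * 0.7, qc * 1.3, by = 0.01 * rng)
    grid <- grid[grid > 0]
    if (!length(grid)) grid <- qc
    scoreQ <- vapply(grid, function(qg) {
      k <- pmin(pmax(round(a / qg), 0), K)
      -sum((a - k * qg)^2)
    }, numeric(1))
    q0 <- grid[which.max(scoreQ)]
    em <- .qmixEM(a, q0, K, sigma1Free)
    nPar <- K + 2 + as.integer(sigma1Free)  # K free weights + q + sigma0 (+ sigma1)
    bic <- -2 * em$logLik + nPar * log(length(a))
    if (is.null(best) || bic < best$bic - 1e-9) {
      best <- c(em, list(bic = bic))
    }
  }
  new("QuantalFit", q = best$q, K = as.integer(best$K),
      weights = best$weights, sigma0 = best$sigma0, sigma1 = best$sigma1,
      logLik = best$logLik, bic = best$bic, n = length(a))
}

#' Summarize release statistics from classified trials and a quantal fit
#'
#' Release probability is \code{1 - failures / trials}. Each successful
#' trial is assigned \code{round(amplitude / q)} quanta (at least 1);
#' quantal content is reported under both conventions: mean quanta per
#' successful response and per stimulus (\code{Pr * meanQuanta}).
#'
#' @param table classified trial table (\code{\link{classifyFailures}}).
#' @param fit a \linkS4class{QuantalFit} (or a plain quantal size via
#'   \code{q}).
#' @param q quantal size override.
#' @return list (quantal summary): \code{releaseProb}, \code{meanQuanta}
#'   (per success), \code{maxQuanta}, \code{quantalContentPerStim},
#'   \code{nTrials}, \code{nFailures}, \code{quanta} (per-trial counts,
#'   0 for failures), and \code{convention} metadata.
#' @export
summarizeQuantal <- function(table, fit = NULL, q = NULL) {
  if (is.null(q)) {
    stopifnot(!is.null(fit))
    q <- quantalSize(fit)
  }
  stopifnot(q > 0, !any(is.na(table$failure)))
  n <- nrow(table)
  fails <- sum(table$failure)
  pr <- 1 - fails / n
  quanta <- integer(n)
  succ <- !table$failure
  quanta[succ] <- pmax(1L, as.integer(round(table$amplitude[succ] / q)))
  meanQ <- if (any(succ)) mean(quanta[succ]) else NA_real_
  maxQ <- if (any(succ)) max(quanta[succ]) else 0L
  list(releaseProb = pr, meanQuanta = meanQ, maxQuanta = maxQ,
       quantalContentPerStim = pr * ifelse(is.na(meanQ), 0, meanQ),
       nTrials = n, nFailures = fails, quanta = quanta,
       convention = "meanQuanta is per successful response; quantalContentPerStim is per stimulus")
}
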