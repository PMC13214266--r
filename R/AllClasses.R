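#' @import methods
NULL

#' FluorescenceMovie: a time-lapse fluorescence image stack
#'
#' The pipeline's central raw-data container: a 3-D array of pixel counts
#' (rows x cols x frames) with the physical metadata needed by every stage
#' (pixel size in micrometers, frame rate in Hz) and the stimulus onset times.
#'
#' @slot frames numeric array, rows x cols x frames, pixel counts.
#' @slot pixelSize numeric(1), micrometers per pixel.
#' @slot frameRate numeric(1), frames per second.
#' @slot stimTimes numeric, stimulus onset times in seconds from movie start.
#'
#' @exportClass FluorescenceMovie
setClass("FluorescenceMovie",
  representation(
    frames = "array",
    pixelSize = "numeric",
    frameRate = "numeric",
    stimTimes = "numeric"
  )
)

setValidity("FluorescenceMovie", function(object) {
  msg <- character()
  if (length(dim(object@frames)) != 3L)
    msg <- c(msg, "'frames' must be a 3-D array (rows x cols x frames)")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    msg <- c(msg, "'pixelSize' must be a single positive number")
  if (length(object@frameRate) != 1L || object@frameRate <= 0)
    msg <- c(msg, "'frameRate' must be a single positive number")
  if (length(object@stimTimes)) {
    dur <- dim(object@frames)[3] / object@frameRate
    if (any(object@stimTimes < 0) || any(object@stimTimes > dur))
      msg <- c(msg, "all 'stimTimes' must lie within the movie duration")
    if (is.unsorted(object@stimTimes, strictly = FALSE))
      msg <- c(msg, "'stimTimes' must be sorted")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a FluorescenceMovie
#'
#' @param frames 3-D numeric array (rows x cols x frames) of pixel counts.
#' @param pixelSize micrometers per pixel.
#' @param frameRate frames per second (Hz).
#' @param stimTimes stimulus onset times (s), sorted, within the movie.
#' @return A \linkS4class{FluorescenceMovie}.
#' @examples
#' mov <- FluorescenceMovie(array(100, c(4, 4, 10)), 0.1625, 10)
#' nFrames(mov)
#' @export
FluorescenceMovie <- function(frames, pixelSize, frameRate,
                              stimTimes = numeric()) {
  new("FluorescenceMovie", frames = frames, pixelSize = pixelSize,
      frameRate = frameRate, stimTimes = as.numeric(stimTimes))
}

#' GroundTruth: generative parameters behind a synthetic movie
#'
#' Sidecar object written next to every synthetic movie: the full simulation
#' configuration, the per-hotspot true parameters (center, spread constant,
#' quantal size, release probability, pool size, refill rate) and the complete
#' per-stimulus release event table. Used as the oracle in recovery tests.
#'
#' @slot config list, the echoed simulation configuration.
#' @slot hotspots data.frame of per-hotspot true parameters.
#' @slot events data.frame, the release event table (one row per hotspot per
#'   stimulus).
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(config = "list", hotspots = "data.frame",
                 events = "data.frame"))

#' HotspotROI: one detected release site
#'
#' @slot id integer hotspot identifier.
#' @slot pixels integer matrix (n x 2) of cluster pixel coordinates (row, col).
#' @slot center numeric(2), center pixel (row, col) = cluster argmax.
#' @slot centerUm numeric(2), center in micrometers from the image origin.
#' @slot peakDff numeric(1), maximal dF/F0 at the center pixel.
#' @slot isolated logical(1), TRUE when no neighboring center lies within the
#'   isolation radius.
#' @exportClass HotspotROI
setClass("HotspotROI",
  representation(id = "integer", pixels = "matrix", center = "numeric",
                 centerUm = "numeric", peakDff = "numeric",
                 isolated = "logical"))

setValidity("HotspotROI", function(object) {
  msg <- character()
  if (ncol(object@pixels) != 2L)
    msg <- c(msg, "'pixels' must have two columns (row, col)")
  if (length(object@center) != 2L)
    msg <- c(msg, "'center' must be length 2")
  if (length(msg)) msg else TRUE
})

#' SpreadFit: single-exponential radial spread fit
#'
#' Result of fitting A * exp(-r / lambda) (plus an optional offset) to a
#' hotspot's radial dF/F0 profile; lambda is the spatial spread length
#' constant in micrometers.
#'
#' @slot amplitude numeric(1), fitted peak amplitude A (dF/F0).
#' @slot lambda numeric(1), spread length constant (um).
#' @slot offset numeric(1), fitted offset (0 unless freed).
#' @slot r2 numeric(1), coefficient of determination.
#' @slot lambdaCI numeric(2), 95% confidence interval on lambda.
#' @slot converged logical(1).
#' @exportClass SpreadFit
setClass("SpreadFit",
  representation(amplitude = "numeric", lambda = "numeric",
                 offset = "numeric", r2 = "numeric", lambdaCI = "numeric",
                 converged = "logical"))

setValidity("SpreadFit", function(object) {
  if (isTRUE(object@converged) && object@lambda <= 0)
    "fitted 'lambda' must be positive on success" else TRUE
})

#' QuantalFit: equal-spacing Gaussian mixture fit to trial amplitudes
#'
#' Maximum-likelihood fit of a mixture whose component means are constrained
#' to integer multiples of a common quantal size q (components at 0, q, 2q,
#' ..., Kq), the optical analogue of a classical quantal amplitude histogram.
#'
#' @slot q numeric(1), quantal size (dF/F0 per vesicle).
#' @slot K integer(1), number of non-zero quantal components.
#' @slot weights numeric, mixture weights for components k = 0..K.
#' @slot sigma0 numeric(1), failure (baseline) noise SD.
#' @slot sigma1 numeric(1), per-quantum SD term; component variance is
#'   sigma0^2 + k * sigma1^2.
#' @slot logLik numeric(1).
#' @slot bic numeric(1).
#' @slot n integer(1), number of amplitudes fitted.
#' @exportClass QuantalFit
setClass("QuantalFit",
  representation(q = "numeric", K = "integer", weights = "numeric",
                 sigma0 = "numeric", sigma1 = "numeric", logLik = "numeric",
                 bic = "numeric", n = "integer"))

setValidity("QuantalFit", function(object) {
  msg <- character()
  if (object@q <= 0) msg <- c(msg, "'q' must be positive")
  if (length(object@weights) != object@K + 1L)
    msg <- c(msg, "'weights' must have K + 1 entries (components 0..K)")
  if (length(msg)) msg else TRUE
})

#' PoolEstimate: readily releasable pool size and refilling rate
#'
#' Back-extrapolation result from the late-phase linear fit to a cumulative
#' release curve: the y intercept estimates the readily releasable pool (RRP)
#' and the slope the vesicular refilling rate. Quantities are carried both in
#' dF/F0 units and, after division by the quantal size, in vesicles.
#'
#' @slot rrpDff numeric(1), RRP in dF/F0 units (intercept).
#' @slot refillPerStimDff numeric(1), refill per stimulus in dF/F0 (slope).
#' @slot rrpVesicles numeric(1), RRP in vesicles (NA until converted).
#' @slot refillPer1000 numeric(1), vesicles per 1,000 pulses (NA until
#'   converted).
#' @slot q numeric(1), quantal size used for conversion (NA until converted).
#' @slot scope character(1), "whole_cell" or "single_hotspot".
#' @slot ci numeric(4), 95% CIs: rrp lo/hi, refill-per-stimulus lo/hi
#'   (dF/F0 units).
#' @slot r2 numeric(1), late-phase linearity.
#' @slot flags character, e.g. "rrp_not_resolvable", "late_phase_nonlinear".
#' @slot diagnostics list, window-sensitivity fits (final quarter / half).
#' @exportClass PoolEstimate
setClass("PoolEstimate",
  representation(rrpDff = "numeric", refillPerStimDff = "numeric",
                 rrpVesicles = "numeric", refillPer1000 = "numeric",
                 q = "numeric", scope = "character", ci = "numeric",
                 r2 = "numeric", flags = "character", diagnostics = "list"))
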