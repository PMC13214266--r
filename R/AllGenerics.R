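#' @include AllClasses.R
NULL

#' Accessors for FluorescenceMovie and result objects
#'
#' @param object a fluoQuanta S4 object.
#' @return The requested slot value.
#' @name accessors
#' @aliases movieData pixelSize frameRate nFrames stimTimes spreadConstant
#'   quantalSize rrpVesicles refillPer1000
NULL

#' @rdname accessors
#' @export
setGeneric("movieData", function(object) standardGeneric("movieData"))

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("frameRate", function(object) standardGeneric("frameRate"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("stimTimes", function(object) standardGeneric("stimTimes"))

#' @rdname accessors
#' @export
setGeneric("spreadConstant", function(object) standardGeneric("spreadConstant"))

#' @rdname accessors
#' @export
setGeneric("quantalSize", function(object) standardGeneric("quantalSize"))

#' @rdname accessors
#' @export
setGeneric("rrpVesicles", function(object) standardGeneric("rrpVesicles"))

#' @rdname accessors
#' @export
setGeneric("refillPer1000", function(object) standardGeneric("refillPer1000"))

#' @rdname accessors
#' @export
setMethod("movieData", "FluorescenceMovie", function(object) object@frames)

#' @rdname accessors
#' @export
setMethod("pixelSize", "FluorescenceMovie", function(object) object@pixelSize)

#' @rdname accessors
#' @export
setMethod("frameRate", "FluorescenceMovie", function(object) object@frameRate)

#' @rdname accessors
#' @export
setMethod("nFrames", "FluorescenceMovie",
          function(object) dim(object@frames)[3])

#' @rdname accessors
#' @export
setMethod("stimTimes", "FluorescenceMovie", function(object) object@stimTimes)

#' @rdname accessors
#' @export
setMethod("spreadConstant", "SpreadFit", function(object) object@lambda)

#' @rdname accessors
#' @export
setMethod("quantalSize", "QuantalFit", function(object) object@q)

#' @rdname accessors
#' @export
setMethod("rrpVesicles", "PoolEstimate", function(object) object@rrpVesicles)

#' @rdname accessors
#' @export
setMethod("refillPer1000", "PoolEstimate",
          function(object) object@refillPer1000)

setMethod("show", "FluorescenceMovie", function(object) {
  d <- dim(object@frames)
  cat(sprintf(
    "FluorescenceMovie: %d x %d px, %d frames @ %.3g Hz (%.4g um/px)\n",
    d[1], d[2], d[3], object@frameRate, object@pixelSize))
  if (length(object@stimTimes))
    cat(sprintf("  %d stimuli, first at %.3g s, last at %.3g s\n",
                length(object@stimTimes), min(object@stimTimes),
                max(object@stimTimes)))
})

setMethod("show", "SpreadFit", function(object) {
  cat(sprintf(
    "SpreadFit: lambda = %.4g um (95%% CI %.4g-%.4g), A = %.4g, R2 = %.3f\n",
    object@lambda, object@lambdaCI[1], object@lambdaCI[2],
    object@amplitude, object@r2))
})

setMethod("show", "QuantalFit", function(object) {
  cat(sprintf(
    "QuantalFit: q = %.4g dF/F0, K = %d, sigma0 = %.3g (n = %d, BIC = %.1f)\n",
    object@q, object@K, object@sigma0, object@n, object@bic))
})

setMethod("show", "PoolEstimate", function(object) {
  cat(sprintf("PoolEstimate (%s): RRP = %.4g dF/F0", object@scope,
              object@rrpDff))
  if (!is.na(object@rrpVesicles))
    cat(sprintf(" = %.4g vesicles", object@rrpVesicles))
  cat(sprintf("; refill = %.4g dF/F0 per stimulus", object@refillPerStimDff))
  if (!is.na(object@refillPer1000))
    cat(sprintf(" = %.4g vesicles / 1,000 pulses", object@refillPer1000))
  cat(sprintf(" (late-phase R2 = %.3f)\n", object@r2))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "HotspotROI", function(object) {
  cat(sprintf(
    "HotspotROI #%d: center (%.1f, %.1f) px / (%.3g, %.3g) um, peak dF/F0 %.3g, %d px%s\n",
    object@id, object@center[1], object@center[2], object@centerUm[1],
    object@centerUm[2], object@peakDff, nrow(object@pixels),
    if (object@isolated) ", isolated" else ""))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d hotspot(s), %d release-event rows\n",
              nrow(object@hotspots), nrow(object@events)))
})
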