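#' @include AllClasses.R
NULL

#' Accessors for recordings and tracks
#'
#' `voltage()` returns the trace in mV, `sampleRate()` the rate in Hz,
#' `durationS()` the duration in seconds (samples / rate for recordings,
#' frames / fps for tracks), `subjectId()` and `genotype()` the labels.
#'
#' @param x an [LfpRecording-class] or [SwimTrack-class].
#' @return The corresponding slot value (a vector or scalar).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voltage", function(x) standardGeneric("voltage"))
#' @rdname accessors
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))
#' @rdname accessors
#' @export
setGeneric("durationS", function(x) standardGeneric("durationS"))
#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setGeneric("genotype", function(x) standardGeneric("genotype"))
#' @rdname accessors
#' @export
setGeneric("fps", function(x) standardGeneric("fps"))
#' @rdname accessors
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' @rdname accessors
setMethod("voltage", "LfpRecording", function(x) x@voltageMv)
#' @rdname accessors
setMethod("sampleRate", "LfpRecording", function(x) x@sampleRateHz)
#' @rdname accessors
setMethod("durationS", "LfpRecording",
          function(x) length(x@voltageMv) / x@sampleRateHz)
#' @rdname accessors
setMethod("subjectId", "LfpRecording", function(x) x@subjectId)
#' @rdname accessors
setMethod("genotype", "LfpRecording", function(x) x@genotype)

#' @rdname accessors
setMethod("fps", "SwimTrack", function(x) x@fps)
#' @rdname accessors
setMethod("durationS", "SwimTrack", function(x) length(x@xMm) / x@fps)
#' @rdname accessors
setMethod("subjectId", "SwimTrack", function(x) x@subjectId)
#' @rdname accessors
setMethod("genotype", "SwimTrack", function(x) x@genotype)
#' @rdname accessors
setMethod("positions", "SwimTrack",
          function(x) data.frame(x_mm = x@xMm, y_mm = x@yMm))

setMethod("show", "LfpRecording", function(object) {
  cat(sprintf("LfpRecording '%s' (%s, %s, %s)\n", object@subjectId,
              object@line, object@genotype, object@condition))
  cat(sprintf("  %d samples @ %g Hz = %.1f s; voltage range [%.3f, %.3f] mV\n",
              length(object@voltageMv), object@sampleRateHz,
              durationS(object), min(object@voltageMv), max(object@voltageMv)))
})

setMethod("show", "SwimTrack", function(object) {
  nGap <- sum(is.na(object@xMm))
  cat(sprintf("SwimTrack '%s' (%s, %s, %s)\n", object@subjectId, object@line,
              object@genotype, object@condition))
  cat(sprintf("  %d frames @ %g fps = %.1f s; arena radius %.1f mm; %d untracked frames\n",
              length(object@xMm), object@fps, durationS(object),
              object@arenaRadiusMm, nGap))
})

setMethod("show", "RasterSeries", function(object) {
  cat(sprintf("RasterSeries: %d bins of %g s starting at %g s; score range [%.3f, %.3f]\n",
              length(object@score), object@binS, object@t0S,
              if (length(object@score)) min(object@score) else NA,
              if (length(object@score)) max(object@score) else NA))
})

setMethod("show", "DetectorConfig", function(object) {
  cat("DetectorConfig:\n")
  cat(sprintf("  threshold: %s\n", if (object@useRelativeThreshold)
    sprintf("%.1f x baseline SD (relative)", object@relativeThresholdSd)
    else sprintf("%.3f mV (absolute)", object@voltageThresholdMv)))
  cat(sprintf("  bin %g s, window %g s, raster threshold %.2f, merge gap %d bins\n",
              object@binS, object@windowS, object@rasterThreshold,
              object@minEventGapBins))
})
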