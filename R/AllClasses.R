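#' @import methods
NULL

GENOTYPES <- c("WT", "HET", "MUT", "unknown")

#' LfpRecording: a uniformly sampled local field potential trace
#'
#' Container for one gap-free LFP epoch: a voltage trace in millivolts at a
#' fixed sampling rate, together with acquisition and genotype metadata.
#' Recordings in the original screening design are 15 min epochs digitized at
#' 10 kHz after 1 kHz low-pass filtering; any positive rate/duration is
#' accepted as long as the rate exceeds twice the analysis band.
#'
#' @slot subjectId single character identifier.
#' @slot sampleRateHz sampling rate in Hz (default 10000).
#' @slot voltageMv numeric vector of voltages in mV; all finite, length >= 1.
#' @slot genotype one of `"WT"`, `"HET"`, `"MUT"`, `"unknown"`.
#' @slot line gene / line label.
#' @slot condition free-text condition label (e.g. `"baseline"` or a drug).
#'
#' @seealso [lfpRecording()], [readLfp()], [genLfp()]
#' @export
setClass("LfpRecording",
  representation(
    subjectId = "character",
    sampleRateHz = "numeric",
    voltageMv = "numeric",
    genotype = "character",
    line = "character",
    condition = "character"
  )
)

setValidity("LfpRecording", function(object) {
  msg <- character()
  if (length(object@subjectId) != 1L) msg <- c(msg, "subjectId must be a single string")
  if (length(object@sampleRateHz) != 1L || !is.finite(object@sampleRateHz) ||
      object@sampleRateHz <= 0)
    msg <- c(msg, "sampleRateHz must be a single positive number")
  if (length(object@voltageMv) < 1L)
    msg <- c(msg, "voltageMv must contain at least one sample")
  if (anyNA(object@voltageMv) || any(!is.finite(object@voltageMv)))
    msg <- c(msg, "voltageMv must be finite")
  if (!object@genotype %in% GENOTYPES)
    msg <- c(msg, sprintf("genotype must be one of %s", paste(GENOTYPES, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct an LfpRecording
#'
#' @param voltageMv numeric voltage trace in mV.
#' @param sampleRateHz sampling rate in Hz.
#' @param subjectId,genotype,line,condition metadata labels.
#' @return An [LfpRecording-class] object.
#' @examples
#' rec <- lfpRecording(rnorm(1000, sd = 0.05), sampleRateHz = 1000)
#' durationS(rec)
#' @export
lfpRecording <- function(voltageMv, sampleRateHz = 10000, subjectId = "subject",
                         genotype = "unknown", line = "unknown",
                         condition = "baseline") {
  new("LfpRecording", subjectId = subjectId, sampleRateHz = sampleRateHz,
      voltageMv = as.numeric(voltageMv), genotype = genotype, line = line,
      condition = condition)
}

#' SwimTrack: a larval swim trajectory
#'
#' Positions of one tracked larva in arena coordinates (mm) at a fixed frame
#' rate. Frames where the subject was not detected carry `NA` positions; gaps
#' of at most 5 frames are interpolated by the reader, longer gaps are kept as
#' `NA` and excluded from speed computation.
#'
#' @slot subjectId single character identifier.
#' @slot fps frame rate (frames/s), default 25.
#' @slot xMm,yMm numeric positions in mm, equal length; `NA` marks a gap.
#' @slot arenaRadiusMm arena radius in mm.
#' @slot genotype,line,condition metadata as in [LfpRecording-class].
#' @slot gaps data.frame log of untracked stretches (`start_frame`,
#'   `end_frame`, `interpolated`).
#' @export
setClass("SwimTrack",
  representation(
    subjectId = "character",
    fps = "numeric",
    xMm = "numeric",
    yMm = "numeric",
    arenaRadiusMm = "numeric",
    genotype = "character",
    line = "character",
    condition = "character",
    gaps = "data.frame"
  )
)

setValidity("SwimTrack", function(object) {
  msg <- character()
  if (length(object@xMm) != length(object@yMm))
    msg <- c(msg, "xMm and yMm must have the same length")
  if (length(object@fps) != 1L || object@fps <= 0)
    msg <- c(msg, "fps must be a single positive number")
  if (length(object@arenaRadiusMm) != 1L || object@arenaRadiusMm <= 0)
    msg <- c(msg, "arenaRadiusMm must be positive")
  ok <- !is.na(object@xMm) & !is.na(object@yMm)
  if (any(ok)) {
    r <- sqrt(object@xMm[ok]^2 + object@yMm[ok]^2)
    if (any(r > object@arenaRadiusMm * 1.05 + 0.1))
      msg <- c(msg, "positions fall outside the arena bounds (plus tolerance)")
  }
  if (!object@genotype %in% GENOTYPES)
    msg <- c(msg, sprintf("genotype must be one of %s", paste(GENOTYPES, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a SwimTrack
#'
#' @param xMm,yMm positions in mm (`NA` = subject undetected).
#' @param fps frame rate in frames/s.
#' @param arenaRadiusMm arena radius in mm.
#' @param subjectId,genotype,line,condition metadata labels.
#' @param gaps optional data.frame logging untracked stretches.
#' @return A [SwimTrack-class] object.
#' @export
swimTrack <- function(xMm, yMm, fps = 25, arenaRadiusMm = 3.5,
                      subjectId = "subject", genotype = "unknown",
                      line = "unknown", condition = "baseline",
                      gaps = data.frame(start_frame = integer(),
                                        end_frame = integer(),
                                        interpolated = logical())) {
  new("SwimTrack", subjectId = subjectId, fps = fps, xMm = as.numeric(xMm),
      yMm = as.numeric(yMm), arenaRadiusMm = arenaRadiusMm,
      genotype = genotype, line = line, condition = condition, gaps = gaps)
}

#' RasterSeries: per-bin raster scores
#'
#' One raster score per analysis bin: the fraction of super-threshold samples
#' within the sliding window starting at that bin (truncated at the trace end).
#' All scores lie in \[0, 1\].
#'
#' @slot score numeric vector of scores in \[0,1\], one per bin.
#' @slot binS bin width in seconds.
#' @slot t0S time of the first bin edge in seconds.
#' @export
setClass("RasterSeries",
  representation(score = "numeric", binS = "numeric", t0S = "numeric")
)

setValidity("RasterSeries", function(object) {
  if (length(object@score) &&
      (min(object@score) < -1e-12 || max(object@score) > 1 + 1e-12))
    return("raster scores must lie in [0, 1]")
  if (object@binS <= 0) return("binS must be positive")
  TRUE
})

## ---- configuration classes ------------------------------------------------

#' DetectorConfig: LFP event-detection parameters
#'
#' Parameters of the binarize / raster-score / segment detector.
#' The voltage threshold legal range is 0.05-1.0 mV; the study tuned it within
#' 0.15-0.25 mV depending on noise level, or used a relative threshold of
#' 3x the baseline noise SD. Raster scores are binned at `binS` (10 ms) and
#' windowed over `windowS`; the raster threshold legal range is 0.05-0.8
#' (study range 0.2-0.4).
#'
#' @slot voltageThresholdMv absolute binarization threshold in mV.
#' @slot useRelativeThreshold if `TRUE` (default) the threshold is
#'   `relativeThresholdSd` times the robust baseline noise SD.
#' @slot relativeThresholdSd multiplier for the relative threshold (default 3).
#' @slot binS raster bin width in s (default 0.01).
#' @slot windowS sliding-window length in s; must be an integer multiple of
#'   `binS` (default 0.02, see the methods vignette for why the window is kept
#'   close to the bin width).
#' @slot rasterThreshold raster score defining event start/end (default 0.3).
#' @slot minEventGapBins sub-threshold gap (in bins) across which adjacent
#'   runs are merged (default 25, i.e. 250 ms, so that multi-spike bursts stay
#'   single events).
#' @export
setClass("DetectorConfig",
  representation(
    voltageThresholdMv = "numeric",
    useRelativeThreshold = "logical",
    relativeThresholdSd = "numeric",
    binS = "numeric",
    windowS = "numeric",
    rasterThreshold = "numeric",
    minEventGapBins = "integer"
  )
)

setValidity("DetectorConfig", function(object) {
  msg <- character()
  rng <- function(what, x, lo, hi)
    sprintf("%s = %g outside legal range [%g, %g]", what, x, lo, hi)
  if (object@voltageThresholdMv < 0.05 || object@voltageThresholdMv > 1.0)
    msg <- c(msg, rng("voltage_threshold_mv", object@voltageThresholdMv, 0.05, 1.0))
  if (object@relativeThresholdSd < 1 || object@relativeThresholdSd > 10)
    msg <- c(msg, rng("relative_threshold_sd", object@relativeThresholdSd, 1, 10))
  if (object@binS < 0.001 || object@binS > 0.1)
    msg <- c(msg, rng("bin_s", object@binS, 0.001, 0.1))
  if (object@rasterThreshold <= 0.05 - 1e-12 || object@rasterThreshold > 0.8)
    msg <- c(msg, rng("raster_threshold", object@rasterThreshold, 0.05, 0.8))
  k <- object@windowS / object@binS
  if (abs(k - round(k)) > 1e-8 || round(k) < 1)
    msg <- c(msg, "window_s must be a positive integer multiple of bin_s")
  if (object@minEventGapBins < 0L)
    msg <- c(msg, "min_event_gap_bins must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname DetectorConfig-class
#' @param voltageThresholdMv,useRelativeThreshold,relativeThresholdSd,binS,windowS,rasterThreshold,minEventGapBins see slots.
#' @return A validated `DetectorConfig`.
#' @export
detectorConfig <- function(voltageThresholdMv = 0.20,
                           useRelativeThreshold = TRUE,
                           relativeThresholdSd = 3.0,
                           binS = 0.01,
                           windowS = 0.02,
                           rasterThreshold = 0.3,
                           minEventGapBins = 25L) {
  new("DetectorConfig", voltageThresholdMv = voltageThresholdMv,
      useRelativeThreshold = useRelativeThreshold,
      relativeThresholdSd = relativeThresholdSd, binS = binS,
      windowS = windowS, rasterThreshold = rasterThreshold,
      minEventGapBins = as.integer(minEventGapBins))
}

#' ScoreConfig: event typing and LFP-score parameters
#'
#' Type I (interictal-like) events are deflections at least `typeIAmpMult`
#' (3x) above baseline noise lasting 10-99 ms; type II (ictal-like) events are
#' multi-spike deflections at least `typeIIAmpMult` (5x) above baseline
#' lasting 45-5090 ms. Type II takes precedence where the two duration ranges
#' overlap. A recording scores 2 with any type II event, 1 with at least
#' `typeIMinCountForScore1` type I events and no type II, else 0; a genotype
#' group whose mean score reaches `epilepsyMeanScoreThreshold` (1.0) is called
#' epileptic.
#'
#' @slot typeIAmpMult,typeIIAmpMult amplitude gates in baseline-SD multiples.
#' @slot typeIDurMs,typeIIDurMs closed duration ranges in ms.
#' @slot typeIIMinSpikes minimum number of distinct spikes (debounced
#'   super-threshold excursions, see [detectEvents()]) for type II
#'   (default 2): type II activity is multi-spike, and a single biphasic
#'   sharp wave contributes one spike.
#' @slot typeIMinCountForScore1 type I events needed for score 1 (default 3).
#' @slot suppressionWindowS post-event window for suppression testing (s).
#' @slot suppressionSdFactor RMS factor defining suppression (default 0.5).
#' @slot epilepsyMeanScoreThreshold mean-score cut for the epilepsy call.
#' @export
setClass("ScoreConfig",
  representation(
    typeIAmpMult = "numeric",
    typeIDurMs = "numeric",
    typeIIAmpMult = "numeric",
    typeIIDurMs = "numeric",
    typeIIMinSpikes = "integer",
    typeIMinCountForScore1 = "integer",
    suppressionWindowS = "numeric",
    suppressionSdFactor = "numeric",
    epilepsyMeanScoreThreshold = "numeric"
  )
)

setValidity("ScoreConfig", function(object) {
  msg <- character()
  if (object@typeIIAmpMult <= object@typeIAmpMult)
    msg <- c(msg, "typeII_amp_mult must exceed typeI_amp_mult")
  if (length(object@typeIDurMs) != 2L || diff(object@typeIDurMs) < 0)
    msg <- c(msg, "typeI_dur_ms must be an ordered range")
  if (length(object@typeIIDurMs) != 2L || diff(object@typeIIDurMs) < 0)
    msg <- c(msg, "typeII_dur_ms must be an ordered range")
  if (object@epilepsyMeanScoreThreshold <= 0)
    msg <- c(msg, "epilepsy_mean_score_threshold must be > 0")
  if (object@suppressionWindowS <= 0 || object@suppressionSdFactor <= 0)
    msg <- c(msg, "suppression parameters must be positive")
  if (length(msg)) msg else TRUE
})

#' @rdname ScoreConfig-class
#' @param typeIAmpMult,typeIDurMs,typeIIAmpMult,typeIIDurMs,typeIIMinSpikes,typeIMinCountForScore1,suppressionWindowS,suppressionSdFactor,epilepsyMeanScoreThreshold see slots.
#' @return A validated `ScoreConfig`.
#' @export
scoreConfig <- function(typeIAmpMult = 3.0, typeIDurMs = c(10, 99),
                        typeIIAmpMult = 5.0, typeIIDurMs = c(45, 5090),
                        typeIIMinSpikes = 2L, typeIMinCountForScore1 = 3L,
                        suppressionWindowS = 5, suppressionSdFactor = 0.5,
                        epilepsyMeanScoreThreshold = 1.0) {
  new("ScoreConfig", typeIAmpMult = typeIAmpMult, typeIDurMs = typeIDurMs,
      typeIIAmpMult = typeIIAmpMult, typeIIDurMs = typeIIDurMs,
      typeIIMinSpikes = as.integer(typeIIMinSpikes),
      typeIMinCountForScore1 = as.integer(typeIMinCountForScore1),
      suppressionWindowS = suppressionWindowS,
      suppressionSdFactor = suppressionSdFactor,
      epilepsyMeanScoreThreshold = epilepsyMeanScoreThreshold)
}

#' BehaviorConfig: movement segmentation parameters
#'
#' Movement events are stretches where swim speed stays at or above
#' `speedThresholdMmS` (0.9 mm/s) for at least `minEventS` (160 ms); adjacent
#' stretches separated by less than `mergeGapS` (40 ms) are combined before
#' the minimum-duration filter. Events with maximum speed at or above the
#' data-driven cutoff (mean + `sdMultiplier` x SD of control maximum speeds)
#' are high-speed; events reaching `hseCutoffMmS` (28 mm/s) for at least
#' `seizureMinDurS` (1 s) are flagged seizure-like.
#'
#' @slot speedThresholdMmS movement threshold (mm/s).
#' @slot minEventS minimum event duration (s).
#' @slot mergeGapS maximum gap combined into one event (s); must be smaller
#'   than `minEventS`.
#' @slot hseCutoffMmS fixed high-speed / seizure-like speed cutoff (mm/s).
#' @slot seizureMinDurS minimum seizure-like duration (s).
#' @slot sdMultiplier multiplier for the data-driven speed-class cutoff.
#' @slot smoothing `"none"` or `"median3"` (3-frame running median).
#' @export
setClass("BehaviorConfig",
  representation(
    speedThresholdMmS = "numeric",
    minEventS = "numeric",
    mergeGapS = "numeric",
    hseCutoffMmS = "numeric",
    seizureMinDurS = "numeric",
    sdMultiplier = "numeric",
    smoothing = "character"
  )
)

setValidity("BehaviorConfig", function(object) {
  msg <- character()
  vals <- c(object@speedThresholdMmS, object@minEventS, object@mergeGapS,
            object@hseCutoffMmS, object@seizureMinDurS, object@sdMultiplier)
  if (any(vals <= 0)) msg <- c(msg, "all behavior thresholds must be positive")
  if (object@mergeGapS >= object@minEventS)
    msg <- c(msg, "merge_gap_s must be smaller than min_event_s")
  if (!object@smoothing %in% c("none", "median3"))
    msg <- c(msg, "smoothing must be 'none' or 'median3'")
  if (length(msg)) msg else TRUE
})

#' @rdname BehaviorConfig-class
#' @param speedThresholdMmS,minEventS,mergeGapS,hseCutoffMmS,seizureMinDurS,sdMultiplier,smoothing see slots.
#' @return A validated `BehaviorConfig`.
#' @export
behaviorConfig <- function(speedThresholdMmS = 0.9, minEventS = 0.16,
                           mergeGapS = 0.04, hseCutoffMmS = 28,
                           seizureMinDurS = 1.0, sdMultiplier = 1.5,
                           smoothing = "none") {
  new("BehaviorConfig", speedThresholdMmS = speedThresholdMmS,
      minEventS = minEventS, mergeGapS = mergeGapS,
      hseCutoffMmS = hseCutoffMmS, seizureMinDurS = seizureMinDurS,
      sdMultiplier = sdMultiplier, smoothing = smoothing)
}

#' PipelineConfig: the full, seedable pipeline configuration
#'
#' Bundles the detector, scorer and behavior configurations with the single
#' integer seed from which all pipeline randomness flows.
#'
#' @slot detector a [DetectorConfig-class].
#' @slot scorer a [ScoreConfig-class].
#' @slot behavior a [BehaviorConfig-class].
#' @slot seed integer RNG seed.
#' @export
setClass("PipelineConfig",
  representation(detector = "DetectorConfig", scorer = "ScoreConfig",
                 behavior = "BehaviorConfig", seed = "integer")
)

#' @rdname PipelineConfig-class
#' @param detector,scorer,behavior,seed see slots.
#' @return A validated `PipelineConfig`.
#' @export
pipelineConfig <- function(detector = detectorConfig(), scorer = scoreConfig(),
                           behavior = behaviorConfig(), seed = 1L) {
  new("PipelineConfig", detector = detector, scorer = scorer,
      behavior = behavior, seed = as.integer(seed))
}
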