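#' @include AllClasses.R utils.R
NULL

#' Robust baseline noise estimate
#'
#' Estimates the baseline noise SD of a recording while excluding
#' event-contaminated stretches: the trace is cut into 1 s segments, the 50%
#' of segments with the lowest segment-wise SD are kept, and the robust SD
#' (1.4826 x median absolute deviation about the median) is computed over the
#' kept samples. A constant trace gives 0.
#'
#' @param rec an [LfpRecording-class] with at least 2 s of signal.
#' @param segmentS segment length in seconds (default 1).
#' @return noise SD in mV.
#' @export
estimateNoise <- function(rec, segmentS = 1) {
  v <- voltage(rec)
  segLen <- round(segmentS * sampleRate(rec))
  nseg <- floor(length(v) / segLen)
  if (nseg < 2L)
    stopf("trace too short for noise estimation: need >= 2 segments of %g s",
          segmentS, class = "seizescreen_length_error")
  m <- matrix(v[seq_len(nseg * segLen)], nrow = segLen)
  mu <- colMeans(m)
  sds <- sqrt(pmax(0, colMeans(m * m) - mu * mu))
  keep <- order(sds)[seq_len(ceiling(nseg / 2))]
  stats::mad(m[, keep])
}

#' Binarize a trace against a voltage threshold
#'
#' Sample i scores 1 iff `|v_i - median(v)| >= T` where `T` is the absolute
#' voltage threshold, or `relativeThresholdSd` times the robust noise SD when
#' the relative threshold is enabled. Comparisons are inclusive.
#'
#' @param rec an [LfpRecording-class].
#' @param cfg a [DetectorConfig-class].
#' @param noiseSdMv optional pre-computed noise SD (avoids re-estimation).
#' @return integer vector of 0/1, one per sample.
#' @export
binarize <- function(rec, cfg = detectorConfig(), noiseSdMv = NULL) {
  validObject(cfg)
  v <- voltage(rec)
  thr <- if (cfg@useRelativeThreshold)
    cfg@relativeThresholdSd * (noiseSdMv %||% estimateNoise(rec))
  else cfg@voltageThresholdMv
  as.integer(abs(v - stats::median(v)) >= thr)
}

#' Sliding-window raster score
#'
#' The trace is cut into bins of `binS`; the score assigned to bin i is the
#' fraction of super-threshold samples within the window `[t_i, t_i +
#' windowS)` starting at that bin. Where the window overruns the trace end it
#' is truncated, so trailing scores average over fewer samples.
#'
#' @param binary 0/1 vector from [binarize()].
#' @param cfg a [DetectorConfig-class].
#' @param sampleRateHz sampling rate of the underlying trace.
#' @return A [RasterSeries-class] with `floor(n / (binS * rate))` scores.
#' @export
rasterScore <- function(binary, cfg = detectorConfig(), sampleRateHz = 10000) {
  validObject(cfg)
  n <- length(binary)
  spb <- cfg@binS * sampleRateHz
  if (abs(spb - round(spb)) > 1e-8)
    stopf("bin_s x sample_rate must be an integer number of samples")
  spb <- as.integer(round(spb))
  wlen <- as.integer(round(cfg@windowS / cfg@binS)) * spb
  if (n < wlen)
    stopf("trace shorter than one window (%g s)", cfg@windowS,
          class = "seizescreen_length_error")
  nbins <- n %/% spb
  cs <- c(0, cumsum(binary))
  startIdx <- (seq_len(nbins) - 1L) * spb + 1L
  endIdx <- pmin(startIdx + wlen - 1L, n)
  score <- (cs[endIdx + 1L] - cs[startIdx]) / (endIdx - startIdx + 1L)
  new("RasterSeries", score = score, binS = cfg@binS, t0S = 0)
}

# Debounced spike count within an event slice of the binarized trace:
# super-threshold excursions separated by less than 4 ms first merge into
# one spike (both lobes of a biphasic deflection, and threshold flicker on
# a plateau, count once), then merged spikes narrower than 2 ms are
# discarded as isolated noise crossings (the 1 kHz acquisition low-pass
# correlates samples, so such crossings last a few samples).
countSpikes <- function(b, rate) {
  gap <- max(0L, as.integer(round(0.004 * rate)) - 1L)
  r <- mergedRuns(b == 1L, gap)
  minWidth <- max(1L, as.integer(round(0.002 * rate)))
  sum(r[, 2L] - r[, 1L] + 1L >= minWidth)
}

# Maximal runs of TRUE, merging runs separated by <= gap FALSE entries.
# Returns a two-column matrix of (start, end) indices.
mergedRuns <- function(flag, gap) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  i <- which(r$values)
  if (!length(i)) return(matrix(integer(), ncol = 2L))
  s <- starts[i]; e <- ends[i]
  if (length(i) > 1L && gap > 0L) {
    keep <- which(s[-1L] - e[-length(e)] - 1L > gap)
    s <- s[c(1L, keep + 1L)]
    e <- e[c(keep, length(e))]
  }
  cbind(s, e)
}

#' Detect electrographic events from a raster series
#'
#' Maximal runs of bins with raster score at or above the raster threshold
#' become events; runs separated by at most `minEventGapBins` sub-threshold
#' bins are merged (so multi-spike bursts stay single events). Event
#' boundaries are the bin edges of the run. When the recording is supplied,
#' each event also carries its peak absolute deviation from the trace median
#' (`peak_amp_mv`, and `peak_amp_mult` in noise-SD multiples) and its count
#' of distinct super-threshold excursions (`n_spikes`). The spike count is
#' debounced: excursions shorter than 2 ms are discarded as noise flicker
#' and excursions separated by less than 4 ms merge into one spike, so a
#' single biphasic sharp wave (whose two lobes straddle a brief zero
#' crossing) contributes one spike.
#'
#' @param raster a [RasterSeries-class].
#' @param cfg a [DetectorConfig-class].
#' @param rec the source [LfpRecording-class] (optional but needed for
#'   amplitude and spike features).
#' @param binary pre-computed binarized trace (optional).
#' @param noiseSdMv pre-computed noise SD (optional).
#' @return data.frame with columns `start_s,end_s,duration_s,peak_amp_mv,
#'   peak_amp_mult,n_spikes`, sorted and non-overlapping.
#' @export
detectEvents <- function(raster, cfg = detectorConfig(), rec = NULL,
                         binary = NULL, noiseSdMv = NULL) {
  stopifnot(is(raster, "RasterSeries"))
  runs <- mergedRuns(raster@score >= cfg@rasterThreshold,
                     as.integer(cfg@minEventGapBins))
  if (!nrow(runs)) return(emptyEvents())
  startS <- raster@t0S + (runs[, 1L] - 1L) * raster@binS
  endS <- raster@t0S + runs[, 2L] * raster@binS
  out <- data.frame(start_s = startS, end_s = endS,
                    duration_s = endS - startS,
                    peak_amp_mv = NA_real_, peak_amp_mult = NA_real_,
                    n_spikes = NA_integer_)
  if (!is.null(rec)) {
    v <- voltage(rec)
    rate <- sampleRate(rec)
    med <- stats::median(v)
    if (is.null(noiseSdMv)) noiseSdMv <- estimateNoise(rec)
    if (is.null(binary)) binary <- binarize(rec, cfg, noiseSdMv = noiseSdMv)
    for (k in seq_len(nrow(out))) {
      i0 <- max(1L, round(startS[k] * rate) + 1L)
      i1 <- min(length(v), round(endS[k] * rate))
      peak <- max(abs(v[i0:i1] - med))
      out$peak_amp_mv[k] <- peak
      out$peak_amp_mult[k] <- if (noiseSdMv > 0) peak / noiseSdMv else Inf
      out$n_spikes[k] <- countSpikes(binary[i0:i1], rate)
    }
  }
  out
}

#' One-call LFP event detection
#'
#' Convenience wrapper running the full detector on a recording: noise
#' estimation, binarization, raster scoring and event segmentation.
#'
#' @param rec an [LfpRecording-class].
#' @param cfg a [DetectorConfig-class].
#' @return list with `events` (see [detectEvents()]), `noiseSdMv`, and
#'   `raster` (the [RasterSeries-class]).
#' @examples
#' g <- genLfp(lfpGenParams(durationS = 20, interictalRatePerMin = 9,
#'                          ictalRatePer15Min = 0), seed = 11)
#' det <- detectLfp(g$recording)
#' nrow(det$events)
#' @export
detectLfp <- function(rec, cfg = detectorConfig()) {
  noiseSd <- estimateNoise(rec)
  b <- binarize(rec, cfg, noiseSdMv = noiseSd)
  ras <- rasterScore(b, cfg, sampleRateHz = sampleRate(rec))
  ev <- detectEvents(ras, cfg, rec = rec, binary = b, noiseSdMv = noiseSd)
  list(events = ev, noiseSdMv = noiseSd, raster = ras)
}

#' Tune detector thresholds against reference annotations
#'
#' Grid search over the voltage threshold (0.15-0.25 mV) and raster score
#' threshold (0.2-0.4): for each grid point the detector runs on the supplied
#' epoch and the relative discrepancy between automated and reference total
#' event duration (or event count) is evaluated. The grid point minimising
#' the discrepancy is returned provided it is below `tol` (3%, the
#' auto-vs-manual acceptance rule); ties break toward the smaller voltage,
#' then the smaller raster threshold.
#'
#' @param rec the tuning epoch (a short [LfpRecording-class], typically 10 s).
#' @param manual reference annotation data.frame with `start_s`, `end_s`
#'   (e.g. manual marks or ground truth).
#' @param cfg base [DetectorConfig-class]; the tuned thresholds are written
#'   into a copy with the absolute threshold enabled.
#' @param voltageGrid,rasterGrid grid values (defaults span the study ranges).
#' @param compare `"total_duration"` (default) or `"count"`.
#' @param tol acceptance tolerance on the relative discrepancy (default 0.03).
#' @return The tuned [DetectorConfig-class]; attributes `ratio` (achieved
#'   discrepancy) and `grid` (full grid results).
#' @export
tuneThresholds <- function(rec, manual, cfg = detectorConfig(),
                           voltageGrid = seq(0.15, 0.25, by = 0.0125),
                           rasterGrid = seq(0.20, 0.40, by = 0.025),
                           compare = c("total_duration", "count"),
                           tol = 0.03) {
  compare <- match.arg(compare)
  refTotal <- if (compare == "total_duration")
    sum(manual$end_s - manual$start_s) else nrow(manual)
  if (!is.finite(refTotal) || refTotal <= 0)
    stopf("reference annotations are empty; cannot tune against them")
  v <- voltage(rec)
  absdev <- abs(v - stats::median(v))
  rate <- sampleRate(rec)
  grid <- expand.grid(voltage = voltageGrid, raster = rasterGrid)
  grid <- grid[order(grid$voltage, grid$raster), , drop = FALSE]
  grid$ratio <- NA_real_
  for (i in seq_len(nrow(grid))) {
    cfgI <- cfg
    cfgI@voltageThresholdMv <- grid$voltage[i]
    cfgI@rasterThreshold <- grid$raster[i]
    cfgI@useRelativeThreshold <- FALSE
    b <- as.integer(absdev >= grid$voltage[i])
    ras <- rasterScore(b, cfgI, sampleRateHz = rate)
    ev <- detectEvents(ras, cfgI)
    auto <- if (compare == "total_duration") sum(ev$duration_s) else nrow(ev)
    grid$ratio[i] <- abs(auto - refTotal) / refTotal
  }
  best <- which.min(grid$ratio)   # grid sorted: ties fall on smaller V, then raster
  if (grid$ratio[best] >= tol)
    stop(errorCondition(
      sprintf("tuning failed: best achieved discrepancy %.1f%% >= %.0f%%",
              100 * grid$ratio[best], 100 * tol),
      class = c("seizescreen_tuning_error", "error"),
      ratio = grid$ratio[best]))
  out <- cfg
  out@voltageThresholdMv <- grid$voltage[best]
  out@rasterThreshold <- grid$raster[best]
  out@useRelativeThreshold <- FALSE
  attr(out, "ratio") <- grid$ratio[best]
  attr(out, "grid") <- grid
  out
}

#' Per-recording event summary
#'
#' @param events detected-events data.frame.
#' @param rec the source recording (for the epoch duration).
#' @return one-row data.frame: `n_events`, `freq_per_min`
#'   (count / minutes), `mean_duration_s`, `max_duration_s` (zeros when no
#'   events were detected).
#' @export
eventStats <- function(events, rec) {
  minutes <- durationS(rec) / 60
  if (!nrow(events))
    return(data.frame(n_events = 0L, freq_per_min = 0,
                      mean_duration_s = 0, max_duration_s = 0))
  data.frame(n_events = nrow(events),
             freq_per_min = nrow(events) / minutes,
             mean_duration_s = mean(events$duration_s),
             max_duration_s = max(events$duration_s))
}
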