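#' @include AllClasses.R utils.R
NULL

#' Classify detected events into types 0 / I / II
#'
#' An event is type II (ictal-like) iff its peak reaches `typeIIAmpMult` (5x)
#' times the baseline noise SD, its duration lies in the type II range
#' (45-5090 ms) and it comprises at least `typeIIMinSpikes` distinct spikes
#' (multi-spike morphology; see [detectEvents()] for the debounced spike
#' count); otherwise it is
#' type I (interictal-like) iff its peak reaches `typeIAmpMult` (3x) the
#' noise SD and its duration lies in 10-99 ms; all remaining events are
#' type 0. Type II is tested first, so an event satisfying both
#' definitions (the duration ranges overlap on 45-99 ms) takes the more
#' severe class.
#'
#' @param events detected-events data.frame (needs `peak_amp_mv`,
#'   `duration_s` and `n_spikes`).
#' @param noiseSdMv baseline noise SD in mV (> 0).
#' @param cfg a [ScoreConfig-class].
#' @return `events` with added columns `peak_amp_mult` (recomputed against
#'   `noiseSdMv`) and `event_type` (factor with levels `0`, `I`, `II`).
#' @export
classifyEvents <- function(events, noiseSdMv, cfg = scoreConfig()) {
  validObject(cfg)
  if (noiseSdMv <= 0) stopf("noiseSdMv must be > 0")
  mult <- events$peak_amp_mv / noiseSdMv
  durMs <- events$duration_s * 1000
  nSpikes <- if (is.null(events$n_spikes)) rep(NA_integer_, nrow(events)) else events$n_spikes
  isII <- mult >= cfg@typeIIAmpMult &
    durMs >= cfg@typeIIDurMs[1L] & durMs <= cfg@typeIIDurMs[2L] &
    (is.na(nSpikes) | nSpikes >= cfg@typeIIMinSpikes)
  isI <- !isII & mult >= cfg@typeIAmpMult &
    durMs >= cfg@typeIDurMs[1L] & durMs <= cfg@typeIDurMs[2L]
  events$peak_amp_mult <- mult
  events$event_type <- factor(ifelse(isII, "II", ifelse(isI, "I", "0")),
                              levels = c("0", "I", "II"))
  events
}

#' Score one recording epoch on the 0/1/2 LFP scale
#'
#' A recording scores 2 with at least one type II event, 1 with no type II
#' but at least `typeIMinCountForScore1` type I events, and 0 otherwise.
#'
#' The original screen's epochs were graded by two independent raters and
#' their scores averaged; this can be emulated by passing a `secondCfg`
#' (e.g. a stricter variant), in which case the reported score is the mean
#' of the two passes and need not be an integer.
#'
#' @param events classified events (from [classifyEvents()]); when
#'   `secondCfg` is given, the unclassified events plus `noiseSdMv` must be
#'   supplied so both passes can classify independently.
#' @param cfg a [ScoreConfig-class].
#' @param subjectId subject label carried into the result.
#' @param secondCfg optional second [ScoreConfig-class] emulating a second
#'   rater (default off).
#' @param noiseSdMv baseline noise SD, needed only with `secondCfg`.
#' @return one-row data.frame: `subject_id, score, n_typeI, n_typeII`
#'   (counts from the first pass).
#' @export
scoreRecording <- function(events, cfg = scoreConfig(), subjectId = "subject",
                           secondCfg = NULL, noiseSdMv = NULL) {
  onePass <- function(ev, cf) {
    nI <- sum(ev$event_type == "I")
    nII <- sum(ev$event_type == "II")
    list(nI = nI, nII = nII,
         score = if (nII >= 1L) 2L
         else if (nI >= cf@typeIMinCountForScore1) 1L
         else 0L)
  }
  p1 <- onePass(events, cfg)
  score <- p1$score
  if (!is.null(secondCfg)) {
    if (is.null(noiseSdMv))
      stopf("noiseSdMv is required for a second-rater pass")
    ev2 <- classifyEvents(events, noiseSdMv, secondCfg)
    score <- (p1$score + onePass(ev2, secondCfg)$score) / 2
  }
  data.frame(subject_id = subjectId, score = score,
             n_typeI = p1$nI, n_typeII = p1$nII)
}

#' Test for post-ictal suppression after an event
#'
#' Ictal-like discharges are often followed by a transient stretch of
#' electrical suppression. The test computes the RMS of the median-subtracted
#' trace over `suppressionWindowS` after the event end and compares it with
#' `suppressionSdFactor` times the baseline noise SD. When less than a full
#' window of signal remains the available stretch is used and the result is
#' flagged partial.
#'
#' @param rec the [LfpRecording-class].
#' @param event one-row event (needs `end_s`).
#' @param cfg a [ScoreConfig-class].
#' @param noiseSdMv baseline noise SD (estimated if missing).
#' @return logical; attribute `partial` is `TRUE` when the window was
#'   truncated ( `NA` if no signal remained).
#' @export
detectSuppression <- function(rec, event, cfg = scoreConfig(),
                              noiseSdMv = NULL) {
  if (is.null(noiseSdMv)) noiseSdMv <- estimateNoise(rec)
  v <- voltage(rec)
  rate <- sampleRate(rec)
  i0 <- round(event$end_s * rate) + 1L
  i1 <- min(length(v), round((event$end_s + cfg@suppressionWindowS) * rate))
  partial <- i1 < round((event$end_s + cfg@suppressionWindowS) * rate)
  if (i0 > length(v)) {
    out <- NA
    attr(out, "partial") <- TRUE
    return(out)
  }
  seg <- v[i0:i1] - stats::median(v)
  out <- sqrt(mean(seg^2)) <= cfg@suppressionSdFactor * noiseSdMv
  attr(out, "partial") <- partial
  out
}

#' Annotate events with the post-ictal suppression flag
#'
#' Applies [detectSuppression()] to every event, adding a
#' `suppression_follows` column (`NA` where no signal remains after the
#' event).
#'
#' @param rec the [LfpRecording-class].
#' @param events detected (optionally classified) events.
#' @param cfg a [ScoreConfig-class].
#' @param noiseSdMv baseline noise SD (estimated if missing).
#' @return `events` with the added logical column.
#' @export
annotateSuppression <- function(rec, events, cfg = scoreConfig(),
                                noiseSdMv = NULL) {
  if (is.null(noiseSdMv)) noiseSdMv <- estimateNoise(rec)
  events$suppression_follows <- vapply(seq_len(nrow(events)), function(k) {
    as.logical(detectSuppression(rec, events[k, ], cfg, noiseSdMv = noiseSdMv))
  }, logical(1))
  events
}

#' Aggregate per-recording scores into a line summary
#'
#' For each genotype group of a line: group size, mean LFP score, percentage
#' of subjects with at least one type II event, and the epilepsy call
#' (mean score at or above `epilepsyMeanScoreThreshold`; the threshold is
#' inclusive, "a mean score of 1.0 or above").
#'
#' @param scores data.frame of per-recording scores (from
#'   [scoreRecording()]) with added `genotype` and `line` columns.
#' @param cfg a [ScoreConfig-class].
#' @return data.frame with one row per line x genotype:
#'   `line, genotype, n, mean_score, pct_typeII, epilepsy_call`; the pooled
#'   per-larva score vectors are attached as attribute `per_larva` (a named
#'   list keyed by `line.genotype`).
#' @export
summarizeLine <- function(scores, cfg = scoreConfig()) {
  stopifnot(all(c("score", "n_typeII", "genotype", "line") %in% names(scores)))
  key <- interaction(scores$line, scores$genotype, drop = TRUE)
  rows <- lapply(levels(key), function(k) {
    sub <- scores[key == k, , drop = FALSE]
    data.frame(line = sub$line[1L], genotype = sub$genotype[1L],
               n = nrow(sub), mean_score = mean(sub$score),
               pct_typeII = 100 * mean(sub$n_typeII >= 1L),
               epilepsy_call = mean(sub$score) >= cfg@epilepsyMeanScoreThreshold)
  })
  out <- do.call(rbind, rows)
  attr(out, "per_larva") <- split(scores$score, key)
  out
}

#' Regress mean LFP score on percent type II across lines
#'
#' Ordinary least squares of the per-line mean score on the per-line
#' percentage of subjects showing type II activity.
#'
#' @param lineSummary output of [summarizeLine()] (one row per line /
#'   genotype cell to include).
#' @return list with `slope`, `intercept`, `r_squared`, `p_slope` (see
#'   [linearFit()]).
#' @export
regressScoreVsPctII <- function(lineSummary) {
  linearFit(lineSummary$pct_typeII, lineSummary$mean_score)
}
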