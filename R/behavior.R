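#' @include AllClasses.R utils.R
NULL

#' Frame-to-frame swim speed
#'
#' Euclidean step distance between consecutive tracked frames times the frame
#' rate, in mm/s; one value per frame interval. Intervals touching an
#' untracked (gap) frame are `NA` and excluded from downstream computation.
#' Optional 3-frame running-median smoothing.
#'
#' @param track a [SwimTrack-class] with at least 2 frames.
#' @param cfg a [BehaviorConfig-class] (controls smoothing).
#' @return numeric vector of length `nframes - 1`.
#' @export
computeSpeed <- function(track, cfg = behaviorConfig()) {
  x <- track@xMm; y <- track@yMm
  if (length(x) < 2L) stopf("track needs at least 2 frames")
  if (all(is.na(x))) stopf("track has no valid positions",
                           class = "seizescreen_quality_error")
  speed <- sqrt(diff(x)^2 + diff(y)^2) * fps(track)
  if (cfg@smoothing == "median3" && length(speed) >= 3L) {
    nas <- is.na(speed)
    tmp <- speed
    tmp[nas] <- 0
    sm <- stats::runmed(tmp, 3L)
    sm[nas] <- NA
    speed <- sm
  }
  speed
}

#' Segment a speed series into movement events
#'
#' Maximal runs of speed at or above `speedThresholdMmS` (0.9 mm/s) become
#' candidate events; runs separated by a gap shorter than `mergeGapS` (40 ms)
#' are combined first, and only then are events shorter than `minEventS`
#' (160 ms) discarded — so two short sub-bouts can form one valid movement.
#' Each event carries its duration, maximum speed and path distance.
#'
#' @param speed numeric speed series (mm/s, `NA` = gap, treated as
#'   sub-threshold).
#' @param fps frame rate of the series.
#' @param cfg a [BehaviorConfig-class].
#' @return data.frame with columns
#'   `start_s,end_s,duration_s,max_speed_mm_s,distance_mm`, sorted, disjoint.
#' @export
segmentMovements <- function(speed, fps = 25, cfg = behaviorConfig()) {
  validObject(cfg)
  above <- !is.na(speed) & speed >= cfg@speedThresholdMmS
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  i <- which(r$values)
  if (!length(i))
    return(data.frame(start_s = numeric(), end_s = numeric(),
                      duration_s = numeric(), max_speed_mm_s = numeric(),
                      distance_mm = numeric()))
  s <- starts[i]; e <- ends[i]
  # merge gaps strictly shorter than mergeGapS, then filter short events
  if (length(s) > 1L) {
    gapFrames <- s[-1L] - e[-length(e)] - 1L
    keep <- which(gapFrames / fps >= cfg@mergeGapS - 1e-12)
    s <- s[c(1L, keep + 1L)]
    e <- e[c(keep, length(e))]
  }
  dur <- (e - s + 1L) / fps
  sel <- dur >= cfg@minEventS - 1e-12
  s <- s[sel]; e <- e[sel]; dur <- dur[sel]
  if (!length(s))
    return(data.frame(start_s = numeric(), end_s = numeric(),
                      duration_s = numeric(), max_speed_mm_s = numeric(),
                      distance_mm = numeric()))
  maxSpeed <- vapply(seq_along(s), function(k)
    max(speed[s[k]:e[k]], na.rm = TRUE), numeric(1))
  dist <- vapply(seq_along(s), function(k)
    sum(speed[s[k]:e[k]], na.rm = TRUE) / fps, numeric(1))
  data.frame(start_s = (s - 1L) / fps, end_s = e / fps, duration_s = dur,
             max_speed_mm_s = maxSpeed, distance_mm = dist)
}

#' Data-driven high-speed cutoff from a control cohort
#'
#' The speed-class cutoff is the mean plus `sdMultiplier` (1.5) standard
#' deviations of the per-movement maximum-speed distribution of a large
#' control group.
#'
#' @param controlMaxSpeeds per-movement maximum speeds (mm/s) pooled from the
#'   control cohort; at least `minMovements` are required (>= 100
#'   recommended, matching the N > 100 control group of the original assay).
#' @param cfg a [BehaviorConfig-class].
#' @param minMovements smallest control sample accepted (default 10).
#' @return cutoff speed in mm/s.
#' @export
deriveSpeedCutoff <- function(controlMaxSpeeds, cfg = behaviorConfig(),
                              minMovements = 10L) {
  if (length(controlMaxSpeeds) < minMovements)
    stopf("need >= %d control movements to derive a cutoff (got %d)",
          minMovements, length(controlMaxSpeeds),
          class = "seizescreen_insufficient_data_error")
  mean(controlMaxSpeeds) + cfg@sdMultiplier * stats::sd(controlMaxSpeeds)
}

#' Classify movements and flag seizure-like events
#'
#' `speed_class` is `high` iff the event's maximum speed reaches the
#' (data-driven) cutoff; `seizure_like` is flagged from the fixed rule:
#' maximum speed at or above `hseCutoffMmS` (28 mm/s) and duration at or
#' above `seizureMinDurS` (1 s). Comparisons are inclusive.
#'
#' @param events movement events from [segmentMovements()].
#' @param cutoff data-driven speed-class cutoff (mm/s); defaults to the
#'   fixed 28 mm/s cutoff when no control distribution is available.
#' @param cfg a [BehaviorConfig-class].
#' @return `events` with added `speed_class` and `seizure_like` columns.
#' @export
classifyMovements <- function(events, cutoff = NULL, cfg = behaviorConfig()) {
  cutoff <- cutoff %||% cfg@hseCutoffMmS
  events$speed_class <- ifelse(events$max_speed_mm_s >= cutoff, "high", "low")
  events$seizure_like <- events$max_speed_mm_s >= cfg@hseCutoffMmS &
    events$duration_s >= cfg@seizureMinDurS
  events
}

#' Per-larva behavioral summary
#'
#' Totals over one track: path distance, maximum velocity, movement count,
#' high-speed events (maximum speed at or above 28 mm/s) and long-duration
#' high-speed events (additionally lasting at least 1 s, the behavioral
#' seizure-like surrogate).
#'
#' @param events classified movement events.
#' @param speed the full speed series of the track.
#' @param fps frame rate.
#' @param cfg a [BehaviorConfig-class].
#' @param subjectId label carried into the result.
#' @return one-row data.frame: `subject_id, total_distance_mm,
#'   max_velocity_mm_s, n_movements, n_hse, n_long_hse`.
#' @export
summarizeLarva <- function(events, speed, fps = 25, cfg = behaviorConfig(),
                           subjectId = "subject") {
  hse <- events$max_speed_mm_s >= cfg@hseCutoffMmS
  data.frame(subject_id = subjectId,
             total_distance_mm = sum(speed, na.rm = TRUE) / fps,
             max_velocity_mm_s = if (any(!is.na(speed)))
               max(speed, na.rm = TRUE) else 0,
             n_movements = nrow(events),
             n_hse = sum(hse),
             n_long_hse = sum(hse & events$duration_s >= cfg@seizureMinDurS))
}

#' Dose-response table of seizure-like event counts
#'
#' Mean and SEM of per-larva seizure-like counts per dose x time-window
#' condition. With a monotone dose effect the mean counts rise with dose;
#' a high-dose mortality knock-down at late windows shows up as a
#' non-monotone late column.
#'
#' @param counts data.frame with one row per larva and columns `dose`,
#'   `window`, `n_seizure`.
#' @return data.frame with one row per condition: `dose, window, n,
#'   mean_count, sem_count`.
#' @export
doseResponse <- function(counts) {
  stopifnot(all(c("dose", "window", "n_seizure") %in% names(counts)))
  key <- interaction(counts$dose, counts$window, drop = TRUE)
  rows <- lapply(levels(key), function(k) {
    sub <- counts[key == k, , drop = FALSE]
    data.frame(dose = sub$dose[1L], window = sub$window[1L], n = nrow(sub),
               mean_count = mean(sub$n_seizure), sem_count = sem(sub$n_seizure))
  })
  out <- do.call(rbind, rows)
  out[order(out$window, out$dose), , drop = FALSE]
}

#' Full behavioral analysis of one track
#'
#' Convenience wrapper: speed, segmentation, classification, summary.
#'
#' @param track a [SwimTrack-class].
#' @param cfg a [BehaviorConfig-class].
#' @param cutoff optional data-driven speed-class cutoff.
#' @return list with `speed`, `events` (classified) and `summary`.
#' @export
analyzeTrack <- function(track, cfg = behaviorConfig(), cutoff = NULL) {
  speed <- computeSpeed(track, cfg)
  ev <- segmentMovements(speed, fps = fps(track), cfg = cfg)
  ev <- classifyMovements(ev, cutoff = cutoff, cfg = cfg)
  list(speed = speed, events = ev,
       summary = summarizeLarva(ev, speed, fps = fps(track), cfg = cfg,
                                subjectId = subjectId(track)))
}
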