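#' @include AllClasses.R utils.R
NULL

#' TrackGenParams: synthetic swim-trajectory generator parameters
#'
#' The generator integrates a piecewise speed profile — sub-threshold rest
#' jitter, raised-cosine swim bouts, and sustained high-speed seizure-like
#' events — along randomly heading paths with reflection at the (circular)
#' arena wall, emulating a larva tracked at 25 frames/s in a 96-well plate.
#'
#' Wild-type defaults are calibrated so that after movement segmentation at
#' the standard thresholds (0.9 mm/s, 160 ms minimum, <40 ms merge) the mean
#' of per-movement maximum speeds is about 10.5 mm/s with bout durations
#' under 1 s, matching the printed control-cohort summary; rest jitter stays
#' below the 0.9 mm/s movement threshold. Seizure-like events must be
#' generated with peak speed above 28 mm/s and duration above 1 s, otherwise
#' the label would be violated and the constructor errors.
#'
#' An optional convulsant dose increases the seizure rate linearly
#' (`doseRateSlopePer15MinPerMm`); at doses at or above `mortalityDoseMm` a
#' larva may die with probability `1 - exp(-mortalityRatePerMin *
#' exposureMin)`, after which it stops moving — reproducing the drop in
#' detected events at high dose and long exposure.
#'
#' @slot fps frame rate (default 25).
#' @slot durationS track length in s (default 900).
#' @slot arenaRadiusMm circular arena radius (default 3.5 mm, 96-well scale).
#' @slot boutRatePerMin Poisson rate of swim bouts (default 6).
#' @slot boutDurS bout duration sampling range (s), default 0.2-0.8.
#' @slot boutPeakSpeedMeanlog,boutPeakSpeedSdlog log-normal parameters of the
#'   bout peak speed (mm/s).
#' @slot restSpeedSdMmS per-axis SD of the rest jitter displacement rate
#'   (mm/s); must keep finite-difference rest speed below 0.9 mm/s.
#' @slot seizureRatePer15Min expected seizure-like events per 15 min.
#' @slot seizurePeakSpeedMmS peak-speed range for seizure-like events
#'   (> 28 mm/s).
#' @slot seizureDurS duration range for seizure-like events (> 1 s).
#' @slot dose convulsant dose (mM), non-negative.
#' @slot doseRateSlopePer15MinPerMm added seizure rate per mM of dose.
#' @slot mortalityDoseMm dose at or above which mortality can occur.
#' @slot mortalityRatePerMin mortality hazard per minute of exposure.
#' @slot exposureMin minutes of drug exposure before the track starts.
#' @export
setClass("TrackGenParams",
  representation(
    fps = "numeric", durationS = "numeric", arenaRadiusMm = "numeric",
    boutRatePerMin = "numeric", boutDurS = "numeric",
    boutPeakSpeedMeanlog = "numeric", boutPeakSpeedSdlog = "numeric",
    restSpeedSdMmS = "numeric", seizureRatePer15Min = "numeric",
    seizurePeakSpeedMmS = "numeric", seizureDurS = "numeric",
    dose = "numeric", doseRateSlopePer15MinPerMm = "numeric",
    mortalityDoseMm = "numeric", mortalityRatePerMin = "numeric",
    exposureMin = "numeric"
  )
)

setValidity("TrackGenParams", function(object) {
  msg <- character()
  if (object@fps <= 0 || object@durationS <= 0 || object@arenaRadiusMm <= 0)
    msg <- c(msg, "fps, durationS and arenaRadiusMm must be positive")
  if (object@restSpeedSdMmS >= 0.9)
    msg <- c(msg, "restSpeedSdMmS must stay below the 0.9 mm/s movement threshold")
  seizureRequested <- object@seizureRatePer15Min > 0 ||
    object@dose * object@doseRateSlopePer15MinPerMm > 0
  if (seizureRequested && object@seizurePeakSpeedMmS[1L] <= 28)
    msg <- c(msg, "seizure events requested but seizure_peak_speed <= 28 mm/s would violate the seizure-like label")
  if (seizureRequested && object@seizureDurS[1L] <= 1)
    msg <- c(msg, "seizure events requested but seizure_dur_s <= 1 s would violate the seizure-like label")
  if (object@dose < 0) msg <- c(msg, "dose must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @rdname TrackGenParams-class
#' @param fps,durationS,arenaRadiusMm,boutRatePerMin,boutDurS,boutPeakSpeedMeanlog,boutPeakSpeedSdlog,restSpeedSdMmS,seizureRatePer15Min,seizurePeakSpeedMmS,seizureDurS,dose,doseRateSlopePer15MinPerMm,mortalityDoseMm,mortalityRatePerMin,exposureMin see slots.
#' @return A validated `TrackGenParams`.
#' @export
trackGenParams <- function(fps = 25, durationS = 900, arenaRadiusMm = 3.5,
                           boutRatePerMin = 6, boutDurS = c(0.2, 0.8),
                           boutPeakSpeedMeanlog = log(10.1),
                           boutPeakSpeedSdlog = 0.35,
                           restSpeedSdMmS = 0.15,
                           seizureRatePer15Min = 0,
                           seizurePeakSpeedMmS = c(30, 40),
                           seizureDurS = c(1.2, 3),
                           dose = 0, doseRateSlopePer15MinPerMm = 0.4,
                           mortalityDoseMm = 10, mortalityRatePerMin = 0.02,
                           exposureMin = 0) {
  new("TrackGenParams", fps = fps, durationS = durationS,
      arenaRadiusMm = arenaRadiusMm, boutRatePerMin = boutRatePerMin,
      boutDurS = boutDurS, boutPeakSpeedMeanlog = boutPeakSpeedMeanlog,
      boutPeakSpeedSdlog = boutPeakSpeedSdlog,
      restSpeedSdMmS = restSpeedSdMmS,
      seizureRatePer15Min = seizureRatePer15Min,
      seizurePeakSpeedMmS = seizurePeakSpeedMmS, seizureDurS = seizureDurS,
      dose = dose, doseRateSlopePer15MinPerMm = doseRateSlopePer15MinPerMm,
      mortalityDoseMm = mortalityDoseMm,
      mortalityRatePerMin = mortalityRatePerMin, exposureMin = exposureMin)
}

#' Generate a synthetic swim track with ground truth
#'
#' Positions integrate a piecewise speed profile: isotropic rest jitter,
#' raised-cosine speed bumps for bouts (peak speed log-normal), and
#' trapezoidal sustained high speed with erratic heading for seizure-like
#' events, reflected at the circular arena wall. The ground truth lists every
#' injected bout and seizure-like event with its peak speed.
#'
#' @param params a [TrackGenParams-class].
#' @param seed integer seed.
#' @param subjectId,genotype,line,condition metadata labels.
#' @return A list with `track` ([SwimTrack-class]) and `truth` (data.frame
#'   with `subject_id,start_s,end_s,label,source,peak_speed_mm_s`; labels are
#'   `bout` / `seizure_like`), plus `alive` (FALSE if the larva died under
#'   high-dose exposure before or during the track).
#' @examples
#' g <- genTrack(trackGenParams(durationS = 60), seed = 3)
#' summary(computeSpeed(g$track))
#' @export
genTrack <- function(params, seed, subjectId = "synth", genotype = "WT",
                     line = "synthetic", condition = "baseline") {
  stopifnot(is(params, "TrackGenParams"))
  validObject(params)
  withSeed(seed, {
    dt <- 1 / params@fps
    nSteps <- round(params@durationS * params@fps)
    alive <- TRUE
    if (params@dose >= params@mortalityDoseMm && params@mortalityDoseMm > 0) {
      pDead <- 1 - exp(-params@mortalityRatePerMin * params@exposureMin)
      alive <- stats::runif(1L) >= pDead
    }
    seizureRate <- params@seizureRatePer15Min +
      params@dose * params@doseRateSlopePer15MinPerMm
    nB <- if (alive) stats::rpois(1L, params@boutRatePerMin * params@durationS / 60) else 0L
    nS <- if (alive) stats::rpois(1L, seizureRate * params@durationS / 900) else 0L
    dB <- stats::runif(nB, params@boutDurS[1L], params@boutDurS[2L])
    dS <- stats::runif(nS, params@seizureDurS[1L], params@seizureDurS[2L])
    starts <- placeEvents(c(dB, dS), params@durationS, minGapS = 0.3,
                          margin = 0.5)
    pB <- stats::rlnorm(nB, params@boutPeakSpeedMeanlog, params@boutPeakSpeedSdlog)
    pS <- stats::runif(nS, params@seizurePeakSpeedMmS[1L], params@seizurePeakSpeedMmS[2L])
    labels <- c(rep("bout", nB), rep("seizure_like", nS))
    durs <- c(dB, dS)
    peaks <- c(pB, pS)
    # speed profile per frame interval, and per-interval heading wobble
    tMid <- (seq_len(nSteps) - 0.5) * dt
    speed <- numeric(nSteps)
    wobble <- numeric(nSteps)
    for (k in seq_along(starts)) {
      idx <- which(tMid >= starts[k] & tMid < starts[k] + durs[k])
      if (!length(idx)) next
      u <- (tMid[idx] - starts[k]) / durs[k]
      prof <- if (labels[k] == "bout") {
        sin(pi * u)^2                     # raised-cosine bump, peak mid-bout
      } else {
        ramp <- min(0.15 / durs[k], 0.25) # trapezoid with 150 ms ramps
        pmin(1, pmin(u, 1 - u) / ramp)
      }
      speed[idx] <- pmax(speed[idx], peaks[k] * prof)
      wobble[idx] <- if (labels[k] == "bout") 0.3 else 1.5
    }
    # integrate the path with reflection inside the circular arena
    R <- params@arenaRadiusMm
    x <- numeric(nSteps + 1L); y <- numeric(nSteps + 1L)
    r0 <- sqrt(stats::runif(1L)) * 0.6 * R
    a0 <- stats::runif(1L, 0, 2 * pi)
    x[1L] <- r0 * cos(a0); y[1L] <- r0 * sin(a0)
    th <- stats::runif(1L, 0, 2 * pi)
    jit <- stats::rnorm(2L * nSteps, sd = params@restSpeedSdMmS * dt)
    wob <- stats::rnorm(nSteps)
    newHeading <- stats::runif(nSteps, 0, 2 * pi)
    for (i in seq_len(nSteps)) {
      if (speed[i] > 0) {
        if (i == 1L || speed[i - 1L] == 0) th <- newHeading[i]
        th <- th + wob[i] * wobble[i]
        px <- x[i] + speed[i] * dt * cos(th)
        py <- y[i] + speed[i] * dt * sin(th)
      } else {
        px <- x[i] + jit[2L * i - 1L]
        py <- y[i] + jit[2L * i]
      }
      rr <- sqrt(px * px + py * py)
      if (rr > R) {            # radial fold-back across the wall
        scale <- (2 * R - rr) / rr
        if (scale < 0) scale <- 0.5 * R / rr
        px <- px * scale; py <- py * scale
        th <- th + pi + 0.5 * wob[i]
      }
      x[i + 1L] <- px; y[i + 1L] <- py
    }
    truth <- data.frame(subject_id = rep(subjectId, length(starts)),
                        start_s = starts, end_s = starts + durs,
                        label = labels, source = rep("ground_truth", length(starts)),
                        peak_speed_mm_s = peaks)
    truth <- truth[order(truth$start_s), , drop = FALSE]
    rownames(truth) <- NULL
    list(track = swimTrack(x, y, fps = params@fps, arenaRadiusMm = R,
                           subjectId = subjectId, genotype = genotype,
                           line = line, condition = condition),
         truth = truth, alive = alive)
  })
}

#' Generate a cohort of swim tracks
#'
#' @param params a [TrackGenParams-class] shared by all subjects.
#' @param n number of larvae.
#' @param seed integer seed (per-subject child seeds are derived from it).
#' @param genotype,line,condition metadata labels.
#' @return A list with `tracks` (list of [SwimTrack-class]), `truth`
#'   (combined ground truth) and `alive` (logical vector).
#' @export
genTrackCohort <- function(params, n, seed, genotype = "WT",
                           line = "synthetic", condition = "baseline") {
  seeds <- childSeeds(seed, n)
  tracks <- list(); truths <- list(); alive <- logical(n)
  for (i in seq_len(n)) {
    id <- sprintf("%s_%s_%03d", line, genotype, i)
    out <- genTrack(params, seed = seeds[i], subjectId = id,
                    genotype = genotype, line = line, condition = condition)
    tracks[[id]] <- out$track
    truths[[id]] <- out$truth
    alive[i] <- out$alive
  }
  list(tracks = tracks,
       truth = do.call(rbind, c(truths, list(make.row.names = FALSE))),
       alive = alive)
}
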