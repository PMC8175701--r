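#' @include AllClasses.R utils.R
NULL

#' LfpGenParams: synthetic LFP generator parameters
#'
#' Parameters of the ground-truth LFP generator. The trace is low-pass
#' filtered Gaussian noise of SD `noiseSdMv` plus injected biphasic sharp
#' transients (interictal-like, 3-8x noise SD, 10-99 ms) and multi-spike
#' bursts (ictal-like, 5-15x noise SD, 45-5090 ms) each followed by a
#' suppression stretch where the noise SD is multiplied by
#' `suppressionFactor`. Event counts are Poisson with the given rates.
#'
#' The wild-type defaults are calibrated to the screening cohort's printed
#' summaries: `ictalRatePer15Min = -log(1 - 0.147)` so that 14.7% of WT
#' epochs contain an ictal-like event, and `interictalRatePerMin = 0.16`
#' (2.4 per 15 min) so that the expected LFP score of a WT epoch is 0.66
#' (see the methods vignette). The baseline SD default of 0.05 mV places the
#' absolute voltage threshold range 0.15-0.25 mV at 3-5x SD, making absolute
#' and relative thresholds consistent.
#'
#' @slot sampleRateHz sampling rate (Hz), default 10000.
#' @slot durationS epoch length (s), default 900 (a 15 min epoch).
#' @slot noiseSdMv baseline noise SD sigma (mV), default 0.05.
#' @slot lowpassHz noise low-pass corner (Hz), default 1000.
#' @slot interictalRatePerMin Poisson rate of interictal-like transients.
#' @slot interictalAmpMult amplitude sampling range in multiples of sigma.
#' @slot interictalDurMs duration sampling range (ms), within \[10, 99\].
#' @slot ictalRatePer15Min Poisson mean count of ictal-like bursts per 15 min.
#' @slot ictalDurS burst duration sampling range (s), within \[0.045, 5.09\].
#' @slot ictalAmpMult burst amplitude range in multiples of sigma.
#' @slot ictalSpikeRateHz within-burst spike rate range (Hz).
#' @slot suppressionS post-ictal suppression duration range (s).
#' @slot suppressionFactor noise SD multiplier during suppression.
#' @export
setClass("LfpGenParams",
  representation(
    sampleRateHz = "numeric", durationS = "numeric", noiseSdMv = "numeric",
    lowpassHz = "numeric", interictalRatePerMin = "numeric",
    interictalAmpMult = "numeric", interictalDurMs = "numeric",
    ictalRatePer15Min = "numeric", ictalDurS = "numeric",
    ictalAmpMult = "numeric", ictalSpikeRateHz = "numeric",
    suppressionS = "numeric", suppressionFactor = "numeric"
  )
)

setValidity("LfpGenParams", function(object) {
  msg <- character()
  ranges <- list(interictalAmpMult = object@interictalAmpMult,
                 interictalDurMs = object@interictalDurMs,
                 ictalDurS = object@ictalDurS,
                 ictalAmpMult = object@ictalAmpMult,
                 ictalSpikeRateHz = object@ictalSpikeRateHz,
                 suppressionS = object@suppressionS)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2L || r[1L] > r[2L])
      msg <- c(msg, sprintf("%s must be an ordered range", nm))
  }
  if (object@noiseSdMv <= 0) msg <- c(msg, "noiseSdMv must be > 0")
  if (object@interictalDurMs[1L] < 10 || object@interictalDurMs[2L] > 99)
    msg <- c(msg, "interictalDurMs must lie within [10, 99] ms")
  if (object@ictalDurS[1L] < 0.045 || object@ictalDurS[2L] > 5.09)
    msg <- c(msg, "ictalDurS must lie within [0.045, 5.09] s")
  if (object@interictalRatePerMin < 0 || object@ictalRatePer15Min < 0)
    msg <- c(msg, "event rates must be >= 0")
  if (object@suppressionFactor <= 0 || object@suppressionFactor >= 1)
    msg <- c(msg, "suppressionFactor must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' @rdname LfpGenParams-class
#' @param sampleRateHz,durationS,noiseSdMv,lowpassHz,interictalRatePerMin,interictalAmpMult,interictalDurMs,ictalRatePer15Min,ictalDurS,ictalAmpMult,ictalSpikeRateHz,suppressionS,suppressionFactor see slots.
#' @return A validated `LfpGenParams`.
#' @export
lfpGenParams <- function(sampleRateHz = 10000, durationS = 900,
                         noiseSdMv = 0.05, lowpassHz = 1000,
                         interictalRatePerMin = 0.16,
                         interictalAmpMult = c(3, 8),
                         interictalDurMs = c(10, 99),
                         ictalRatePer15Min = -log(1 - 0.147),
                         ictalDurS = c(0.045, 5.09),
                         ictalAmpMult = c(5, 15),
                         ictalSpikeRateHz = c(5, 20),
                         suppressionS = c(2, 10),
                         suppressionFactor = 0.5) {
  new("LfpGenParams", sampleRateHz = sampleRateHz, durationS = durationS,
      noiseSdMv = noiseSdMv, lowpassHz = lowpassHz,
      interictalRatePerMin = interictalRatePerMin,
      interictalAmpMult = interictalAmpMult,
      interictalDurMs = interictalDurMs,
      ictalRatePer15Min = ictalRatePer15Min, ictalDurS = ictalDurS,
      ictalAmpMult = ictalAmpMult, ictalSpikeRateHz = ictalSpikeRateHz,
      suppressionS = suppressionS, suppressionFactor = suppressionFactor)
}

#' Epileptic-line generator preset
#'
#' Convenience preset with an elevated ictal burst rate and interictal rate,
#' emulating a mutant line with an unambiguous electrographic phenotype.
#'
#' @param ictalRatePer15Min mean ictal bursts per 15 min epoch (default 3).
#' @param interictalRatePerMin interictal rate per minute (default 2).
#' @param ... further overrides passed to [lfpGenParams()].
#' @return An [LfpGenParams-class].
#' @export
lfpGenParamsEpileptic <- function(ictalRatePer15Min = 3,
                                  interictalRatePerMin = 2, ...) {
  lfpGenParams(ictalRatePer15Min = ictalRatePer15Min,
               interictalRatePerMin = interictalRatePerMin, ...)
}

# Plateaued biphasic transient sampled at `rate`, peak |amplitude| = 1.
# Fast (~1.5 ms) cosine ramps flank two opposite-polarity plateaus, so the
# waveform's nominal support and its super-threshold extent coincide; the
# negative phase reaches 85% of the positive peak.
biphasicWave <- function(d, rate) {
  n <- max(4L, round(d * rate))
  tt <- (seq_len(n) - 0.5) / rate
  s <- 0.45 * d
  trap <- function(t0, t1) {
    L <- t1 - t0
    ramp <- min(0.0015, L / 3)
    w <- numeric(length(tt))
    inside <- tt >= t0 & tt <= t1
    u <- tt[inside]
    v <- rep(1, length(u))
    a <- (u - t0) < ramp
    v[a] <- 0.5 * (1 - cos(pi * (u[a] - t0) / ramp))
    b <- (t1 - u) < ramp
    v[b] <- pmin(v[b], 0.5 * (1 - cos(pi * (t1 - u[b]) / ramp)))
    w[inside] <- v
    w
  }
  trap(0, s) - 0.85 * trap(s, d)
}

# Multi-spike burst: biphasic transients spread from burst start to burst
# end at the drawn spike rate (at least two spikes), under unit peak.
# One randomly chosen spike carries the full amplitude so the burst's peak
# equals the drawn amplitude multiple.
ictalBurst <- function(d, rate, spikeRateHz) {
  n <- max(4L, round(d * rate))
  nsp <- max(2L, floor(d * spikeRateHz))
  sdur <- min(0.03, 0.9 * d / nsp)
  starts <- if (nsp == 1L) 0 else seq(0, d - sdur, length.out = nsp)
  w <- numeric(n)
  f <- stats::runif(nsp, 0.85, 1)
  f[sample.int(nsp, 1L)] <- 1
  pol <- sample(c(-1, 1), nsp, replace = TRUE)
  for (k in seq_len(nsp)) {
    sw <- biphasicWave(sdur, rate) * f[k] * pol[k]
    i0 <- round(starts[k] * rate)
    idx <- i0 + seq_along(sw)
    idx <- idx[idx <= n]
    w[idx] <- w[idx] + sw[seq_along(idx)]
  }
  w
}

# Low-pass filtered standard Gaussian noise rescaled to unit SD.
shapedNoise <- function(n, rate, lowpassHz) {
  x <- stats::rnorm(n)
  if (lowpassHz < rate / 2) {
    bf <- signal::butter(4, 2 * lowpassHz / rate)
    x <- .iir_filter(bf$b, bf$a, x)
    x <- x / stats::sd(x)
  }
  x
}

# Place non-overlapping event spans within [margin, total-margin], separated
# by at least `minGapS`, uniformly over all admissible configurations
# (stick-breaking: sorted uniforms over the free length). `spanS` holds each
# event's occupied span (event + trailing suppression for bursts). Returns
# start times aligned with `spanS`.
placeEvents <- function(spanS, totalS, minGapS = 0.35, margin = 0.5) {
  k <- length(spanS)
  if (k == 0L) return(numeric())
  lo <- margin
  hi <- totalS - margin
  free <- (hi - lo) - sum(spanS) - (k - 1) * minGapS
  if (free < 0)
    stopf("event load infeasible: %d events occupying %.1f s do not fit in %.1f s",
          k, sum(spanS), hi - lo, class = "seizescreen_infeasible_error")
  perm <- sample.int(k)
  u <- sort(stats::runif(k, 0, free))
  sp <- spanS[perm]
  st <- lo + u + c(0, cumsum(sp[-k] + minGapS))[seq_len(k)]
  starts <- numeric(k)
  starts[perm] <- st
  starts
}

#' Generate a synthetic LFP recording with ground truth
#'
#' Builds one epoch of low-pass-filtered Gaussian noise, injects
#' interictal-like sharp transients and ictal-like multi-spike bursts (each
#' burst followed by a suppression stretch of reduced noise), and returns the
#' recording together with a ground-truth annotation table listing every
#' injected event. Identical `(params, seed)` give bit-identical output.
#' Injected events are separated by at least 0.35 s so distinct events are
#' never merged by the detector, and the expected event load may not exceed
#' half the epoch.
#'
#' @param params an [LfpGenParams-class].
#' @param seed integer seed.
#' @param subjectId,genotype,line,condition metadata for the recording.
#' @return A list with elements `recording` ([LfpRecording-class]) and
#'   `truth` (data.frame with columns `subject_id,start_s,end_s,label,source`
#'   plus `amp_mult`; labels are `interictal` / `ictal`).
#' @examples
#' g <- genLfp(lfpGenParams(durationS = 30, interictalRatePerMin = 6,
#'                          ictalRatePer15Min = 0), seed = 7)
#' nrow(g$truth)
#' @export
genLfp <- function(params, seed, subjectId = "synth", genotype = "WT",
                   line = "synthetic", condition = "baseline") {
  stopifnot(is(params, "LfpGenParams"))
  validObject(params)
  withSeed(seed, {
    rate <- params@sampleRateHz
    n <- round(params@durationS * rate)
    sigma <- params@noiseSdMv
    nI <- stats::rpois(1L, params@interictalRatePerMin * params@durationS / 60)
    nII <- stats::rpois(1L, params@ictalRatePer15Min * params@durationS / 900)
    dI <- stats::runif(nI, params@interictalDurMs[1L], params@interictalDurMs[2L]) / 1000
    dII <- stats::runif(nII, params@ictalDurS[1L], params@ictalDurS[2L])
    supp <- stats::runif(nII, params@suppressionS[1L], params@suppressionS[2L])
    if (sum(dI) + sum(dII) > 0.5 * params@durationS)
      stopf("expected event time exceeds 50%% of the trace",
            class = "seizescreen_infeasible_error")
    spans <- c(dI, dII + supp)
    starts <- placeEvents(spans, params@durationS)
    noise <- shapedNoise(n, rate, params@lowpassHz) * sigma
    labels <- c(rep("interictal", nI), rep("ictal", nII))
    durs <- c(dI, dII)
    amps <- c(stats::runif(nI, params@interictalAmpMult[1L], params@interictalAmpMult[2L]),
              stats::runif(nII, params@ictalAmpMult[1L], params@ictalAmpMult[2L]))
    # suppression first, then event waveforms ride on the attenuated noise
    for (k in seq_len(nII)) {
      i0 <- round((starts[nI + k] + dII[k]) * rate) + 1L
      i1 <- min(n, round((starts[nI + k] + dII[k] + supp[k]) * rate))
      if (i0 <= i1) noise[i0:i1] <- noise[i0:i1] * params@suppressionFactor
    }
    v <- noise
    for (k in seq_along(starts)) {
      w <- if (labels[k] == "interictal")
        biphasicWave(durs[k], rate) * sample(c(-1, 1), 1L)
      else
        ictalBurst(durs[k], rate, stats::runif(1L, params@ictalSpikeRateHz[1L],
                                               params@ictalSpikeRateHz[2L]))
      i0 <- round(starts[k] * rate)
      idx <- i0 + seq_along(w)
      idx <- idx[idx >= 1L & idx <= n]
      v[idx] <- v[idx] + w[seq_along(idx)] * amps[k] * sigma
    }
    truth <- data.frame(subject_id = rep(subjectId, length(starts)),
                        start_s = starts, end_s = starts + durs,
                        label = labels, source = rep("ground_truth", length(starts)),
                        amp_mult = amps)
    truth <- truth[order(truth$start_s), , drop = FALSE]
    rownames(truth) <- NULL
    list(recording = lfpRecording(v, sampleRateHz = rate, subjectId = subjectId,
                                  genotype = genotype, line = line,
                                  condition = condition),
         truth = truth)
  })
}

#' Generate a blinded LFP screening cohort
#'
#' Draws recordings for each genotype group of one line from its own
#' generator parameters. Subject ids are coded (`<line>_<genotype>_<k>`) so
#' genotype can be joined post hoc, mimicking a blinded screen. The whole
#' cohort is returned in memory (a 15 min / 10 kHz recording is ~72 MB), so
#' for screen-scale cohorts prefer [runScreen()], which analyzes recordings
#' one at a time.
#'
#' @param lineSpec a named list: for each genotype (`WT`, `HET`, `MUT`) a list
#'   with elements `n` (group size) and `params` ([LfpGenParams-class]).
#' @param seed integer seed; each subject uses a child seed derived from it.
#' @param line line (gene) label.
#' @return A list with `recordings` (list of [LfpRecording-class]), `truth`
#'   (combined ground-truth table) and `genotypes` (subject-to-genotype map).
#' @export
genLfpCohort <- function(lineSpec, seed, line = "synthetic") {
  stopifnot(all(names(lineSpec) %in% GENOTYPES))
  total <- sum(vapply(lineSpec, function(g) g$n, numeric(1)))
  seeds <- childSeeds(seed, total)
  recordings <- list()
  truths <- list()
  genoRows <- list()
  i <- 0L
  for (g in names(lineSpec)) {
    for (k in seq_len(lineSpec[[g]]$n)) {
      i <- i + 1L
      id <- sprintf("%s_%s_%02d", line, g, k)
      out <- genLfp(lineSpec[[g]]$params, seed = seeds[i], subjectId = id,
                    genotype = g, line = line)
      recordings[[id]] <- out$recording
      truths[[id]] <- out$truth
      genoRows[[id]] <- data.frame(subject_id = id, line = line, genotype = g)
    }
  }
  list(recordings = recordings,
       truth = do.call(rbind, c(truths, list(make.row.names = FALSE))),
       genotypes = do.call(rbind, c(genoRows, list(make.row.names = FALSE))))
}
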