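# Shared fixtures and independent oracles, all built in code.

# Deterministic small recording: pure Gaussian noise at a given SD.
noiseRecording <- function(seed = 1, durationS = 10, rate = 1000, sd = 0.05) {
  set.seed(seed)
  lfpRecording(rnorm(durationS * rate, sd = sd), sampleRateHz = rate)
}

# Brute-force event detector: per-sample window recount, literal translation
# of the contract (leading window truncated at trace end, inclusive
# thresholds, gap merge), kept independent of the package implementation.
bruteForceDetect <- function(binary, rate, binS, windowS, rasterThreshold,
                             gapBins) {
  spb <- round(binS * rate)
  wlen <- round(windowS * rate)
  nbins <- length(binary) %/% spb
  score <- numeric(nbins)
  for (i in seq_len(nbins)) {
    s <- (i - 1) * spb + 1
    e <- min(s + wlen - 1, length(binary))
    score[i] <- sum(binary[s:e]) / (e - s + 1)
  }
  above <- score >= rasterThreshold
  events <- list()
  i <- 1
  while (i <= nbins) {
    if (above[i]) {
      j <- i
      while (j < nbins) {
        # extend across sub-threshold gaps of at most gapBins bins
        k <- j + 1
        while (k <= nbins && !above[k] && (k - j) <= gapBins) k <- k + 1
        if (k <= nbins && above[k]) j <- k else break
      }
      events[[length(events) + 1]] <- c(start = (i - 1) * binS, end = j * binS)
      i <- j + 1
    } else i <- i + 1
  }
  if (!length(events))
    return(data.frame(start_s = numeric(), end_s = numeric()))
  m <- do.call(rbind, events)
  data.frame(start_s = m[, "start"], end_s = m[, "end"])
}

# Brute-force movement scanner: explicit run-length walk with merge-then-
# filter, independent of segmentMovements().
bruteForceMovements <- function(speed, fps, thr = 0.9, minDur = 0.16,
                                mergeGap = 0.04) {
  above <- !is.na(speed) & speed >= thr
  runs <- list()
  i <- 1
  n <- length(above)
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1]) j <- j + 1
      runs[[length(runs) + 1]] <- c(i, j)
      i <- j + 1
    } else i <- i + 1
  }
  if (!length(runs)) return(data.frame(start_s = numeric(), end_s = numeric()))
  # merge gaps strictly shorter than mergeGap
  merged <- list(runs[[1]])
  for (r in runs[-1]) {
    last <- merged[[length(merged)]]
    gapS <- (r[1] - last[2] - 1) / fps
    if (gapS < mergeGap - 1e-12) merged[[length(merged)]] <- c(last[1], r[2])
    else merged[[length(merged) + 1]] <- r
  }
  keep <- Filter(function(r) (r[2] - r[1] + 1) / fps >= minDur - 1e-12, merged)
  if (!length(keep)) return(data.frame(start_s = numeric(), end_s = numeric()))
  m <- do.call(rbind, keep)
  data.frame(start_s = (m[, 1] - 1) / fps, end_s = m[, 2] / fps)
}

# Match detected intervals to truth intervals by overlap; returns per-truth
# index of the matching detection (NA if none).
matchEvents <- function(truth, detected) {
  vapply(seq_len(nrow(truth)), function(i) {
    hit <- which(detected$start_s < truth$end_s[i] &
                 detected$end_s > truth$start_s[i])
    if (length(hit)) hit[1L] else NA_integer_
  }, integer(1))
}
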