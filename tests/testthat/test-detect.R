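test_that("noise estimate is accurate and robust to large bursts", {
  # Monte-Carlo oracle: pure Gaussian noise of known SD
  set.seed(77)
  rec <- lfpRecording(rnorm(60 * 10000, sd = 0.05), sampleRateHz = 10000)
  expect_equal(estimateNoise(rec), 0.05, tolerance = 0.05)

  # robustness: one 5 s 8x burst must not bias the estimate
  v <- voltage(rec)
  v[100000:150000] <- v[100000:150000] + 0.4
  rec2 <- lfpRecording(v, sampleRateHz = 10000)
  expect_equal(estimateNoise(rec2), 0.05, tolerance = 0.05)

  expect_equal(estimateNoise(lfpRecording(rep(0.3, 5000), sampleRateHz = 1000)), 0)
  expect_error(estimateNoise(lfpRecording(rnorm(500), sampleRateHz = 1000)),
               class = "seizescreen_length_error")
})

test_that("binarization is inclusive at the threshold and median-centred", {
  v <- rep(0, 1000)
  v[c(100, 200)] <- c(0.2, -0.2)       # exactly +/- T
  v[300] <- 0.1999
  rec <- lfpRecording(v, sampleRateHz = 1000)
  cfg <- detectorConfig(useRelativeThreshold = FALSE, voltageThresholdMv = 0.2)
  b <- binarize(rec, cfg)
  expect_equal(which(b == 1L), c(100L, 200L))
  expect_length(b, 1000L)
  expect_equal(binarize(lfpRecording(rep(0, 100), sampleRateHz = 100), cfg),
               rep(0L, 100))
})

test_that("binarized active fraction matches the Gaussian tail", {
  set.seed(123)
  rec <- lfpRecording(rnorm(1e6, sd = 0.05), sampleRateHz = 10000)
  cfg <- detectorConfig(useRelativeThreshold = FALSE, voltageThresholdMv = 0.2)
  frac <- mean(binarize(rec, cfg))
  expect_equal(frac, 2 * pnorm(-4), tolerance = 0.35)   # ~6.3e-5
})

test_that("raster scores follow the leading-window definition", {
  cfg <- detectorConfig(windowS = 0.5)
  # 0.25 s solid block at the start of a 10 s trace at 10 kHz
  b <- integer(1e5); b[1:2500] <- 1L
  ras <- rasterScore(b, cfg, sampleRateHz = 10000)
  expect_equal(ras@score[1], 0.5)            # 2500 of 5000 samples
  expect_length(ras@score, 1000L)            # floor(duration / bin)
  expect_equal(rasterScore(rep(1L, 1e4), cfg, 10000)@score,
               rep(1, 100))
  expect_equal(rasterScore(integer(1e4), cfg, 10000)@score,
               rep(0, 100))
  # trailing windows truncate at the trace end instead of padding
  b2 <- integer(5500); b2[5001:5500] <- 1L
  r2 <- rasterScore(b2, detectorConfig(windowS = 0.5), 10000)
  expect_equal(r2@score[51], 1)              # window = last 500 samples only
})

test_that("event detection matches a brute-force recount on random instances", {
  set.seed(42)
  rate <- 500
  for (i in 1:200) {
    n <- sample(1000:3000, 1)
    b <- integer(n)
    for (k in seq_len(sample(1:6, 1))) {     # random activity clumps
      s <- sample(n - 100, 1)
      b[s:(s + sample(5:80, 1))] <- 1L
    }
    wS <- sample(c(0.01, 0.02, 0.05, 0.1), 1)
    cfg <- detectorConfig(windowS = wS,
                          rasterThreshold = sample(c(0.2, 0.3, 0.5), 1),
                          minEventGapBins = sample(c(0L, 1L, 3L, 25L), 1))
    ras <- rasterScore(b, cfg, sampleRateHz = rate)
    got <- detectEvents(ras, cfg)
    want <- bruteForceDetect(b, rate, cfg@binS, wS, cfg@rasterThreshold,
                             cfg@minEventGapBins)
    expect_equal(got$start_s, want$start_s)
    expect_equal(got$end_s, want$end_s)
  }
})

test_that("no super-threshold bin means no events", {
  cfg <- detectorConfig()
  ras <- rasterScore(integer(2000), cfg, 1000)
  expect_equal(nrow(detectEvents(ras, cfg)), 0L)
})

test_that("detection recovers injected bursts as sorted disjoint events", {
  p <- lfpGenParams(durationS = 30, interictalRatePerMin = 0,
                    ictalRatePer15Min = 0)
  g <- genLfp(p, seed = 8)
  v <- voltage(g$recording)
  # inject one 500 ms 8x burst, and a second one 5 s later
  burst <- seizescreen:::ictalBurst(0.5, 10000, 10) * 8 * 0.05
  v[100001:(100000 + length(burst))] <- v[100001:(100000 + length(burst))] + burst
  v[150001:(150000 + length(burst))] <- v[150001:(150000 + length(burst))] + burst
  rec <- lfpRecording(v, sampleRateHz = 10000)
  det <- detectLfp(rec)
  expect_equal(nrow(det$events), 2L)
  expect_true(all(diff(det$events$start_s) > 0))
  expect_true(all(det$events$start_s[-1] >= det$events$end_s[-2]))
  expect_equal(det$events$duration_s, c(0.5, 0.5), tolerance = 0.1)
  expect_equal(det$events$start_s, c(10, 15), tolerance = 0.05)
})

test_that("raising either threshold never increases total event duration", {
  g <- genLfp(lfpGenParams(durationS = 60, interictalRatePerMin = 8,
                           ictalRatePer15Min = 15), seed = 13)
  v <- voltage(g$recording)
  absdev <- abs(v - median(v))
  total <- function(vt, rt) {
    cfg <- detectorConfig(useRelativeThreshold = FALSE,
                          voltageThresholdMv = vt, rasterThreshold = rt)
    sum(detectEvents(rasterScore(as.integer(absdev >= vt), cfg, 10000),
                     cfg)$duration_s)
  }
  for (rt in c(0.2, 0.3, 0.4)) {
    tots <- vapply(c(0.15, 0.2, 0.25), function(vt) total(vt, rt), numeric(1))
    expect_true(all(diff(tots) <= 1e-12))
  }
  for (vt in c(0.15, 0.2)) {
    tots <- vapply(c(0.2, 0.3, 0.4), function(rt) total(vt, rt), numeric(1))
    expect_true(all(diff(tots) <= 1e-12))
  }
})

test_that("threshold tuning returns a fixed point with zero discrepancy", {
  g <- genLfp(lfpGenParams(durationS = 10, interictalRatePerMin = 42,
                           ictalRatePer15Min = 0), seed = 301)
  rec <- g$recording
  # manual marks = detector output at one grid point -> that point wins, ratio 0
  cfg0 <- detectorConfig(useRelativeThreshold = FALSE,
                         voltageThresholdMv = 0.2, rasterThreshold = 0.3)
  auto <- detectLfp(rec, cfg0)$events
  tuned <- tuneThresholds(rec, auto)
  expect_equal(attr(tuned, "ratio"), 0)
  # the winning point reproduces the reference total duration exactly;
  # among equivalent points ties go to the smallest voltage then raster
  grid <- attr(tuned, "grid")
  zero <- grid[grid$ratio == 0, ]
  expect_true(nrow(zero) >= 1)
  expect_equal(tuned@voltageThresholdMv, min(zero$voltage))
  best <- zero[zero$voltage == min(zero$voltage), ]
  expect_equal(tuned@rasterThreshold, min(best$raster))

  expect_error(tuneThresholds(rec, auto[0, ]), "empty")
})

test_that("per-recording event statistics are simple arithmetic", {
  rec <- lfpRecording(rnorm(15 * 60 * 100, sd = 0.05), sampleRateHz = 100)
  ev <- data.frame(start_s = seq(1, by = 30, length.out = 30))
  ev$end_s <- ev$start_s + 0.05
  ev$duration_s <- 0.05
  st <- eventStats(ev, rec)
  expect_equal(st$freq_per_min, 2.0)       # 30 events in 15 min
  expect_equal(st$mean_duration_s, 0.05)
  st0 <- eventStats(emptyEvents <- data.frame(start_s = numeric(),
                                              end_s = numeric(),
                                              duration_s = numeric()), rec)
  expect_equal(unlist(st0), c(n_events = 0, freq_per_min = 0,
                              mean_duration_s = 0, max_duration_s = 0))
})

test_that("event frequency tracks the generating Poisson rate", {
  lambda <- 6   # per minute
  p <- lfpGenParams(durationS = 120, interictalRatePerMin = lambda,
                    ictalRatePer15Min = 0)
  freqs <- vapply(1:8, function(s) {
    g <- genLfp(p, seed = 500 + s)
    det <- detectLfp(g$recording)
    eventStats(det$events, g$recording)$freq_per_min
  }, numeric(1))
  # mean of 8 x 2 min epochs: SE = sqrt(lambda / 16) ~ 0.6
  expect_equal(mean(freqs), lambda, tolerance = 0.35)
})
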