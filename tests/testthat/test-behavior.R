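test_that("speed computation is finite-difference arithmetic", {
  # straight line, 1 mm per frame at 25 fps -> 25 mm/s everywhere
  n <- 50
  tr <- swimTrack(seq_len(n), rep(0, n), fps = 25, arenaRadiusMm = 60)
  expect_equal(computeSpeed(tr), rep(25, n - 1))
  # stationary -> zeros
  tr0 <- swimTrack(rep(1, n), rep(1, n), fps = 25, arenaRadiusMm = 5)
  expect_equal(computeSpeed(tr0), rep(0, n - 1))
  # gap frames propagate NA into adjacent speed samples
  x <- as.numeric(seq_len(n)); x[10] <- NA
  trg <- swimTrack(x, rep(0, n), fps = 25, arenaRadiusMm = 60)
  sp <- computeSpeed(trg)
  expect_true(all(is.na(sp[9:10])))
  expect_false(anyNA(sp[-(9:10)]))
  expect_error(computeSpeed(swimTrack(NA_real_ * 1:5, 1:5 * NA_real_, fps = 25)),
               class = "seizescreen_quality_error")
})

test_that("movement segmentation applies threshold, merge and minimum rules", {
  cfg <- behaviorConfig()
  fps <- 100   # 10 ms frames make the merge/minimum arithmetic exact
  # constant sub-threshold speed -> nothing
  expect_equal(nrow(segmentMovements(rep(0.5, 500), fps, cfg)), 0L)
  # 2 mm/s sustained 200 ms -> one event of 0.2 s
  sp <- rep(0, 200); sp[51:70] <- 2
  ev <- segmentMovements(sp, fps, cfg)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$duration_s, 0.2)
  expect_equal(ev$max_speed_mm_s, 2)
  # two 100 ms runs separated by 20 ms -> merged into one 220 ms event
  sp <- rep(0, 300); sp[101:110] <- 2; sp[113:122] <- 3
  ev <- segmentMovements(sp, fps, cfg)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$duration_s, 0.22)
  expect_equal(ev$max_speed_mm_s, 3)
  # two 100 ms runs separated by 60 ms -> not merged, both below 160 ms
  sp <- rep(0, 300); sp[101:110] <- 2; sp[117:126] <- 2
  expect_equal(nrow(segmentMovements(sp, fps, cfg)), 0L)
  # a 40 ms gap is NOT merged (the rule is strictly < 40 ms)
  sp <- rep(0, 300); sp[101:120] <- 2; sp[125:144] <- 2
  expect_equal(nrow(segmentMovements(sp, fps, cfg)), 2L)
})

test_that("segmentation matches a brute-force scanner on random series", {
  set.seed(99)
  for (i in 1:200) {
    fps <- sample(c(25, 50, 100), 1)
    n <- sample(200:2000, 1)
    # random walk speeds hovering around the threshold produce rich run
    # structure
    sp <- abs(cumsum(rnorm(n, sd = 0.4)))
    if (i %% 3 == 0) sp[sample(n, n %/% 20)] <- NA
    got <- segmentMovements(sp, fps)
    want <- bruteForceMovements(sp, fps)
    expect_equal(got$start_s, want$start_s)
    expect_equal(got$end_s, want$end_s)
    if (nrow(got) > 1) {
      expect_true(all(diff(got$start_s) > 0))
      expect_true(all(got$start_s[-1] >= got$end_s[-nrow(got)]))
    }
  }
})

test_that("per-event distances and gaps conserve total path length", {
  g <- genTrack(trackGenParams(durationS = 120), seed = 55)
  sp <- computeSpeed(g$track)
  ev <- segmentMovements(sp, fps = 25)
  total <- sum(sp) / 25
  inEvents <- sum(ev$distance_mm)
  frames <- rep(TRUE, length(sp))
  for (k in seq_len(nrow(ev)))
    frames[(round(ev$start_s[k] * 25) + 1):round(ev$end_s[k] * 25)] <- FALSE
  expect_equal(inEvents + sum(sp[frames]) / 25, total, tolerance = 1e-9)
})

test_that("the data-driven cutoff is mean + 1.5 SD of control maxima", {
  expect_equal(deriveSpeedCutoff(c(8, 10, 12), minMovements = 3),
               10 + 1.5 * sd(c(8, 10, 12)))
  expect_equal(deriveSpeedCutoff(rep(7, 20)), 7)   # zero SD
  expect_error(deriveSpeedCutoff(c(8, 9)),
               class = "seizescreen_insufficient_data_error")
  # a synthetic control cohort stays below the convulsive 28 mm/s
  allmax <- unlist(lapply(1:10, function(s) {
    g <- genTrack(trackGenParams(durationS = 300), seed = 600 + s)
    segmentMovements(computeSpeed(g$track), fps = 25)$max_speed_mm_s
  }))
  expect_gt(length(allmax), 100)
  expect_lt(deriveSpeedCutoff(allmax), 28)
})

test_that("speed classes and the seizure-like flag follow the fixed rules", {
  ev <- data.frame(start_s = 1:3, end_s = 1:3 + c(1.2, 0.5, 2),
                   duration_s = c(1.2, 0.5, 2),
                   max_speed_mm_s = c(30, 30, 10), distance_mm = 1)
  out <- classifyMovements(ev)
  expect_equal(out$speed_class, c("high", "high", "low"))
  expect_equal(out$seizure_like, c(TRUE, FALSE, FALSE))
  # with a data-driven cutoff below 28, class and flag can disagree
  out2 <- classifyMovements(ev, cutoff = 15)
  expect_equal(out2$speed_class, c("high", "high", "low"))
  expect_equal(out2$seizure_like, out$seizure_like)
})

test_that("per-larva summaries respect the count hierarchy", {
  g <- genTrack(trackGenParams(durationS = 300, seizureRatePer15Min = 6),
                seed = 77)
  res <- analyzeTrack(g$track)
  s <- res$summary
  expect_lte(s$n_long_hse, s$n_hse)
  expect_lte(s$n_hse, s$n_movements)
  expect_equal(s$n_movements, nrow(res$events))
  expect_gte(s$max_velocity_mm_s, max(res$events$max_speed_mm_s))
  # no movement -> all zeros
  quiet <- analyzeTrack(genTrack(trackGenParams(durationS = 60,
                                                boutRatePerMin = 0),
                                 seed = 2)$track)
  expect_equal(quiet$summary$n_movements, 0L)
  expect_equal(quiet$summary$n_hse, 0L)
})

test_that("dose-response counts rise with dose and fall with late mortality", {
  countFor <- function(dose, exposure, seedBase, n = 12) {
    vapply(seq_len(n), function(i) {
      p <- trackGenParams(durationS = 300, dose = dose,
                          exposureMin = exposure)
      g <- genTrack(p, seed = seedBase + i)
      sum(analyzeTrack(g$track)$events$seizure_like)
    }, numeric(1))
  }
  rows <- list()
  for (dose in c(0, 5, 15)) for (win in c(5, 90))
    rows[[paste(dose, win)]] <- data.frame(
      dose = dose, window = win,
      n_seizure = countFor(dose, win, seedBase = dose * 1000 + win * 7))
  tab <- doseResponse(do.call(rbind, rows))
  early <- tab[tab$window == 5, ]
  expect_equal(early$mean_count[early$dose == 0], 0)
  expect_true(all(diff(early$mean_count[order(early$dose)]) >= 0))
  # mortality knock-down: high dose at long exposure yields fewer events
  late15 <- tab$mean_count[tab$dose == 15 & tab$window == 90]
  early15 <- tab$mean_count[tab$dose == 15 & tab$window == 5]
  expect_lt(late15, early15)
})
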