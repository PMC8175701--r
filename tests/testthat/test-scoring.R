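mkEvents <- function(mult, durMs, nSpikes = 1L) {
  data.frame(start_s = as.numeric(seq_along(mult)),
             end_s = seq_along(mult) + durMs / 1000,
             duration_s = durMs / 1000, peak_amp_mv = mult * 0.05,
             n_spikes = as.integer(rep_len(nSpikes, length(mult))))
}

test_that("event typing follows the amplitude/duration taxonomy", {
  sigma <- 0.05
  # 4x / 50 ms -> I;  6x multi-spike / 500 ms -> II;  2x -> 0
  ev <- classifyEvents(mkEvents(c(4, 6, 2), c(50, 500, 200),
                                c(1L, 5L, 1L)), sigma)
  expect_equal(as.character(ev$event_type), c("I", "II", "0"))
  # 6x / 60 ms lies in both duration ranges: type II takes precedence
  ev2 <- classifyEvents(mkEvents(6, 60, 3L), sigma)
  expect_equal(as.character(ev2$event_type), "II")
  # but a lone sharp wave (single spike) of the same size stays type I
  ev3 <- classifyEvents(mkEvents(6, 60, 1L), sigma)
  expect_equal(as.character(ev3$event_type), "I")
  # every event gets exactly one type
  set.seed(1)
  evR <- classifyEvents(mkEvents(runif(50, 1, 10), runif(50, 5, 6000),
                                 sample(1:6, 50, TRUE)), sigma)
  expect_false(anyNA(evR$event_type))
})

test_that("recording scores implement the 0/1/2 decision rule", {
  sigma <- 0.05
  expect_equal(scoreRecording(classifyEvents(mkEvents(numeric(), numeric()),
                                             sigma))$score, 0L)
  # 1 type II -> 2
  expect_equal(scoreRecording(classifyEvents(mkEvents(6, 500, 4L),
                                             sigma))$score, 2L)
  # 4 type I, no type II, min count 3 -> 1
  s <- scoreRecording(classifyEvents(mkEvents(rep(4, 4), rep(50, 4)), sigma))
  expect_equal(s$score, 1L)
  expect_equal(s$n_typeI, 4L)
  # 2 type I only -> 0
  expect_equal(scoreRecording(classifyEvents(mkEvents(rep(4, 2), rep(50, 2)),
                                             sigma))$score, 0L)
  # adding a type II event never decreases the score
  base <- classifyEvents(mkEvents(rep(4, 4), rep(50, 4)), sigma)
  plus <- rbind(base, classifyEvents(mkEvents(6, 500, 4L), sigma))
  expect_gte(scoreRecording(plus)$score, scoreRecording(base)$score)
})

test_that("post-ictal suppression is detected from the trace", {
  p <- lfpGenParams(durationS = 60, interictalRatePerMin = 0,
                    ictalRatePer15Min = 45, suppressionS = c(6, 10),
                    suppressionFactor = 0.35)
  s <- 17
  repeat { g <- genLfp(p, seed = s); if (nrow(g$truth) >= 1) break; s <- s + 1 }
  noiseSd <- 0.05   # generator sigma; see note in the annotation test below
  ev <- g$truth[1, ]
  expect_true(detectSuppression(g$recording, ev, noiseSdMv = noiseSd))
  # an interictal event is followed by normal noise
  p2 <- lfpGenParams(durationS = 60, interictalRatePerMin = 6,
                     ictalRatePer15Min = 0)
  s <- 18
  repeat { g2 <- genLfp(p2, seed = s); if (nrow(g2$truth) >= 1) break; s <- s + 1 }
  expect_false(detectSuppression(g2$recording, g2$truth[1, ],
                                 noiseSdMv = estimateNoise(g2$recording)))
  # event at the trace end: evaluated on the remainder, flagged partial
  res <- detectSuppression(g2$recording, data.frame(end_s = 58),
                           noiseSdMv = estimateNoise(g2$recording))
  expect_true(attr(res, "partial"))
})

test_that("a second-rater pass averages the two scores", {
  sigma <- 0.05
  ev <- classifyEvents(mkEvents(rep(4, 4), rep(50, 4)), sigma)  # score 1
  strict <- scoreConfig(typeIMinCountForScore1 = 6L)            # score 0
  s <- scoreRecording(ev, secondCfg = strict, noiseSdMv = sigma)
  expect_equal(s$score, 0.5)
  expect_equal(scoreRecording(ev)$score, 1L)
  expect_error(scoreRecording(ev, secondCfg = strict), "noiseSdMv")
})

test_that("suppression annotation adds the flag per event", {
  p <- lfpGenParams(durationS = 40, interictalRatePerMin = 0,
                    ictalRatePer15Min = 60, suppressionS = c(6, 10),
                    suppressionFactor = 0.35)
  s <- 19
  repeat { g <- genLfp(p, seed = s); if (nrow(g$truth) >= 1) break; s <- s + 1 }
  det <- detectLfp(g$recording)
  # the generator sigma is supplied directly: on a short trace this much
  # suppression would dominate the quietest-segment noise estimate
  ev <- annotateSuppression(g$recording, det$events, noiseSdMv = 0.05)
  expect_true("suppression_follows" %in% names(ev))
  expect_true(any(ev$suppression_follows))
})

test_that("line summaries aggregate scores and make the epilepsy call", {
  scores <- data.frame(subject_id = sprintf("s%d", 1:8),
                       score = c(2, 2, 1, 0, 0, 0, 1, 0),
                       n_typeI = 0L,
                       n_typeII = c(1L, 2L, 0L, 0L, 0L, 0L, 0L, 0L),
                       genotype = rep(c("MUT", "WT"), each = 4),
                       line = "geneA")
  ls_ <- summarizeLine(scores)
  mut <- ls_[ls_$genotype == "MUT", ]
  expect_equal(mut$mean_score, 1.25)
  expect_true(mut$epilepsy_call)
  expect_equal(mut$pct_typeII, 50)
  wt <- ls_[ls_$genotype == "WT", ]
  expect_equal(wt$mean_score, 0.25)
  expect_false(wt$epilepsy_call)

  # mean exactly 1.0 -> call true (inclusive threshold)
  sc1 <- data.frame(subject_id = "a", score = 1, n_typeI = 3L, n_typeII = 0L,
                    genotype = "MUT", line = "g")
  expect_true(summarizeLine(sc1)$epilepsy_call)
  # all-zero scores -> call false
  sc0 <- transform(sc1, score = 0)
  expect_false(summarizeLine(sc0)$epilepsy_call)
})

test_that("score-vs-percent-type-II regression reduces to OLS", {
  ls_ <- data.frame(pct_typeII = c(0, 50, 100), mean_score = c(1, 2, 3))
  fit <- regressScoreVsPctII(ls_)
  expect_equal(fit$r_squared, 1)       # collinear points
  expect_equal(fit$slope, 0.02)
  fit2 <- regressScoreVsPctII(data.frame(pct_typeII = c(10, 80),
                                         mean_score = c(0.3, 1.9)))
  expect_equal(fit2$r_squared, 1)      # two points fit exactly
})
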