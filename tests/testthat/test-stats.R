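test_that("pooled t reproduces the screen's printed degrees of freedom", {
  set.seed(1)
  r1 <- twoSampleT(rnorm(781), rnorm(190), method = "pooled")
  expect_identical(r1$df, 969)
  r2 <- twoSampleT(rnorm(56), rnorm(299), method = "pooled")
  expect_identical(r2$df, 353)
})

test_that("t statistics match the textbook formulas on random samples", {
  set.seed(7)
  for (i in 1:25) {
    x <- rnorm(sample(3:40, 1), mean = runif(1, -1, 1))
    y <- rnorm(sample(3:40, 1), sd = runif(1, 0.5, 2))
    n1 <- length(x); n2 <- length(y)
    # pooled formula oracle
    sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
    tPool <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    rp <- twoSampleT(x, y, "pooled")
    expect_equal(rp$t, tPool, tolerance = 1e-12)
    expect_equal(rp$p, 2 * pt(-abs(tPool), n1 + n2 - 2), tolerance = 1e-12)
    # Welch formula oracle, and Welch df never exceeds the pooled df
    se2 <- var(x) / n1 + var(y) / n2
    dfW <- se2^2 / ((var(x) / n1)^2 / (n1 - 1) + (var(y) / n2)^2 / (n2 - 1))
    rw <- twoSampleT(x, y, "welch")
    expect_equal(rw$t, (mean(x) - mean(y)) / sqrt(se2), tolerance = 1e-12)
    expect_equal(rw$df, dfW, tolerance = 1e-9)
    expect_lte(rw$df, n1 + n2 - 2 + 1e-9)
  }
})

test_that("degenerate zero-variance inputs are handled explicitly", {
  expect_equal(twoSampleT(rep(1, 5), rep(1, 9))$t, 0)
  inf <- twoSampleT(rep(2, 5), rep(1, 9))
  expect_true(is.infinite(inf$t) && inf$t > 0)
  expect_true(inf$degenerate)
  mw <- twoSampleT(1:10, 5:14, method = "mannwhitney")
  expect_true(is.na(mw$t) && !is.na(mw$p))
})

test_that("linear regression matches the normal-equations oracle", {
  x <- c(1, 2, 3, 4)
  fit <- linearFit(x, 2 * x + 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r_squared, 1)
  cfit <- linearFit(x, rep(3, 4))
  expect_equal(cfit$slope, 0)
  expect_equal(cfit$r_squared, 0)
  set.seed(5)
  for (i in 1:20) {
    xx <- rnorm(sample(3:30, 1))
    yy <- 0.5 * xx + rnorm(length(xx))
    f <- linearFit(xx, yy)
    X <- cbind(1, xx)
    beta <- solve(t(X) %*% X, t(X) %*% yy)     # normal equations
    expect_equal(f$intercept, beta[1], tolerance = 1e-10)
    expect_equal(f$slope, beta[2], tolerance = 1e-10)
    res <- yy - X %*% beta
    expect_equal(f$r_squared, 1 - sum(res^2) / sum((yy - mean(yy))^2),
                 tolerance = 1e-10)
  }
})

test_that("Kaplan-Meier matches hand-computed worked examples", {
  # no censoring, deaths at 8, 8, 9, 10 dpf
  km <- kmEstimate(data.frame(time_dpf = c(8, 8, 9, 10), event = TRUE))
  expect_equal(km$time, c(8, 9, 10))
  expect_equal(km$surv, c(0.5, 0.25, 0))
  expect_equal(km$median_dpf, 8)
  # half die at 8, half censored at 13 -> survival 0.5 after 8, median 8
  km2 <- kmEstimate(data.frame(time_dpf = c(8, 8, 13, 13),
                               event = c(TRUE, TRUE, FALSE, FALSE)))
  expect_equal(km2$surv[km2$time == 8], 0.5)
  expect_equal(km2$median_dpf, 8)
  # all censored -> flat at 1, median undefined
  km3 <- kmEstimate(data.frame(time_dpf = rep(13, 6), event = FALSE))
  expect_true(all(km3$surv == 1))
  expect_true(is.na(km3$median_dpf))
  # without censoring KM equals the empirical survival function
  set.seed(3)
  tt <- sample(5:15, 30, replace = TRUE)
  km4 <- kmEstimate(data.frame(time_dpf = tt, event = TRUE))
  for (j in seq_along(km4$time))
    expect_equal(km4$surv[j], mean(tt > km4$time[j]))
})

test_that("log-rank matches a hand-computed observed/expected table", {
  # A: deaths at 1, 2, censored 3; B: deaths at 2, 4, censored 5.
  # Death times 1, 2, 4 give E_A = 0.5 + 0.8 + 0 = 1.3, O_A = 2,
  # V = 0.25 + 0.36 + 0 = 0.61, chi-square = 0.7^2 / 0.61.
  rec <- data.frame(time_dpf = c(1, 2, 3, 2, 4, 5),
                    event = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE))
  grp <- rep(c("A", "B"), each = 3)
  lr <- logrankTest(rec, grp)
  expect_equal(lr$chisq, 0.7^2 / 0.61, tolerance = 1e-10)
  expect_equal(lr$df, 1L)
  expect_equal(unname(lr$observed), c(2, 2))
  expect_equal(unname(lr$expected), c(1.3, 2.7), tolerance = 1e-10)
  # invariant under swapping the group labels
  lr2 <- logrankTest(rec, rev(grp))
  expect_equal(lr2$chisq, lr$chisq)
  # identical groups -> statistic ~ 0
  rec2 <- data.frame(time_dpf = rep(c(8, 9, 10), 2), event = TRUE)
  expect_lt(logrankTest(rec2, rep(c("A", "B"), each = 3))$chisq, 1e-10)
})

test_that("log-rank separates generator medians 8 vs 12 dpf", {
  hits <- vapply(1:20, function(s) {
    g <- data.frame(genotype = c("WT", "MUT"), n = c(50, 50),
                    median_dpf = c(12, 8))
    recs <- genSurvival(g, seed = 7000 + s)
    logrankTest(recs)$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("homology scores average identity and tool support", {
  expect_equal(homologyScore(100, 12)$score, 100)
  expect_true(homologyScore(100, 12)$include)
  expect_equal(homologyScore(80, 9)$score, 77.5)      # (80 + 75) / 2
  expect_true(homologyScore(80, 9)$include)
  expect_equal(homologyScore(50, 6)$score, 50)
  expect_false(homologyScore(50, 6)$include)
  # a score of exactly 65 is excluded (strict > 65)
  at65 <- homologyScore(60, 7, nTools = 10)           # (60 + 70) / 2 = 65
  expect_equal(at65$score, 65)
  expect_false(at65$include)
  expect_error(homologyScore(50, 13), "diopt_count")
  # bounded, symmetric after scaling, monotone in each argument
  set.seed(11)
  pct <- runif(40, 0, 100); cnt <- sample(0:12, 40, TRUE)
  sc <- homologyScore(pct, cnt)$score
  expect_true(all(sc >= 0 & sc <= 100))
  expect_equal(homologyScore(cnt / 12 * 100, round(pct / 100 * 12))$score,
               homologyScore(round(pct / 100 * 12) / 12 * 100, cnt)$score)
  expect_true(all(diff(homologyScore(sort(pct), 6)$score) >= 0))
  expect_true(all(diff(homologyScore(50, 0:12)$score) >= 0))
})
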