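#' @include utils.R
NULL

#' Two-sample comparison
#'
#' Pooled-variance or Welch two-sample t test (two-sided), or a Mann-Whitney
#' U test. With the pooled method the degrees of freedom are exactly
#' `n1 + n2 - 2`; zero pooled variance gives `t = 0` for equal means and a
#' flagged infinite statistic for unequal means.
#'
#' @param x1,x2 numeric samples (each n >= 2).
#' @param method `"pooled"` (default), `"welch"` or `"mannwhitney"`.
#' @return list of class `TwoSampleResult`: `t, df, p, mean1, mean2, sem1,
#'   sem2, n1, n2, method` (for Mann-Whitney, `t` is `NA` and `w` holds the
#'   U statistic).
#' @examples
#' r <- twoSampleT(rnorm(56), rnorm(299))
#' r$df   # 353
#' @export
twoSampleT <- function(x1, x2, method = c("pooled", "welch", "mannwhitney")) {
  method <- match.arg(method)
  n1 <- length(x1); n2 <- length(x2)
  if (n1 < 2L || n2 < 2L) stopf("both samples need n >= 2")
  out <- list(mean1 = mean(x1), mean2 = mean(x2),
              sem1 = sem(x1), sem2 = sem(x2), n1 = n1, n2 = n2,
              method = method)
  if (method == "mannwhitney") {
    wt <- stats::wilcox.test(x1, x2, exact = FALSE)
    out <- c(out, list(t = NA_real_, df = NA_real_, w = unname(wt$statistic),
                       p = wt$p.value))
  } else if (stats::var(x1) == 0 && stats::var(x2) == 0) {
    equal <- isTRUE(all.equal(mean(x1), mean(x2)))
    out <- c(out, list(
      t = if (equal) 0 else sign(mean(x1) - mean(x2)) * Inf,
      df = if (method == "pooled") n1 + n2 - 2 else NA_real_,
      p = if (equal) 1 else 0, degenerate = TRUE))
  } else {
    tt <- stats::t.test(x1, x2, var.equal = (method == "pooled"))
    out <- c(out, list(t = unname(tt$statistic), df = unname(tt$parameter),
                       p = tt$p.value))
  }
  class(out) <- "TwoSampleResult"
  out
}

#' @export
print.TwoSampleResult <- function(x, ...) {
  cat(sprintf("Two-sample comparison (%s): t = %.4g, df = %.4g, p = %.4g\n",
              x$method, x$t, x$df, x$p))
  cat(sprintf("  group 1: mean %.4g +/- %.3g SEM (n = %d)\n", x$mean1, x$sem1, x$n1))
  cat(sprintf("  group 2: mean %.4g +/- %.3g SEM (n = %d)\n", x$mean2, x$sem2, x$n2))
  invisible(x)
}

#' Simple linear regression
#'
#' Ordinary least squares of `y` on `x` with `R^2 = 1 - SSres/SStot` and the
#' two-sided p value for a non-zero slope. A constant `y` gives slope 0 and
#' `R^2 = 0`.
#'
#' @param x,y numeric vectors of equal length (n >= 2).
#' @return list: `slope, intercept, r_squared, p_slope, n`.
#' @export
linearFit <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (stats::var(y) == 0)
    return(list(slope = 0, intercept = y[1L], r_squared = 0,
                p_slope = NA_real_, n = length(x)))
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))   # perfect fits are legitimate here
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = sm$r.squared,
       p_slope = if (nrow(sm$coefficients) > 1L) sm$coefficients[2L, 4L] else NA_real_,
       n = length(x))
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator with right censoring. The median survival is the
#' earliest time at which the survival curve drops to 0.5 or below
#' (`NA` when the curve never reaches 0.5).
#'
#' @param records survival data.frame with `time_dpf` and logical `event`.
#' @return list of class `KmCurve`: `time`, `surv`, `n_risk`, `n_event`,
#'   `median_dpf`, `n`.
#' @examples
#' rec <- data.frame(time_dpf = c(8, 8, 9, 10), event = TRUE)
#' kmEstimate(rec)$median_dpf   # 8
#' @export
kmEstimate <- function(records) {
  stopifnot(all(c("time_dpf", "event") %in% names(records)))
  fit <- survival::survfit(survival::Surv(records$time_dpf, records$event) ~ 1)
  med <- if (any(fit$surv <= 0.5)) fit$time[which(fit$surv <= 0.5)[1L]] else NA_real_
  out <- list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
              n_event = fit$n.event, median_dpf = med, n = nrow(records))
  class(out) <- "KmCurve"
  out
}

#' @export
print.KmCurve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, %d deaths, median = %s dpf\n",
              x$n, sum(x$n_event), format(x$median_dpf)))
  invisible(x)
}

#' Log-rank test across groups
#'
#' Standard (Mantel-Haenszel) log-rank test over two or more groups,
#' `df = groups - 1`.
#'
#' @param records survival data.frame with `time_dpf` and logical `event`.
#' @param group group labels, one per record (defaults to `records$genotype`).
#' @return list: `chisq, df, p`, plus the per-group observed and expected
#'   death counts.
#' @export
logrankTest <- function(records, group = records$genotype) {
  group <- factor(group)
  if (nlevels(group) < 2L) stopf("log-rank needs at least 2 groups")
  sd_ <- survival::survdiff(
    survival::Surv(records$time_dpf, records$event) ~ group)
  df <- nlevels(group) - 1L
  list(chisq = unname(sd_$chisq), df = df,
       p = stats::pchisq(sd_$chisq, df, lower.tail = FALSE),
       observed = sd_$obs, expected = sd_$exp)
}

#' Gene-orthology homology score
#'
#' The homology score of a human-zebrafish gene pairing is the mean of the
#' percent protein identity and the ortholog-tool support expressed as a
#' percentage (`100 * diopt_count / n_tools`, with 12 prediction tools by
#' default). Genes scoring strictly above 65 pass the inclusion gate.
#'
#' @param pctIdentity percent protein identity, in \[0, 100\].
#' @param dioptCount number of ortholog-prediction tools supporting the pair.
#' @param nTools total number of prediction tools (default 12).
#' @return data.frame with `score` (in \[0, 100\]) and logical `include`
#'   (`score > 65`).
#' @examples
#' homologyScore(80, 9)   # (80 + 75) / 2 = 77.5, included
#' @export
homologyScore <- function(pctIdentity, dioptCount, nTools = 12L) {
  k <- max(length(pctIdentity), length(dioptCount))
  pctIdentity <- rep_len(pctIdentity, k)
  dioptCount <- rep_len(dioptCount, k)
  nTools <- rep_len(nTools, k)
  if (any(pctIdentity < 0 | pctIdentity > 100))
    stopf("pct_identity must lie in [0, 100]")
  if (any(dioptCount < 0 | dioptCount > nTools))
    stopf("diopt_count must lie in [0, n_tools]")
  score <- (pctIdentity + 100 * dioptCount / nTools) / 2
  data.frame(score = score, include = score > 65)
}
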