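#' @include utils.R
NULL

#' Generate a synthetic survival cohort
#'
#' Death times are drawn per group from a Weibull distribution parameterised
#' by its median (`scale = median / log(2)^(1/shape)`), rounded up to the
#' nearest half day (larvae are checked twice daily), and right-censored at
#' `censorDpf` for subjects still alive then.
#'
#' @param groups data.frame with one row per group and columns `genotype`,
#'   `n`, `median_dpf`, plus optional `line`, `treatment` and `shape`
#'   (Weibull shape, default 12 — a steep larval die-off).
#' @param censorDpf end of observation in days post fertilization (default 13).
#' @param seed integer seed.
#' @return A survival data.frame with columns
#'   `subject_id,line,genotype,time_dpf,event,treatment`.
#' @examples
#' g <- data.frame(genotype = c("WT", "MUT"), n = c(20, 20),
#'                 median_dpf = c(12, 8))
#' recs <- genSurvival(g, seed = 1)
#' table(recs$genotype, recs$event)
#' @export
genSurvival <- function(groups, censorDpf = 13, seed = 1L) {
  stopifnot(all(c("genotype", "n", "median_dpf") %in% names(groups)))
  if (is.null(groups$shape)) groups$shape <- 12
  if (is.null(groups$line)) groups$line <- "synthetic"
  if (is.null(groups$treatment)) groups$treatment <- "vehicle"
  withSeed(seed, {
    rows <- lapply(seq_len(nrow(groups)), function(i) {
      g <- groups[i, ]
      scale <- g$median_dpf / log(2)^(1 / g$shape)
      death <- ceiling(stats::rweibull(g$n, shape = g$shape, scale = scale) * 2) / 2
      death <- pmax(death, 0.5)
      censored <- death > censorDpf
      data.frame(
        subject_id = sprintf("%s_%s_%s_%03d", g$line, g$genotype, g$treatment,
                             seq_len(g$n)),
        line = g$line, genotype = g$genotype,
        time_dpf = ifelse(censored, censorDpf, death),
        event = !censored, treatment = g$treatment)
    })
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })
}
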