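#' @include AllClasses.R utils.R
NULL

#' Run the full electrophysiology screen end-to-end
#'
#' Generates (or ingests) a cohort of LFP recordings, runs detection and type
#' classification on coded subject ids, scores every epoch on the 0/1/2
#' scale, joins genotypes last (emulating the blinded, post hoc genotyping
#' workflow) and aggregates per-line summaries with the epilepsy call. All
#' randomness flows from the single seed; a rerun with identical inputs
#' gives a byte-identical report.
#'
#' @param lines either a generator specification — a named list mapping line
#'   name to a `lineSpec` as in [genLfpCohort()] — or a directory containing
#'   `lfp_<subject>.csv` traces and a `genotypes.csv`
#'   (`subject_id,line,genotype`) table. Subjects without a genotype entry
#'   are excluded and logged.
#' @param config a [PipelineConfig-class].
#' @param seed integer seed overriding `config@seed` (optional).
#' @param outDir optional directory; when given, intermediate CSVs
#'   (`events.csv`, `scores.csv`, `line_summary.csv`, `report_meta.csv`) are
#'   written there.
#' @return list of class `ScreenReport`: `scores` (per recording),
#'   `lineSummary` (per line x genotype with epilepsy call), `eventSummary`
#'   (per line x genotype interictal/ictal frequency and duration means),
#'   `events` (all classified events), `excluded`, and `meta`
#'   (seed, config hash, package version).
#' @examples
#' \donttest{
#' spec <- list(
#'   geneA = list(MUT = list(n = 4, params = lfpGenParamsEpileptic(durationS = 60)),
#'                WT  = list(n = 4, params = lfpGenParams(durationS = 60))),
#'   geneB = list(MUT = list(n = 4, params = lfpGenParams(durationS = 60)),
#'                WT  = list(n = 4, params = lfpGenParams(durationS = 60))))
#' rep <- runScreen(spec, seed = 42)
#' rep$lineSummary
#' }
#' @export
runScreen <- function(lines, config = pipelineConfig(), seed = NULL,
                      outDir = NULL) {
  seed <- as.integer(seed %||% config@seed)
  det <- config@detector
  sco <- config@scorer
  # recordings are analyzed one at a time (blind, on coded ids) and
  # discarded immediately: a 15 min / 10 kHz cohort never sits in memory
  scoreRows <- list()
  eventRows <- list()
  epochMin <- numeric()
  analyzeOne <- function(id, rec) {
    dres <- detectLfp(rec, det)
    ev <- classifyEvents(dres$events, dres$noiseSdMv, sco)
    scoreRows[[id]] <<- scoreRecording(ev, sco, subjectId = id)
    if (nrow(ev)) eventRows[[id]] <<- cbind(subject_id = id, ev)
    epochMin[[id]] <<- durationS(rec) / 60
  }
  if (is.character(lines) && length(lines) == 1L) {
    paths <- list.files(lines, pattern = "^lfp_.*\\.csv$", full.names = TRUE)
    if (!length(paths)) stopf("no lfp_*.csv traces found in '%s'", lines,
                              class = "seizescreen_empty_input_error")
    genoPath <- file.path(lines, "genotypes.csv")
    genotypes <- if (file.exists(genoPath))
      utils::read.csv(genoPath, colClasses = c(subject_id = "character"))
    else data.frame(subject_id = character(), line = character(),
                    genotype = character())
    for (p in paths) {
      id <- sub("^lfp_(.*)\\.csv$", "\\1", basename(p))
      analyzeOne(id, readLfp(p, metadata = list(subject_id = id)))
    }
  } else {
    if (!length(lines)) stopf("empty generator specification",
                              class = "seizescreen_empty_input_error")
    lineSeeds <- childSeeds(seed, length(lines))
    genoList <- list()
    for (j in seq_along(lines)) {
      lineName <- names(lines)[j]
      spec <- lines[[j]]
      total <- sum(vapply(spec, function(g) g$n, numeric(1)))
      subjSeeds <- childSeeds(lineSeeds[j], total)
      i <- 0L
      rows <- list()
      for (g in names(spec)) {
        for (k in seq_len(spec[[g]]$n)) {
          i <- i + 1L
          id <- sprintf("%s_%s_%02d", lineName, g, k)
          out <- genLfp(spec[[g]]$params, seed = subjSeeds[i], subjectId = id,
                        genotype = g, line = lineName)
          analyzeOne(id, out$recording)
          rows[[id]] <- data.frame(subject_id = id, line = lineName,
                                   genotype = g)
        }
      }
      genoList[[j]] <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    }
    genotypes <- do.call(rbind, genoList)
  }
  scores <- do.call(rbind, c(scoreRows, list(make.row.names = FALSE)))
  events <- if (length(eventRows))
    do.call(rbind, c(eventRows, list(make.row.names = FALSE)))
  else cbind(subject_id = character(), emptyEvents(), event_type = character())
  # un-blind: join genotypes last
  merged <- merge(scores, genotypes, by = "subject_id", all.x = TRUE)
  excluded <- merged$subject_id[is.na(merged$genotype)]
  merged <- merged[!is.na(merged$genotype), , drop = FALSE]
  merged <- merged[order(merged$subject_id), , drop = FALSE]
  lineSummary <- summarizeLine(merged, sco)
  # per line x genotype event frequency/duration summaries
  events2 <- merge(events, genotypes, by = "subject_id", all.x = TRUE)
  epochMin <- unlist(epochMin)
  evRows <- list()
  for (lab in c("I", "II")) {
    sub <- events2[!is.na(events2$genotype) & events2$event_type == lab, , drop = FALSE]
    key <- interaction(merged$line, merged$genotype, drop = TRUE)
    for (k in levels(key)) {
      ids <- merged$subject_id[key == k]
      se <- sub[sub$subject_id %in% ids, , drop = FALSE]
      evRows[[paste(lab, k)]] <- data.frame(
        line = merged$line[key == k][1L],
        genotype = merged$genotype[key == k][1L],
        event_type = lab,
        n_events = nrow(se),
        freq_per_min = nrow(se) / sum(epochMin[ids]),
        mean_duration_s = if (nrow(se)) mean(se$duration_s) else 0)
    }
  }
  eventSummary <- do.call(rbind, c(evRows, list(make.row.names = FALSE)))
  cfgHash <- configHash(config)
  report <- list(scores = merged, lineSummary = lineSummary,
                 eventSummary = eventSummary, events = events2,
                 excluded = excluded,
                 meta = data.frame(seed = seed, config_hash = cfgHash,
                                   version = as.character(utils::packageVersion("seizescreen")),
                                   n_subjects = length(epochMin),
                                   n_scored = nrow(merged),
                                   n_excluded = length(excluded)))
  class(report) <- "ScreenReport"
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(report$events, file.path(outDir, "events.csv"), row.names = FALSE)
    utils::write.csv(report$scores, file.path(outDir, "scores.csv"), row.names = FALSE)
    utils::write.csv(report$lineSummary, file.path(outDir, "line_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(report$meta, file.path(outDir, "report_meta.csv"),
                     row.names = FALSE)
  }
  report
}

# Stable fingerprint of a configuration: md5 of its deparsed slot values.
configHash <- function(config) {
  txt <- paste(utils::capture.output({
    for (cls in c("detector", "scorer", "behavior")) {
      obj <- slot(config, cls)
      for (s in slotNames(obj)) cat(cls, s, format(slot(obj, s), digits = 15), "\n")
    }
  }), collapse = "\n")
  tf <- tempfile()
  writeLines(txt, tf)
  on.exit(unlink(tf))
  unname(tools::md5sum(tf))
}

#' @export
print.ScreenReport <- function(x, ...) {
  cat(sprintf("ScreenReport: %d subjects scored (%d excluded), seed %d\n",
              x$meta$n_scored, x$meta$n_excluded, x$meta$seed))
  print(x$lineSummary)
  invisible(x)
}

#' Heatmap-style table of mean LFP scores
#'
#' Lines x genotypes matrix of mean scores, ranked from the highest
#' homozygote (MUT) score to the lowest; ties break alphabetically by line.
#'
#' @param report a `ScreenReport` from [runScreen()].
#' @return numeric matrix with lines as rows (ranked) and genotypes as
#'   columns.
#' @export
makeHeatmapTable <- function(report) {
  ls_ <- report$lineSummary
  lines <- sort(unique(ls_$line))
  genos <- intersect(c("MUT", "HET", "WT", "unknown"), unique(ls_$genotype))
  m <- matrix(NA_real_, nrow = length(lines), ncol = length(genos),
              dimnames = list(lines, genos))
  for (i in seq_len(nrow(ls_)))
    m[ls_$line[i], ls_$genotype[i]] <- ls_$mean_score[i]
  rank <- if ("MUT" %in% colnames(m)) m[, "MUT"] else m[, 1L]
  rank[is.na(rank)] <- -Inf
  m[order(-rank, rownames(m)), , drop = FALSE]
}
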