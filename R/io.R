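#' @include AllClasses.R
NULL

## File formats are plain delimited text so that fixtures and results remain
## diffable and language-neutral:
##   LFP trace:  CSV, header time_s,voltage_mv (or voltage_mv alone with a
##               '# sample_rate_hz: <hz>' comment line)
##   Track:      CSV, header frame,time_s,x_mm,y_mm (empty cells = undetected)
##   Events:     CSV, header subject_id,start_s,end_s,label,source
##   Survival:   CSV, header subject_id,line,genotype,time_dpf,event,treatment
##   Config:     YAML with sections detector / scorer / behavior and a seed

#' Read an LFP trace from a delimited text file
#'
#' Accepts a two-column `time_s,voltage_mv` table with a one-line header, or a
#' single-column `voltage_mv` variant whose sampling rate is given in a
#' `# sample_rate_hz: <hz>` comment line. A time column must be uniform to
#' within 1e-6 s; it is then discarded in favor of the derived sampling rate.
#'
#' @param path file path.
#' @param metadata optional named list of overrides (`subject_id`, `genotype`,
#'   `line`, `condition`, `sample_rate_hz`).
#' @return An [LfpRecording-class].
#' @seealso [writeLfp()]
#' @export
readLfp <- function(path, metadata = list()) {
  header <- readLines(path, n = 20L)
  comment <- grep("^#", header, value = TRUE)
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#", colClasses = "numeric"),
    warning = function(w) stopf("parse error reading '%s': %s", path, conditionMessage(w)),
    error = function(e) NULL)
  if (is.null(df)) {
    raw <- utils::read.csv(path, comment.char = "#", colClasses = "character")
    for (j in seq_along(raw)) {
      bad <- which(is.na(suppressWarnings(as.numeric(raw[[j]]))) & nzchar(raw[[j]]))
      if (length(bad))
        stopf("parse error in '%s': non-numeric cell in column '%s', row %d",
              path, names(raw)[j], bad[1L])
    }
    stopf("parse error reading '%s'", path)
  }
  if (anyNA(df))
    stopf("parse error in '%s': non-numeric or empty cell at row %d",
          path, which(rowSums(is.na(df)) > 0)[1L])
  if (ncol(df) == 2L && all(c("time_s", "voltage_mv") %in% names(df))) {
    tm <- df$time_s
    if (length(tm) < 2L) {
      rate <- metadata$sample_rate_hz %||% 10000
    } else {
      dt <- diff(tm)
      step <- stats::median(dt)
      bad <- which(abs(dt - step) > 1e-6)
      if (length(bad))
        stopf("format error in '%s': non-uniform time step at row %d (dt = %g s, expected %g s)",
              path, bad[1L] + 1L, dt[bad[1L]], step)
      rate <- 1 / step
    }
    v <- df$voltage_mv
  } else if ("voltage_mv" %in% names(df)) {
    rateLine <- grep("sample_rate_hz", comment, value = TRUE)
    rate <- if (length(rateLine))
      as.numeric(sub(".*sample_rate_hz:\\s*", "", rateLine[1L]))
    else metadata$sample_rate_hz %||% NULL
    if (is.null(rate) || is.na(rate))
      stopf("format error in '%s': single-column trace needs a '# sample_rate_hz:' header",
            path)
    v <- df$voltage_mv
  } else {
    stopf("format error in '%s': expected columns time_s,voltage_mv", path)
  }
  lfpRecording(v, sampleRateHz = metadata$sample_rate_hz %||% rate,
               subjectId = metadata$subject_id %||% "subject",
               genotype = metadata$genotype %||% "unknown",
               line = metadata$line %||% "unknown",
               condition = metadata$condition %||% "baseline")
}

#' Write an LFP trace as CSV
#'
#' Emits a deterministic two-column `time_s,voltage_mv` file (times to 1e-6 s,
#' voltages to 1e-9 mV), so that a write/read round trip reproduces the trace
#' to within 1e-9 mV.
#'
#' @param rec an [LfpRecording-class]; must hold at least one sample.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeLfp <- function(rec, path) {
  stopifnot(is(rec, "LfpRecording"))
  v <- voltage(rec)
  if (length(v) == 0L) stopf("cannot write a zero-sample recording")
  tm <- (seq_along(v) - 1) / sampleRate(rec)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("time_s,voltage_mv", con)
  writeLines(sprintf("%.6f,%.9f", tm, v), con)
  invisible(path)
}

#' Read a swim trajectory
#'
#' Expects columns `frame,time_s,x_mm,y_mm`; empty position cells mark frames
#' where the subject was not detected. Gaps of at most `maxInterpFrames`
#' frames are filled by linear interpolation; longer gaps are kept as `NA`,
#' logged in the track's `gaps` slot, and excluded from speed computation.
#'
#' @param path file path.
#' @param metadata optional named list of overrides (as in [readLfp()], plus
#'   `arena_radius_mm`).
#' @param maxInterpFrames longest gap filled by interpolation (default 5).
#' @return A [SwimTrack-class].
#' @export
readTrack <- function(path, metadata = list(), maxInterpFrames = 5L) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("frame", "time_s", "x_mm", "y_mm")
  if (!all(need %in% names(df)))
    stopf("format error in '%s': expected columns %s", path, paste(need, collapse = ","))
  n <- nrow(df)
  x <- as.numeric(df$x_mm); y <- as.numeric(df$y_mm)
  miss <- is.na(x) | is.na(y)
  if (mean(miss) > 0.5)
    stopf("quality error in '%s': %.0f%% of rows have no position (> 50%%)",
          path, 100 * mean(miss), class = "seizescreen_quality_error")
  x[miss] <- NA; y[miss] <- NA
  gaps <- data.frame(start_frame = integer(), end_frame = integer(),
                     interpolated = logical())
  if (any(miss)) {
    r <- rle(miss)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      glen <- r$lengths[k]
      interp <- glen <= maxInterpFrames && starts[k] > 1L && ends[k] < n
      if (interp) {
        idx <- (starts[k] - 1L):(ends[k] + 1L)
        x[idx] <- stats::approx(c(idx[1L], idx[length(idx)]),
                                x[c(idx[1L], idx[length(idx)])], xout = idx)$y
        y[idx] <- stats::approx(c(idx[1L], idx[length(idx)]),
                                y[c(idx[1L], idx[length(idx)])], xout = idx)$y
      }
      gaps <- rbind(gaps, data.frame(start_frame = starts[k],
                                     end_frame = ends[k], interpolated = interp))
    }
  }
  tm <- df$time_s
  rate <- if (n >= 2L) (n - 1) / (tm[n] - tm[1L]) else 25
  ok <- !is.na(x)
  radius <- metadata$arena_radius_mm %||%
    max(3.5, if (any(ok)) max(sqrt(x[ok]^2 + y[ok]^2)) else 0)
  swimTrack(x, y, fps = metadata$fps %||% rate, arenaRadiusMm = radius,
            subjectId = metadata$subject_id %||% "subject",
            genotype = metadata$genotype %||% "unknown",
            line = metadata$line %||% "unknown",
            condition = metadata$condition %||% "baseline",
            gaps = gaps)
}

#' Write a swim trajectory as CSV
#'
#' @param track a [SwimTrack-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTrack <- function(track, path) {
  stopifnot(is(track, "SwimTrack"))
  n <- length(track@xMm)
  tm <- (seq_len(n) - 1) / fps(track)
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.6f", v))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("frame,time_s,x_mm,y_mm", con)
  writeLines(sprintf("%d,%.6f,%s,%s", seq_len(n) - 1L, tm,
                     fmt(track@xMm), fmt(track@yMm)), con)
  invisible(path)
}

validateEvents <- function(df, where = "events") {
  need <- c("subject_id", "start_s", "end_s", "label", "source")
  if (!all(need %in% names(df)))
    stopf("%s must have columns %s", where, paste(need, collapse = ","))
  if (any(df$start_s >= df$end_s))
    stopf("%s: start_s must be < end_s (row %d)", where,
          which(df$start_s >= df$end_s)[1L])
  df <- df[order(df$subject_id, df$source, df$start_s), , drop = FALSE]
  for (key in unique(paste(df$subject_id, df$source))) {
    sub <- df[paste(df$subject_id, df$source) == key, , drop = FALSE]
    if (nrow(sub) > 1L && any(sub$start_s[-1L] < sub$end_s[-nrow(sub)] - 1e-12))
      stopf("%s: overlapping intervals for %s", where, key)
  }
  df[order(df$subject_id, df$start_s), , drop = FALSE]
}

#' Read / write event annotations
#'
#' Event annotations are BED-like half-open intervals `[start_s, end_s)` in
#' seconds from recording start, one row per event, with columns
#' `subject_id,start_s,end_s,label,source` (`source` one of `ground_truth`,
#' `manual`, `auto`). Intervals from the same subject and source must not
#' overlap; files are sorted by `(subject_id, start_s)` on write and the
#' writer/reader pair is a round-trip identity.
#'
#' @param path file path.
#' @return `readEvents()` returns the validated, sorted data.frame.
#' @export
readEvents <- function(path) {
  df <- utils::read.csv(path, comment.char = "#",
                        colClasses = c(subject_id = "character",
                                       label = "character",
                                       source = "character"))
  validateEvents(df, where = path)
}

#' @rdname readEvents
#' @param events a data.frame of annotations (validated and sorted on write).
#' @export
writeEvents <- function(events, path) {
  df <- validateEvents(events)
  out <- data.frame(subject_id = df$subject_id,
                    start_s = sprintf("%.6f", df$start_s),
                    end_s = sprintf("%.6f", df$end_s),
                    label = df$label, source = df$source)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write survival tables
#'
#' Columns `subject_id,line,genotype,time_dpf,event,treatment`; `time_dpf` is
#' the follow-up time in days post fertilization, `event` is `TRUE` for an
#' observed death and `FALSE` for censoring.
#'
#' @param path file path.
#' @return `readSurvival()` returns the validated data.frame.
#' @export
readSurvival <- function(path) {
  df <- utils::read.csv(path, comment.char = "#",
                        colClasses = c(subject_id = "character"))
  need <- c("subject_id", "line", "genotype", "time_dpf", "event", "treatment")
  if (!all(need %in% names(df)))
    stopf("format error in '%s': expected columns %s", path,
          paste(need, collapse = ","))
  df$event <- as.logical(df$event)
  if (anyNA(df$event)) stopf("'%s': event must be TRUE/FALSE", path)
  if (any(!is.finite(df$time_dpf) | df$time_dpf <= 0))
    stopf("'%s': time_dpf must be positive", path)
  df
}

#' @rdname readSurvival
#' @param records survival data.frame.
#' @export
writeSurvival <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a homology-input table
#'
#' Columns `gene,pct_identity,diopt_count` and optional `n_tools`
#' (default 12 ortholog-prediction tools).
#'
#' @param path file path.
#' @return data.frame with the four columns.
#' @export
readHomology <- function(path) {
  df <- utils::read.csv(path, comment.char = "#",
                        colClasses = c(gene = "character"))
  need <- c("gene", "pct_identity", "diopt_count")
  if (!all(need %in% names(df)))
    stopf("format error in '%s': expected columns %s", path,
          paste(need, collapse = ","))
  if (is.null(df$n_tools)) df$n_tools <- 12L
  df
}

#' Load a validated pipeline configuration
#'
#' Reads a YAML config with optional sections `detector`, `scorer`,
#' `behavior` and a top-level `seed`; keys use snake_case (e.g.
#' `voltage_threshold_mv`). Absent keys take the documented defaults; every
#' value is range-checked and an out-of-range value raises an error naming
#' the key, the value and the legal range.
#'
#' @param path YAML file path.
#' @return A [PipelineConfig-class].
#' @examples
#' cfg <- pipelineConfig()   # all defaults, equivalent to an empty config
#' @export
loadConfig <- function(path) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  raw <- raw %||% list()
  camel <- function(keys) {
    vapply(keys, function(k) {
      parts <- strsplit(k, "_", fixed = TRUE)[[1L]]
      paste0(parts[1L], paste0(toupper(substring(parts[-1L], 1, 1)),
                               substring(parts[-1L], 2), collapse = ""))
    }, character(1))
  }
  buildArgs <- function(sec, ctor, section) {
    if (is.null(sec)) return(list())
    names(sec) <- camel(names(sec))
    unknown <- setdiff(names(sec), names(formals(ctor)))
    if (length(unknown))
      stopf("config section '%s': unknown key(s) %s", section,
            paste(unknown, collapse = ", "))
    sec
  }
  det <- do.call(detectorConfig, buildArgs(raw$detector, detectorConfig, "detector"))
  sco <- do.call(scoreConfig, buildArgs(raw$scorer, scoreConfig, "scorer"))
  beh <- do.call(behaviorConfig, buildArgs(raw$behavior, behaviorConfig, "behavior"))
  pipelineConfig(det, sco, beh, seed = raw$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
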