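#' Write a recording to a CSV file with a JSON metadata sidecar
#'
#' The on-disk dialect is one CSV per recording with columns
#' `time,eadi,paw[,flow]` (times in seconds) and a sidecar
#' `<name>.meta.json` holding `fs_hz`, `units`, `peep_cmh2o`, `mode`,
#' `subject` and `t0_s`. [read_recording()] inverts it.
#'
#' @param rec A [recording()].
#' @param path Output CSV path; the sidecar is written next to it with the
#'   `.csv` extension replaced by `.meta.json`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "ns_recording"))
  df <- data.frame(time = signal_times(rec$eadi),
                   eadi = rec$eadi$values,
                   paw = rec$paw$values)
  if (!is.null(rec$flow)) df$flow <- rec$flow$values
  ok <- tryCatch({
    utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("cannot write recording to '", path, "': ",
         conditionMessage(ok), call. = FALSE)
  meta <- rec$meta
  side <- list(
    fs_hz = rec$eadi$fs,
    units = list(eadi = "uV", paw = "cmH2O",
                 flow = if (is.null(rec$flow)) NULL else "L/min"),
    peep_cmh2o = meta$peep_cmh2o,
    mode = meta$mode,
    subject = meta$subject,
    t0_s = rec$eadi$t0
  )
  jsonlite::write_json(side, meta_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

meta_path <- function(path) paste0(sub("\\.csv$", "", path), ".meta.json")

#' Read a recording from a CSV file (with optional JSON sidecar)
#'
#' Expects columns `time`, `eadi`, `paw` and optionally `flow`. The time
#' column is used only to validate uniform sampling (relative step
#' deviations above 1% are a format error); internally samples are indexed
#' at the sampling rate `fs`, taken from the sidecar (default 62.5 Hz).
#'
#' @param path CSV path; a sidecar `<name>.meta.json` is read if present.
#' @return A [recording()].
#' @export
read_recording <- function(path) {
  if (!file.exists(path))
    stop("file not found: '", path, "'", call. = FALSE)
  df <- utils::read.csv(path)
  req <- c("time", "eadi", "paw")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("recording CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  cols <- intersect(c("time", "eadi", "paw", "flow"), names(df))
  for (cl in cols) {
    bad <- which(!is.finite(df[[cl]]))
    if (length(bad))
      stop("non-finite sample in column '", cl, "' at row ", bad[1L],
           call. = FALSE)
  }
  if (nrow(df) >= 3L) {
    dt <- diff(df$time)
    dt_ref <- stats::median(dt)
    if (dt_ref <= 0 || any(abs(dt - dt_ref) > 0.01 * dt_ref))
      stop("time column is not uniformly sampled ",
           "(step deviates by more than 1%)", call. = FALSE)
  }
  mp <- meta_path(path)
  meta <- if (file.exists(mp)) jsonlite::read_json(mp) else list()
  fs <- if (!is.null(meta$fs_hz)) as.numeric(meta$fs_hz) else 62.5
  t0 <- if (!is.null(meta$t0_s)) as.numeric(meta$t0_s) else df$time[1L]
  recording(
    eadi = df$eadi, paw = df$paw,
    flow = if ("flow" %in% names(df)) df$flow else NULL,
    fs = fs, t0 = t0,
    meta = list(
      fs_hz = fs,
      peep_cmh2o = if (!is.null(meta$peep_cmh2o)) as.numeric(meta$peep_cmh2o),
      mode = if (!is.null(meta$mode)) as.character(meta$mode),
      subject = if (!is.null(meta$subject)) as.character(meta$subject)
    )
  )
}

#' Extract the trailing analysis window of a recording
#'
#' Study parameters are computed from a stable trailing window (5 minutes
#' by default) of each recording. Returns the final
#' `min(window_s, duration)` seconds of every channel, preserving
#' synchronization; `t0` is advanced so event times stay on the original
#' recording's clock. Never changes `fs` or sample order; applying the same
#' window twice is idempotent.
#'
#' @param rec A [recording()].
#' @param window_s Window length in seconds (default 300).
#' @return A [recording()] covering the trailing window.
#' @export
extract_analysis_window <- function(rec, window_s = 300) {
  stopifnot(inherits(rec, "ns_recording"))
  if (!is.numeric(window_s) || length(window_s) != 1L || window_s <= 0)
    stop("'window_s' must be a single positive number", call. = FALSE)
  n <- length(rec$eadi$values)
  keep <- min(n, round(window_s * rec$eadi$fs))
  idx <- seq.int(n - keep + 1L, n)
  t0 <- rec$eadi$t0 + (n - keep) / rec$eadi$fs
  recording(
    eadi = rec$eadi$values[idx], paw = rec$paw$values[idx],
    flow = if (!is.null(rec$flow)) rec$flow$values[idx],
    fs = rec$eadi$fs, t0 = t0, meta = rec$meta
  )
}

#' Write ground-truth annotations to JSON
#'
#' Serialises an annotation set (`neural_events`, `vent_events`, `labels`
#' and, for simulator output, the `matched` per-breath truth table) to a
#' JSON file that [read_annotations()] inverts.
#'
#' @param ann A list with data-frame elements `neural_events`
#'   (`onset_s`, `peak_s`, `cycleoff_s`, ...), `vent_events` (`trigger_s`,
#'   `cycleoff_s`, ...) and `labels` (`time_s`, `class`); extra elements
#'   are preserved.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  stopifnot(is.list(ann))
  jsonlite::write_json(ann, path, dataframe = "columns", auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Read ground-truth annotations from JSON
#' @param path JSON path written by [write_annotations()].
#' @return A list of data frames.
#' @export
read_annotations <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("neural_events", "vent_events", "labels", "matched"))
    if (!is.null(raw[[nm]])) raw[[nm]] <- as.data.frame(raw[[nm]])
  raw
}
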