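#' Construct a uniformly sampled physiological signal
#'
#' A `ns_signal` holds one channel of a synchronized respiratory recording:
#' an ordered vector of samples at a fixed sampling rate, with sample `i`
#' (1-based) occurring at time `t0 + (i - 1) / fs` seconds.
#'
#' @param values Numeric vector of samples; must be non-empty and finite.
#' @param fs Sampling rate in Hz (default 62.5, the acquisition rate of
#'   EAdi-capable ventilator serial output).
#' @param name Channel label, e.g. `"eadi"`.
#' @param unit Unit string, one of `"uV"`, `"cmH2O"`, `"L/min"`.
#' @param t0 Start time of the first sample in seconds (default 0).
#' @return An object of class `ns_signal`.
#' @export
sampled_signal <- function(values, fs = 62.5, name = "signal",
                           unit = c("uV", "cmH2O", "L/min"), t0 = 0) {
  unit <- match.arg(unit)
  if (!is.numeric(values) || length(values) == 0L)
    stop("'values' must be a non-empty numeric vector", call. = FALSE)
  if (!all(is.finite(values)))
    stop("'values' contains non-finite samples (first at index ",
         which(!is.finite(values))[1L], ")", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("'fs' must be a single positive number", call. = FALSE)
  structure(
    list(name = name, unit = unit, fs = fs,
         values = as.numeric(values), t0 = as.numeric(t0)),
    class = "ns_signal"
  )
}

#' Sample times of a signal
#' @param sig A `ns_signal`.
#' @return Numeric vector of times in seconds, same length as the samples.
#' @export
signal_times <- function(sig) {
  stopifnot(inherits(sig, "ns_signal"))
  sig$t0 + (seq_along(sig$values) - 1) / sig$fs
}

#' Duration of a signal in seconds
#' @param sig A `ns_signal`.
#' @return Length of the signal in seconds (`n / fs`).
#' @export
signal_duration <- function(sig) {
  stopifnot(inherits(sig, "ns_signal"))
  length(sig$values) / sig$fs
}

#' @export
print.ns_signal <- function(x, ...) {
  cat(sprintf("<ns_signal> %s [%s]: %d samples @ %.4g Hz, t0 = %.3f s (%.1f s)\n",
              x$name, x$unit, length(x$values), x$fs, x$t0,
              signal_duration(x)))
  invisible(x)
}

#' Construct a synchronized multichannel recording
#'
#' Bundles EAdi (uV), Paw (cmH2O) and optionally flow (L/min) channels that
#' share a sampling rate, start time and length, together with metadata.
#'
#' @param eadi,paw Numeric vectors (or `ns_signal` objects) for diaphragm
#'   electrical activity and airway pressure.
#' @param flow Optional numeric vector (or `ns_signal`) of flow in L/min.
#' @param fs Sampling rate in Hz, used when channels are plain vectors.
#' @param t0 Start time in seconds, used when channels are plain vectors.
#' @param meta Named list of metadata. Recognised keys: `fs_hz`,
#'   `peep_cmh2o`, `mode`, `subject`.
#' @return An object of class `ns_recording` with elements `eadi`, `paw`,
#'   `flow` (possibly `NULL`) and `meta`.
#' @export
recording <- function(eadi, paw, flow = NULL, fs = 62.5, t0 = 0,
                      meta = list()) {
  as_sig <- function(x, name, unit) {
    if (inherits(x, "ns_signal")) x
    else sampled_signal(x, fs = fs, name = name, unit = unit, t0 = t0)
  }
  eadi <- as_sig(eadi, "eadi", "uV")
  paw  <- as_sig(paw,  "paw",  "cmH2O")
  if (!is.null(flow)) flow <- as_sig(flow, "flow", "L/min")
  chans <- c(list(eadi, paw), if (!is.null(flow)) list(flow))
  fss <- vapply(chans, function(s) s$fs, numeric(1))
  lens <- vapply(chans, function(s) length(s$values), integer(1))
  t0s <- vapply(chans, function(s) s$t0, numeric(1))
  if (length(unique(fss)) != 1L || length(unique(lens)) != 1L ||
      diff(range(t0s)) > 1e-9)
    stop("channels are not synchronized: fs, length and t0 must match",
         call. = FALSE)
  if (is.null(meta$fs_hz)) meta$fs_hz <- eadi$fs
  structure(list(eadi = eadi, paw = paw, flow = flow, meta = meta),
            class = "ns_recording")
}

#' @export
print.ns_recording <- function(x, ...) {
  cat(sprintf("<ns_recording> %d samples @ %.4g Hz (%.1f s)%s\n",
              length(x$eadi$values), x$eadi$fs, recording_duration(x),
              if (is.null(x$flow)) ", no flow channel" else ""))
  if (!is.null(x$meta$mode)) cat("  mode:    ", x$meta$mode, "\n")
  if (!is.null(x$meta$subject) && !is.na(x$meta$subject))
    cat("  subject: ", x$meta$subject, "\n")
  if (!is.null(x$meta$peep_cmh2o))
    cat("  PEEP:    ", x$meta$peep_cmh2o, "cmH2O\n")
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec A `ns_recording`.
#' @return Duration in seconds.
#' @export
recording_duration <- function(rec) {
  stopifnot(inherits(rec, "ns_recording"))
  signal_duration(rec$eadi)
}
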