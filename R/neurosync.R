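#' Automated patient-ventilator interaction analysis
#'
#' Runs the full breath-level analysis on a recording: extracts the
#' trailing analysis window (5 minutes by default), segments EAdi into
#' neural breaths and Paw into ventilator assists, applies the EAdi
#' signal-quality gate, matches neural efforts to assists, scores signed
#' trigger and cycle-off timing errors as percentages of neural
#' inspiratory and expiratory time, classifies asynchronies (assigned
#' 100% error), and summarises the result with the NeuroSync index — the
#' mean per-breath percentage error — together with the synchrony-box
#' proportions and a breath-density grid.
#'
#' @param rec A [recording()] (or the list returned by
#'   [simulate_recording()], whose `$recording` element is used).
#' @param window_s Trailing analysis window in seconds (default 300).
#' @param params A [detector_params()].
#' @param peep PEEP in cmH2O or `"auto"`.
#' @param combine Per-breath error combination rule (`"mean"` or `"max"`).
#' @param box_threshold_pct Synchrony box half-width (default 20%).
#' @param bin_width_pct Breath-density grid bin width (default 5%).
#' @param min_median_peak_uV Quality-gate threshold on the median peak
#'   EAdi amplitude (uV).
#' @param enforce_quality If `TRUE` (default) a failing quality gate
#'   aborts the analysis with a condition of class `ns_quality_error`
#'   carrying the verdict; if `FALSE` the verdict is only recorded.
#' @param lead_slack_s,autotrigger_factor Matching parameters, see
#'   [match_events()].
#' @return An object of class `neurosync` (extending
#'   `ns_synchrony_report`): the report fields plus `pattern` (median
#'   peak EAdi, peak Paw, peak flow and neural respiratory rate over the
#'   window), `quality`, `neural`, `vent`, `params`, `peep`, `meta` and
#'   `call`. Methods: `print`, `summary`, `plot`, `as.data.frame`.
#' @examples
#' sim <- simulate_recording(preset_mode_config("NAVA-like", seed = 1,
#'                                              duration_s = 120))
#' fit <- neurosync(sim$recording, window_s = 120)
#' fit
#' head(as.data.frame(fit))
#' @export
neurosync <- function(rec, window_s = 300, params = detector_params(),
                      peep = "auto", combine = c("mean", "max"),
                      box_threshold_pct = 20, bin_width_pct = 5,
                      min_median_peak_uV = 1.0, enforce_quality = TRUE,
                      lead_slack_s = 0.15, autotrigger_factor = 0.5) {
  combine <- match.arg(combine)
  if (is.list(rec) && !inherits(rec, "ns_recording") &&
      inherits(rec$recording, "ns_recording"))
    rec <- rec$recording
  stopifnot(inherits(rec, "ns_recording"))
  win <- extract_analysis_window(rec, window_s)
  dur <- recording_duration(win)

  nb <- detect_neural_breaths(win$eadi, params)
  quality <- check_signal_quality(nb, min_median_peak_uV)
  if (!quality$ok && enforce_quality) {
    cond <- structure(
      class = c("ns_quality_error", "error", "condition"),
      list(message = paste0("analysis refused, EAdi signal quality ",
                            "inadequate: ", quality$reason),
           call = sys.call(-1), quality = quality))
    stop(cond)
  }
  vb <- detect_vent_breaths(win$paw, peep = peep, params = params,
                            flow = win$flow)
  recs <- match_events(nb, vb, lead_slack_s = lead_slack_s,
                       autotrigger_factor = autotrigger_factor)
  recs <- score_breaths(recs, combine)
  rep <- build_report(recs, dur, bin_width_pct, box_threshold_pct)

  pattern <- list(
    peak_eadi_uV = if (nrow(nb)) stats::median(nb$peak_uV) else NA_real_,
    peak_paw_cmH2O = if (nrow(vb)) stats::median(vb$peak_paw_cmH2O)
                     else NA_real_,
    peak_flow_lmin = if (nrow(vb) && any(is.finite(vb$peak_flow_lmin)))
      stats::median(vb$peak_flow_lmin, na.rm = TRUE) else NA_real_,
    neural_rr_bpm = neural_respiratory_rate(nb, dur)
  )
  out <- c(rep, list(pattern = pattern, quality = quality, neural = nb,
                     vent = vb, params = params,
                     peep = attr(vb, "peep"), combine = combine,
                     window_s = window_s, meta = rec$meta,
                     call = match.call()))
  class(out) <- c("neurosync", "ns_synchrony_report")
  out
}

#' @export
print.neurosync <- function(x, digits = 3, ...) {
  cat("Automated patient-ventilator interaction analysis\n\n")
  if (!is.null(x$meta$mode)) cat("  mode:", x$meta$mode, "\n")
  cat(sprintf("  window: %.0f s, %d neural breaths, %d assists (PEEP %.1f cmH2O)\n",
              x$duration_s, nrow(x$neural), nrow(x$vent), x$peep))
  cat(sprintf("  neural respiratory rate: %.1f breaths/min\n",
              x$pattern$neural_rr_bpm))
  cat(sprintf("\n  NeuroSync index: %.*g %% (without wasted efforts: %.*g %%)\n",
              digits, x$neurosync_pct, digits, x$neurosync_no_wasted_pct))
  cat(sprintf("  synchronous / dyssynchronous / asynchronous: %.1f / %.1f / %.1f %%\n",
              x$pct_synchronous, x$pct_dyssynchronous, x$pct_asynchronous))
  cnt <- x$counts[x$counts > 0]
  if (length(cnt))
    cat("  breath classes:", paste(sprintf("%s=%d", names(cnt), cnt),
                                   collapse = ", "), "\n")
  invisible(x)
}

iqr_fmt <- function(x, digits = 1) {
  q <- stats::quantile(x, c(0.5, 0.25, 0.75), na.rm = TRUE, names = FALSE)
  sprintf("%.*f (%.*f to %.*f)", digits, q[1], digits, q[2], digits, q[3])
}

#' Summary of a neurosync analysis
#'
#' Median (IQR) summaries of breathing pattern and timing errors over the
#' analysis window, following the reporting convention of the analysis
#' (medians with interquartile ranges; means only for absolute cycling-off
#' milliseconds).
#'
#' @param object A `neurosync` object.
#' @param ... Unused.
#' @return An object of class `summary.neurosync`, printed as a table.
#' @export
summary.neurosync <- function(object, ...) {
  x <- object
  pb <- x$per_breath
  m <- pb[pb$klass == "matched", , drop = FALSE]
  s <- list(
    meta = x$meta,
    n_breaths = x$n_breaths,
    counts = x$counts,
    neurosync_pct = x$neurosync_pct,
    neurosync_no_wasted_pct = x$neurosync_no_wasted_pct,
    pattern = x$pattern,
    trigger_delay = if (nrow(m)) iqr_fmt(m$trigger_delay_ms, 0) else NA,
    trigger_error = if (nrow(m)) iqr_fmt(m$trigger_error_pct, 1) else NA,
    cycleoff_error = if (any(is.finite(m$cycleoff_error_pct)))
      iqr_fmt(m$cycleoff_error_pct, 1) else NA,
    cycleoff_abs_ms = if (any(is.finite(m$cycleoff_error_ms)))
      sprintf("%.0f +/- %.0f",
              mean(abs(m$cycleoff_error_ms), na.rm = TRUE),
              stats::sd(abs(m$cycleoff_error_ms), na.rm = TRUE)) else NA,
    wasted_per_min = x$wasted_per_min,
    proportions = c(synchronous = x$pct_synchronous,
                    dyssynchronous = x$pct_dyssynchronous,
                    asynchronous = x$pct_asynchronous),
    quality = x$quality
  )
  class(s) <- "summary.neurosync"
  s
}

#' @export
print.summary.neurosync <- function(x, ...) {
  cat("Patient-ventilator interaction summary",
      if (!is.null(x$meta$mode)) paste0("— ", x$meta$mode), "\n\n")
  cat(sprintf("  Breathing pattern (medians):\n"))
  cat(sprintf("    peak EAdi:        %.1f uV\n", x$pattern$peak_eadi_uV))
  cat(sprintf("    peak Paw:         %.1f cmH2O\n",
              x$pattern$peak_paw_cmH2O))
  if (is.finite(x$pattern$peak_flow_lmin))
    cat(sprintf("    peak flow:        %.1f L/min\n",
                x$pattern$peak_flow_lmin))
  cat(sprintf("    neural RR:        %.1f /min\n",
              x$pattern$neural_rr_bpm))
  cat("\n  Timing, median (IQR):\n")
  cat("    trigger delay:    ", x$trigger_delay, "ms\n")
  cat("    trigger error:    ", x$trigger_error, "%\n")
  cat("    cycle-off error:  ", x$cycleoff_error, "%\n")
  cat("    |cycle-off|:      ", x$cycleoff_abs_ms, "ms (mean +/- SD)\n")
  cat(sprintf("\n  NeuroSync index: %.2f %% (decoupled: %.2f %%)\n",
              x$neurosync_pct, x$neurosync_no_wasted_pct))
  cat(sprintf("  wasted efforts:  %.2f /min\n", x$wasted_per_min))
  cat(sprintf("  synchronous %.1f%% / dyssynchronous %.1f%% / asynchronous %.1f%%\n",
              x$proportions[1], x$proportions[2], x$proportions[3]))
  invisible(x)
}

#' @export
as.data.frame.neurosync <- function(x, ...) {
  df <- x$per_breath
  class(df) <- "data.frame"
  df
}

#' Breath-density plot of timing errors
#'
#' Plots the 2-D breath-density histogram of relative cycling-off
#' (x-axis) versus trigger (y-axis) errors for matched breaths, with the
#' synchrony box drawn at the classification threshold, and a side panel
#' with the class proportions.
#'
#' @param x A `neurosync` object.
#' @param ... Passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.neurosync <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 2), mar = c(4.5, 4.5, 3, 1))
  on.exit(graphics::par(old))
  g <- x$density_grid
  mids <- g$breaks[-1] - diff(g$breaks) / 2
  cnt <- g$counts
  graphics::image(mids, mids, log1p(cnt),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "cycling-off error (% of te,n)",
                  ylab = "trigger error (% of ti,n)",
                  main = "Breath density", ...)
  thr <- x$box_threshold_pct
  graphics::rect(-thr, -thr, thr, thr, border = "white", lwd = 2)
  props <- c(x$pct_synchronous, x$pct_dyssynchronous, x$pct_asynchronous)
  graphics::barplot(props, names.arg = c("sync", "dyssync", "async"),
                    ylab = "% of breaths", ylim = c(0, 100),
                    main = sprintf("NeuroSync = %.1f%%", x$neurosync_pct),
                    col = c("#4daf4a", "#ff7f00", "#e41a1c"))
  invisible(x)
}
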