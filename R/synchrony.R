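# Neural-ventilator event matching, per-breath timing errors, asynchrony
# classification, NeuroSync index and summary report.

BREATH_CLASSES <- c("matched", "wasted_effort", "auto_trigger",
                    "double_trigger", "multi_eadi")

#' Match neural efforts to ventilator assists and classify asynchronies
#'
#' Each pneumatic trigger is assigned to the neural breath whose onset
#' interval contains it (intervals run from one onset to the next, shifted
#' earlier by `lead_slack_s` to tolerate small trigger leads). A neural
#' breath with no assigned trigger is a wasted effort; a trigger falling
#' in no interval, or starting later than the breath's cycle-off plus
#' `autotrigger_factor * te_n`, is an auto-trigger; a breath with two or
#' more assigned triggers is a double trigger; two or more neural peaks
#' under one assist mark the involved breaths as multiple-EAdi; remaining
#' one-to-one pairs are matched. Every neural breath and every ventilator
#' event appears in exactly one record.
#'
#' @param neural Data frame from [detect_neural_breaths()].
#' @param vent Data frame from [detect_vent_breaths()].
#' @param lead_slack_s Allowed trigger lead before the neural onset (s).
#' @param autotrigger_factor Fraction of `te_n` past the neural cycle-off
#'   beyond which an assist is deemed dissociated (auto-trigger).
#' @return A data frame of class `ns_breath_records`, one row per breath
#'   record, with the neural and ventilator timing columns, `klass`, and
#'   (unfilled) error columns; score with [score_breaths()].
#' @export
match_events <- function(neural, vent, lead_slack_s = 0.15,
                         autotrigger_factor = 0.5) {
  nb <- as.data.frame(neural)
  vb <- as.data.frame(vent)
  Kn <- nrow(nb); Kv <- nrow(vb)
  if (Kn > 1L && is.unsorted(nb$onset_s))
    stop("'neural' must be ordered by onset time", call. = FALSE)
  if (Kv > 1L && is.unsorted(vb$trigger_s))
    stop("'vent' must be ordered by trigger time", call. = FALSE)

  vent_to <- rep(NA_integer_, Kv)   # neural index each vent is assigned to
  vent_auto <- rep(FALSE, Kv)
  if (Kv) {
    if (Kn) {
      idx <- findInterval(vb$trigger_s, nb$onset_s - lead_slack_s)
      for (v in seq_len(Kv)) {
        i <- idx[v]
        if (i == 0L) { vent_auto[v] <- TRUE; next }
        te_i <- nb$te_n_s[i]
        if (is.finite(te_i) &&
            vb$trigger_s[v] > nb$cycleoff_s[i] + autotrigger_factor * te_i)
          vent_auto[v] <- TRUE
        else vent_to[v] <- i
      }
    } else vent_auto[] <- TRUE
  }

  n_assigned <- tabulate(vent_to[!is.na(vent_to)], nbins = max(Kn, 1L))
  klass <- rep("matched", Kn)
  if (Kn) {
    klass[n_assigned[seq_len(Kn)] == 0L] <- "wasted_effort"
    klass[n_assigned[seq_len(Kn)] >= 2L] <- "double_trigger"
  }
  first_vent <- rep(NA_integer_, Kn)
  if (Kn && Kv)
    for (v in seq_len(Kv))
      if (!is.na(vent_to[v]) && is.na(first_vent[vent_to[v]]))
        first_vent[vent_to[v]] <- v

  # multiple EAdi bursts under one assist
  if (Kn && Kv) {
    for (i in which(klass == "matched")) {
      v <- first_vent[i]
      covered <- which(nb$peak_s >= vb$trigger_s[v] &
                       nb$peak_s <= vb$cycleoff_s[v])
      if (length(covered) >= 2L) {
        klass[i] <- "multi_eadi"
        extra <- setdiff(covered, i)
        klass[extra][klass[extra] == "wasted_effort"] <- "multi_eadi"
      }
    }
  }

  rec_n <- if (Kn) data.frame(
    neural_idx = seq_len(Kn), vent_idx = first_vent,
    n_vent = if (Kn) n_assigned[seq_len(Kn)] else integer(0),
    klass = klass,
    onset_s = nb$onset_s, peak_s = nb$peak_s,
    neural_cycleoff_s = nb$cycleoff_s,
    ti_n_s = nb$ti_n_s, te_n_s = nb$te_n_s,
    peak_uV = if (!is.null(nb$peak_uV)) nb$peak_uV else NA_real_,
    trigger_s = ifelse(is.na(first_vent), NA_real_,
                       vb$trigger_s[first_vent]),
    vent_cycleoff_s = ifelse(is.na(first_vent), NA_real_,
                             vb$cycleoff_s[first_vent]),
    stringsAsFactors = FALSE
  ) else NULL
  auto_idx <- which(vent_auto)
  rec_v <- if (length(auto_idx)) data.frame(
    neural_idx = NA_integer_, vent_idx = auto_idx, n_vent = 1L,
    klass = "auto_trigger",
    onset_s = NA_real_, peak_s = NA_real_, neural_cycleoff_s = NA_real_,
    ti_n_s = NA_real_, te_n_s = NA_real_, peak_uV = NA_real_,
    trigger_s = vb$trigger_s[auto_idx],
    vent_cycleoff_s = vb$cycleoff_s[auto_idx],
    stringsAsFactors = FALSE
  ) else NULL
  recs <- rbind(rec_n, rec_v)
  if (is.null(recs))
    recs <- data.frame(neural_idx = integer(0), vent_idx = integer(0),
                       n_vent = integer(0), klass = character(0),
                       onset_s = numeric(0), peak_s = numeric(0),
                       neural_cycleoff_s = numeric(0), ti_n_s = numeric(0),
                       te_n_s = numeric(0), peak_uV = numeric(0),
                       trigger_s = numeric(0), vent_cycleoff_s = numeric(0))
  o <- order(ifelse(is.na(recs$onset_s), recs$trigger_s, recs$onset_s))
  recs <- recs[o, , drop = FALSE]
  recs$breath_id <- seq_len(nrow(recs))
  recs$trigger_error_pct <- NA_real_
  recs$trigger_delay_ms <- NA_real_
  recs$cycleoff_error_pct <- NA_real_
  recs$cycleoff_error_ms <- NA_real_
  recs$breath_error_pct <- NA_real_
  rownames(recs) <- NULL
  class(recs) <- c("ns_breath_records", "data.frame")
  recs
}

cap100 <- function(x) pmin(pmax(x, -100), 100)

#' Trigger error of a matched breath record
#'
#' Signed trigger timing error: `100 * (trigger - onset) / ti_n` percent
#' (positive = late triggering), with the millisecond delay alongside.
#' Magnitudes are capped at 100%.
#'
#' @param rec A single matched breath record (one-row data frame or list).
#' @return A list with `trigger_error_pct` and `trigger_delay_ms`.
#' @export
trigger_error <- function(rec) {
  rec <- as.list(rec)
  if (!identical(rec$klass, "matched"))
    stop("trigger_error() applies to matched records only", call. = FALSE)
  d <- rec$trigger_s - rec$onset_s
  list(trigger_error_pct = cap100(100 * d / rec$ti_n_s),
       trigger_delay_ms = 1000 * d)
}

#' Cycle-off error of a matched breath record
#'
#' Signed cycling-off error: `100 * (vent cycle-off - neural cycle-off) /
#' te_n` percent. Positive values indicate late cycling off, negative
#' values early cycling off. Magnitudes are capped at 100%. Undefined
#' (error) when `te_n` is undefined (last breath of a record).
#'
#' @param rec A single matched breath record.
#' @return A list with `cycleoff_error_pct` and `cycleoff_error_ms`.
#' @export
cycleoff_error <- function(rec) {
  rec <- as.list(rec)
  if (!identical(rec$klass, "matched"))
    stop("cycleoff_error() applies to matched records only", call. = FALSE)
  if (!is.finite(rec$te_n_s))
    stop("cycle-off error undefined: te_n is not defined for this breath",
         call. = FALSE)
  d <- rec$vent_cycleoff_s - rec$neural_cycleoff_s
  list(cycleoff_error_pct = cap100(100 * d / rec$te_n_s),
       cycleoff_error_ms = 1000 * d)
}

#' Per-breath percentage error entering the NeuroSync average
#'
#' Non-matched records (asynchronies) are assigned 100% error. Matched
#' records combine the trigger and cycle-off error magnitudes (mean by
#' default, max optionally); when `te_n` is undefined only the trigger
#' error contributes. Always in \[0, 100\].
#'
#' @param rec A single classified breath record with error fields filled
#'   for matched records.
#' @param combine `"mean"` (default) or `"max"`.
#' @return Percentage error in \[0, 100\].
#' @export
breath_error <- function(rec, combine = c("mean", "max")) {
  combine <- match.arg(combine)
  rec <- as.list(rec)
  if (!identical(rec$klass, "matched")) return(100)
  tr <- abs(rec$trigger_error_pct)
  co <- abs(rec$cycleoff_error_pct)
  v <- if (!is.finite(co)) tr
       else if (combine == "mean") mean(c(tr, co)) else max(tr, co)
  min(v, 100)
}

#' Fill timing-error and per-breath-error fields of breath records
#'
#' Vectorised application of [trigger_error()], [cycleoff_error()] and
#' [breath_error()] to a record table from [match_events()].
#'
#' @param records A `ns_breath_records` data frame.
#' @param combine Per-breath error combination rule, `"mean"` or `"max"`.
#' @return The records with error columns filled.
#' @export
score_breaths <- function(records, combine = c("mean", "max")) {
  combine <- match.arg(combine)
  r <- records
  m <- r$klass == "matched"
  d <- r$trigger_s[m] - r$onset_s[m]
  r$trigger_delay_ms[m] <- 1000 * d
  r$trigger_error_pct[m] <- cap100(100 * d / r$ti_n_s[m])
  mc <- m & is.finite(r$te_n_s)
  dc <- r$vent_cycleoff_s[mc] - r$neural_cycleoff_s[mc]
  r$cycleoff_error_ms[mc] <- 1000 * dc
  r$cycleoff_error_pct[mc] <- cap100(100 * dc / r$te_n_s[mc])
  tr <- abs(r$trigger_error_pct)
  co <- abs(r$cycleoff_error_pct)
  be <- ifelse(is.finite(co),
               if (combine == "mean") (tr + co) / 2 else pmax(tr, co),
               tr)
  r$breath_error_pct <- ifelse(m, pmin(be, 100), 100)
  attr(r, "combine") <- combine
  r
}

#' NeuroSync index
#'
#' The arithmetic mean of the per-breath percentage errors over all breath
#' records (asynchronies counted as 100%). With `include_wasted = FALSE`
#' wasted-effort records are dropped before averaging — the decoupled
#' variant used when regressing wasted efforts against the index, to avoid
#' mathematically coupled variables.
#'
#' @param records Scored breath records (see [score_breaths()]).
#' @param include_wasted Keep wasted-effort records in the average?
#' @return The index in percent.
#' @export
neurosync_index <- function(records, include_wasted = TRUE) {
  r <- as.data.frame(records)
  if (!include_wasted) r <- r[r$klass != "wasted_effort", , drop = FALSE]
  if (!nrow(r))
    stop("NeuroSync index undefined: no breath records retained",
         call. = FALSE)
  if (any(!is.finite(r$breath_error_pct)))
    stop("records must be scored first (see score_breaths())",
         call. = FALSE)
  mean(r$breath_error_pct)
}

#' Classify breath records against the synchrony box
#'
#' Matched breaths with both |trigger error| and |cycle-off error| at or
#' below the threshold (default 20%) are synchronous ("inside the box");
#' matched breaths outside it are dyssynchronous; all asynchrony classes
#' are asynchronous. A missing cycle-off error (last breath) leaves the
#' trigger error alone to decide.
#'
#' @param records Scored breath records (or a single record).
#' @param threshold_pct Box half-width in percent (default 20).
#' @return Character vector: `"synchronous"`, `"dyssynchronous"` or
#'   `"asynchronous"`.
#' @export
classify_box <- function(records, threshold_pct = 20) {
  r <- as.data.frame(as.list.maybe(records))
  tr <- abs(r$trigger_error_pct)
  co <- abs(r$cycleoff_error_pct)
  ifelse(r$klass != "matched", "asynchronous",
         ifelse(tr <= threshold_pct & (is.na(co) | co <= threshold_pct),
                "synchronous", "dyssynchronous"))
}

as.list.maybe <- function(x) {
  if (is.data.frame(x)) x else as.data.frame(as.list(x),
                                             stringsAsFactors = FALSE)
}

#' Build a synchrony report from scored breath records
#'
#' Aggregates breath records into the summary used for reporting: the
#' NeuroSync index with and without wasted efforts, class counts, wasted
#' efforts per minute, the synchronous/dyssynchronous/asynchronous
#' proportions, and a 2-D breath-density histogram of (cycle-off error,
#' trigger error) for matched breaths on a fixed \[-100, 100\] percent
#' grid.
#'
#' @param records Scored breath records.
#' @param duration_s Analysed duration in seconds (for per-minute rates).
#' @param bin_width_pct Density-grid bin width in percent (default 5).
#' @param box_threshold_pct Synchrony box half-width in percent.
#' @return A list of class `ns_synchrony_report`.
#' @export
build_report <- function(records, duration_s, bin_width_pct = 5,
                         box_threshold_pct = 20) {
  r <- as.data.frame(records)
  n <- nrow(r)
  counts <- vapply(BREATH_CLASSES, function(k) sum(r$klass == k),
                   integer(1))
  brks <- seq(-100, 100, by = bin_width_pct)
  m <- r[r$klass == "matched", , drop = FALSE]
  grid <- matrix(0L, nrow = length(brks) - 1L, ncol = length(brks) - 1L)
  if (nrow(m)) {
    xb <- cut(cap100(m$cycleoff_error_pct), brks, include.lowest = TRUE)
    yb <- cut(cap100(m$trigger_error_pct), brks, include.lowest = TRUE)
    keep <- !is.na(xb) & !is.na(yb)
    tb <- table(xb[keep], yb[keep])
    grid <- matrix(as.integer(tb), nrow = length(brks) - 1L)
  }
  box <- if (n) classify_box(r, box_threshold_pct) else character(0)
  r$box <- box
  if (n) {
    ns_all <- neurosync_index(r, include_wasted = TRUE)
    ns_nw <- if (any(r$klass != "wasted_effort"))
      neurosync_index(r, include_wasted = FALSE) else NA_real_
  } else ns_all <- ns_nw <- NA_real_
  structure(list(
    neurosync_pct = ns_all,
    neurosync_no_wasted_pct = ns_nw,
    n_breaths = n,
    counts = counts,
    wasted_per_min = unname(counts["wasted_effort"]) * 60 / duration_s,
    pct_synchronous = if (n) 100 * sum(box == "synchronous") / n
                      else NA_real_,
    pct_dyssynchronous = if (n) 100 * sum(box == "dyssynchronous") / n
                         else NA_real_,
    pct_asynchronous = if (n) 100 * sum(box == "asynchronous") / n
                       else NA_real_,
    density_grid = list(breaks = brks, counts = grid,
                        x = "cycleoff_error_pct", y = "trigger_error_pct"),
    box_threshold_pct = box_threshold_pct,
    duration_s = duration_s,
    per_breath = r
  ), class = "ns_synchrony_report")
}

#' @export
print.ns_synchrony_report <- function(x, digits = 3, ...) {
  cat("Patient-ventilator synchrony report\n")
  cat(sprintf("  breaths analysed:      %d (%.1f s window)\n",
              x$n_breaths, x$duration_s))
  cat(sprintf("  NeuroSync index:       %.*g %%\n", digits,
              x$neurosync_pct))
  cat(sprintf("  ... without wasted:    %.*g %%\n", digits,
              x$neurosync_no_wasted_pct))
  cat(sprintf("  synchronous/dyssynchronous/asynchronous: %.1f / %.1f / %.1f %%\n",
              x$pct_synchronous, x$pct_dyssynchronous, x$pct_asynchronous))
  cnt <- x$counts[x$counts > 0]
  if (length(cnt))
    cat("  classes:", paste(sprintf("%s=%d", names(cnt), cnt),
                            collapse = ", "), "\n")
  invisible(x)
}
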