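# Breath segmentation: EAdi -> neural breaths (onset, peak, 70% cycle-off),
# Paw -> ventilator assists (pneumatic trigger, cycle-off).

#' Detector parameters
#'
#' Tunable thresholds of the breath detectors. The neural cycle-off
#' fraction defaults to 0.70 (the 70%-of-peak-EAdi rule); all fractions
#' must lie in (0, 1).
#'
#' @param onset_fraction Fraction of (peak - tonic) at which the neural
#'   onset crossing is located when backtracking from the peak (default
#'   0.10); the onset itself is the ramp foot extrapolated from two
#'   crossings (see Details).
#' @param cycleoff_fraction Fraction of (peak - tonic) defining neural
#'   cycle-off (default 0.70, fixed by the analysis convention).
#' @param min_peak_uV Minimum EAdi peak prominence above the tonic
#'   baseline for a neural effort (uV). The effective floor is raised to
#'   4 robust noise SDs (estimated from successive differences) when the
#'   signal is noisy.
#' @param min_breath_interval_s Minimum separation between neural peaks.
#' @param min_ti_s Minimum neural inspiratory time (s); shorter
#'   onset-to-cycle-off intervals are rejected as noise transients.
#' @param paw_trigger_cmH2O Paw rise above PEEP that flags a pneumatic
#'   pressurization (cmH2O).
#' @param paw_cycleoff_fraction Fraction of driving pressure
#'   (peak - PEEP) above PEEP at which an assist is deemed cycled off.
#' @param smoothing_ms Width of the centered moving average applied to
#'   both signals before detection (default 48 ms, 3 samples at 62.5 Hz).
#' @param tonic_window_s Length of the sliding window for the tonic
#'   (baseline) EAdi estimate.
#' @param tonic_percentile Percentile of the sliding window used as the
#'   tonic estimate (default 0.10).
#' @param refine `"foot"` (default) refines event times by two-crossing
#'   secant extrapolation to the ramp foot (neural onset, pneumatic
#'   trigger) or the plateau-release onset (pneumatic cycle-off), giving
#'   sub-sample timing; `"crossing"` reports the interpolated threshold
#'   crossings themselves.
#'
#' @details With `refine = "foot"` the onset/trigger is located by finding
#' two interpolated crossings on the rising limb and extrapolating their
#' secant back to the baseline; at 62.5 Hz (16 ms/sample) this removes the
#' systematic lag a raw threshold crossing would add to millisecond-scale
#' timing errors.
#' @return A list of class `ns_detector_params`.
#' @export
detector_params <- function(onset_fraction = 0.10, cycleoff_fraction = 0.70,
                            min_peak_uV = 1.0, min_breath_interval_s = 0.5,
                            min_ti_s = 0.3,
                            paw_trigger_cmH2O = 1.0,
                            paw_cycleoff_fraction = 0.25,
                            smoothing_ms = 48, tonic_window_s = 10,
                            tonic_percentile = 0.10,
                            refine = c("foot", "crossing")) {
  refine <- match.arg(refine)
  p <- list(onset_fraction = onset_fraction,
            cycleoff_fraction = cycleoff_fraction,
            min_peak_uV = min_peak_uV,
            min_breath_interval_s = min_breath_interval_s,
            min_ti_s = min_ti_s,
            paw_trigger_cmH2O = paw_trigger_cmH2O,
            paw_cycleoff_fraction = paw_cycleoff_fraction,
            smoothing_ms = smoothing_ms, tonic_window_s = tonic_window_s,
            tonic_percentile = tonic_percentile, refine = refine)
  for (nm in c("onset_fraction", "cycleoff_fraction",
               "paw_cycleoff_fraction", "tonic_percentile"))
    if (!is.numeric(p[[nm]]) || p[[nm]] <= 0 || p[[nm]] >= 1)
      stop("'", nm, "' must lie in (0, 1)", call. = FALSE)
  for (nm in c("min_peak_uV", "min_breath_interval_s", "min_ti_s",
               "paw_trigger_cmH2O", "smoothing_ms", "tonic_window_s"))
    if (!is.numeric(p[[nm]]) || p[[nm]] <= 0)
      stop("'", nm, "' must be positive", call. = FALSE)
  structure(p, class = "ns_detector_params")
}

moving_average <- function(x, w) {
  if (w <= 1L) return(x)
  if (w %% 2L == 0L) w <- w + 1L
  s <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
  na <- is.na(s)
  s[na] <- x[na]
  s
}

# sliding-percentile baseline, evaluated on a coarse grid and interpolated
sliding_percentile <- function(x, fs, window_s, prob, step_s = 0.5) {
  n <- length(x)
  h <- max(1L, round(window_s * fs / 2))
  centers <- unique(c(seq(1L, n, by = max(1L, round(step_s * fs))), n))
  vals <- vapply(centers, function(i) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    stats::quantile(x[lo:hi], prob, names = FALSE, type = 7)
  }, numeric(1))
  if (length(centers) == 1L) return(rep(vals, n))
  stats::approx(centers, vals, xout = seq_len(n), rule = 2)$y
}

# interpolated time of the last upward crossing of `level` before index
# `i_hi`, searching not before `i_lo`; returns NA if absent
last_rise_crossing <- function(s, tt, level, i_lo, i_hi) {
  idx <- i_lo:i_hi
  below <- which(s[idx] <= level)
  if (!length(below)) return(NA_real_)
  j <- idx[max(below)]
  if (j >= i_hi) return(tt[j])
  num <- level - s[j]; den <- s[j + 1L] - s[j]
  tt[j] + if (den > 0) (num / den) * (tt[j + 1L] - tt[j]) else 0
}

# interpolated time of the first downward crossing of `level` after `i_lo`,
# searching up to `i_hi`
first_fall_crossing <- function(s, tt, level, i_lo, i_hi) {
  if (i_lo >= i_hi) return(NA_real_)
  idx <- (i_lo + 1L):i_hi
  below <- which(s[idx] <= level)
  if (!length(below)) return(NA_real_)
  k <- idx[min(below)]
  num <- s[k - 1L] - level; den <- s[k - 1L] - s[k]
  tt[k - 1L] + if (den > 0) (num / den) * (tt[k] - tt[k - 1L]) else 0
}

#' Detect neural breaths in an EAdi signal
#'
#' Segments the (smoothed) EAdi waveform into neural breaths. Peaks are
#' local maxima with prominence at least `min_peak_uV` above a sliding
#' low-percentile tonic baseline, separated by at least
#' `min_breath_interval_s`. For each peak, the onset is located on the
#' rising limb (backtracking to the `onset_fraction` crossing, refined to
#' the ramp foot by default) and the cycle-off is the first post-peak
#' crossing of `tonic + cycleoff_fraction * (peak - tonic)` (the 70% rule),
#' linearly interpolated between samples. Neural inspiratory time `ti_n_s`
#' runs onset to cycle-off; expiratory time `te_n_s` runs cycle-off to the
#' next onset (`NA` for the last breath).
#'
#' @param eadi A [sampled_signal()] (uV) or numeric vector.
#' @param params A [detector_params()].
#' @param fs Sampling rate, used only when `eadi` is a plain vector.
#' @return A data frame of class `ns_neural_breaths` with columns
#'   `onset_s`, `peak_s`, `cycleoff_s`, `peak_uV` (prominence above
#'   tonic), `tonic_uV`, `ti_n_s`, `te_n_s`. Zero rows when no activity
#'   is found.
#' @export
detect_neural_breaths <- function(eadi, params = detector_params(),
                                  fs = 62.5) {
  if (!inherits(eadi, "ns_signal"))
    eadi <- sampled_signal(eadi, fs = fs, name = "eadi", unit = "uV")
  if (!all(is.finite(eadi$values)))
    stop("EAdi contains non-finite samples", call. = FALSE)
  x <- eadi$values
  n <- length(x)
  tt <- signal_times(eadi)
  fs <- eadi$fs
  w <- max(1L, round(params$smoothing_ms / 1000 * fs))
  s <- moving_average(x, w)
  tonic <- sliding_percentile(s, fs, params$tonic_window_s,
                              params$tonic_percentile)

  empty <- data.frame(onset_s = numeric(0), peak_s = numeric(0),
                      cycleoff_s = numeric(0), peak_uV = numeric(0),
                      tonic_uV = numeric(0), ti_n_s = numeric(0),
                      te_n_s = numeric(0))
  class(empty) <- c("ns_neural_breaths", "data.frame")
  if (n < 5L) return(empty)

  # candidate peaks: local maxima with sufficient prominence over tonic
  core <- 2:(n - 1L)
  is_max <- s[core] > s[core - 1L] & s[core] >= s[core + 1L]
  # amplitude gate: configured minimum, raised to 4 robust noise SDs so
  # that baseline noise transients cannot register as efforts
  sigma <- stats::median(abs(diff(x))) / 0.6745 / sqrt(2)
  prom_floor <- max(params$min_peak_uV, 4 * sigma)
  cand <- core[is_max & (s[core] - tonic[core]) >= prom_floor]
  if (!length(cand)) return(empty)
  # merge candidates not separated by a sufficiently deep valley: two
  # maxima are distinct bursts only if the signal between them loses at
  # least half of the smaller one's prominence (keeps noise bumps on a
  # burst's flanks from splitting it)
  stack <- cand[1L]
  for (i in cand[-1L]) {
    repeat {
      top <- stack[length(stack)]
      valley <- min(s[top:i])
      p_top <- s[top] - tonic[top]
      p_new <- s[i] - tonic[i]
      base <- (tonic[top] + tonic[i]) / 2
      if (valley <= base + 0.5 * min(p_top, p_new)) {
        stack <- c(stack, i)          # genuinely separate bursts
        break
      }
      if (p_new > p_top) {
        stack <- stack[-length(stack)]  # flank bump superseded by new max
        if (!length(stack)) { stack <- i; break }
      } else break                      # new max is a flank bump; drop it
    }
  }
  pk <- stack
  # enforce minimum peak separation, keeping the more prominent peak
  min_gap <- params$min_breath_interval_s * fs
  if (length(pk) > 1L) {
    prom <- s[pk] - tonic[pk]
    keep_flag <- rep(TRUE, length(pk))
    for (i in seq_along(pk)[-1L]) {
      prev <- max(which(keep_flag[seq_len(i - 1L)]))
      if (pk[i] - pk[prev] < min_gap) {
        if (prom[i] > prom[prev]) keep_flag[prev] <- FALSE
        else keep_flag[i] <- FALSE
      }
    }
    pk <- pk[keep_flag]
  }

  K <- length(pk)
  onset <- peak_t <- coff <- amp <- tonics <- rep(NA_real_, K)
  bounds_lo <- c(1L, pk[-K])       # search floor: previous peak
  bounds_hi <- c(pk[-1L], n)       # search ceiling: next peak
  for (k in seq_len(K)) {
    i <- pk[k]
    T0 <- tonic[i]
    Ak <- s[i] - T0
    f1 <- params$onset_fraction
    f2 <- min(f1 + 0.30, 0.8)
    t1 <- last_rise_crossing(s, tt, T0 + f1 * Ak, bounds_lo[k], i)
    t2 <- last_rise_crossing(s, tt, T0 + f2 * Ak, bounds_lo[k], i)
    if (is.na(t1)) {
      # preceding activity never returned below the onset threshold
      # (e.g. a second burst riding on the previous decay tail): fall
      # back to the inter-peak minimum
      jmin <- which.min(s[bounds_lo[k]:i]) + bounds_lo[k] - 1L
      t1 <- tt[jmin]
      t2 <- NA_real_
    }
    on_k <- if (params$refine == "foot" && !is.na(t2) && t2 > t1)
      t1 - (t2 - t1) * f1 / (f2 - f1) else t1
    on_k <- max(on_k, tt[bounds_lo[k]])
    co_k <- first_fall_crossing(s, tt, T0 + params$cycleoff_fraction * Ak,
                                i, bounds_hi[k])
    if (is.na(co_k)) next
    onset[k] <- on_k; peak_t[k] <- tt[i]; coff[k] <- co_k
    amp[k] <- Ak; tonics[k] <- T0
  }
  ok <- !is.na(onset) & !is.na(coff) & onset < peak_t & peak_t < coff &
    (coff - onset) >= params$min_ti_s
  br <- data.frame(onset_s = onset[ok], peak_s = peak_t[ok],
                   cycleoff_s = coff[ok], peak_uV = amp[ok],
                   tonic_uV = tonics[ok])
  br$ti_n_s <- br$cycleoff_s - br$onset_s
  br$te_n_s <- c(br$onset_s[-1L], NA_real_) - br$cycleoff_s
  br <- br[is.na(br$te_n_s) | br$te_n_s > 0, , drop = FALSE]
  rownames(br) <- NULL
  class(br) <- c("ns_neural_breaths", "data.frame")
  br
}

#' Detect ventilator assists in a Paw signal
#'
#' Flags a pneumatic trigger wherever Paw shows a sustained (>= 3 samples)
#' rise of at least `paw_trigger_cmH2O` above PEEP, and a pneumatic
#' cycle-off where Paw falls back to
#' `PEEP + paw_cycleoff_fraction * (peak - PEEP)`. With the default
#' `refine = "foot"` the trigger is extrapolated to the pressurization
#' ramp foot and the cycle-off to the onset of the release from the
#' plateau; with `refine = "crossing"` the interpolated threshold
#' crossings are reported. PEEP may be given or estimated as the modal
#' Paw value rounded to 0.5 cmH2O.
#'
#' @param paw A [sampled_signal()] (cmH2O) or numeric vector.
#' @param peep PEEP in cmH2O, or `"auto"` to estimate it.
#' @param params A [detector_params()].
#' @param flow Optional flow signal used to report inspiratory peak flow.
#' @param fs Sampling rate, used only when `paw` is a plain vector.
#' @return A data frame of class `ns_vent_breaths` with columns
#'   `trigger_s`, `cycleoff_s`, `peak_paw_cmH2O`, `peak_flow_lmin`, plus
#'   an attribute `peep` (the PEEP used).
#' @export
detect_vent_breaths <- function(paw, peep = "auto",
                                params = detector_params(), flow = NULL,
                                fs = 62.5) {
  if (!inherits(paw, "ns_signal"))
    paw <- sampled_signal(paw, fs = fs, name = "paw", unit = "cmH2O")
  x <- paw$values
  n <- length(x)
  tt <- signal_times(paw)
  fs <- paw$fs
  w <- max(1L, round(params$smoothing_ms / 1000 * fs))
  s <- moving_average(x, w)
  if (identical(peep, "auto")) {
    rounded <- round(s * 2) / 2
    tb <- table(rounded)
    peep <- as.numeric(names(tb)[which.max(tb)])
  }
  if (!is.numeric(peep) || length(peep) != 1L || !is.finite(peep))
    stop("'peep' must be \"auto\" or a single number", call. = FALSE)
  if (peep >= max(s) - params$paw_trigger_cmH2O)
    stop("no pressurization detected: PEEP estimate (", peep,
         " cmH2O) reaches the signal maximum", call. = FALSE)

  empty <- data.frame(trigger_s = numeric(0), cycleoff_s = numeric(0),
                      peak_paw_cmH2O = numeric(0),
                      peak_flow_lmin = numeric(0))
  class(empty) <- c("ns_vent_breaths", "data.frame")
  attr(empty, "peep") <- peep

  above <- s >= peep + params$paw_trigger_cmH2O
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values & r$lengths >= 3L)
  if (!length(runs)) return(empty)
  run_start <- starts[runs]
  run_end <- ends[runs]

  out <- vector("list", length(runs))
  for (j in seq_along(runs)) {
    a <- run_start[j]
    reg_lo <- if (j == 1L) 1L else run_end[j - 1L] + 1L
    reg_hi <- if (j == length(runs)) n else run_start[j + 1L] - 1L
    ipk <- which.max(s[a:reg_hi]) + a - 1L
    peak <- s[ipk]
    drv <- peak - peep
    if (drv < params$paw_trigger_cmH2O) next
    # plateau level robust to noise spikes at the maximum
    hold_idx <- a:reg_hi
    hold_idx <- hold_idx[s[hold_idx] >= peep + 0.9 * drv]
    plateau <- if (length(hold_idx) >= 3L) stats::median(s[hold_idx]) else peak
    drv <- plateau - peep

    # trigger: secant through the 30% and 60% rising crossings,
    # extrapolated to the PEEP baseline (the ramp foot)
    t30 <- last_rise_crossing(s, tt, peep + 0.3 * drv, reg_lo, ipk)
    t60 <- last_rise_crossing(s, tt, peep + 0.6 * drv, reg_lo, ipk)
    tthr <- last_rise_crossing(s, tt, peep + params$paw_trigger_cmH2O,
                               reg_lo, ipk)
    trig <- if (params$refine == "foot" && !is.na(t30) && !is.na(t60) &&
                t60 > t30) t30 - (t60 - t30) else tthr
    if (is.na(trig)) next

    # cycle-off: crossings on the falling limb, extrapolated back to the
    # plateau (release onset) under "foot" refinement
    fo <- params$paw_cycleoff_fraction
    fm <- min(fo + 0.30, 0.85)
    toff <- first_fall_crossing(s, tt, peep + fo * drv, ipk, reg_hi)
    tmid <- first_fall_crossing(s, tt, peep + fm * drv, ipk, reg_hi)
    if (is.na(toff)) next
    coff <- if (params$refine == "foot" && !is.na(tmid) && toff > tmid)
      tmid - (toff - tmid) * (1 - fm) / (fm - fo) else toff
    coff <- max(coff, tt[ipk])

    pk_flow <- if (!is.null(flow)) {
      fv <- if (inherits(flow, "ns_signal")) flow$values else flow
      max(fv[a:min(reg_hi, length(fv))])
    } else NA_real_
    out[[j]] <- c(trigger_s = trig, cycleoff_s = coff,
                  peak_paw_cmH2O = max(x[a:reg_hi]),
                  peak_flow_lmin = pk_flow)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty)
  vb <- as.data.frame(do.call(rbind, out))
  vb <- vb[order(vb$trigger_s), , drop = FALSE]
  vb <- vb[vb$trigger_s < vb$cycleoff_s, , drop = FALSE]
  rownames(vb) <- NULL
  class(vb) <- c("ns_vent_breaths", "data.frame")
  attr(vb, "peep") <- peep
  vb
}

#' Neural respiratory rate
#'
#' The number of detected EAdi peaks per minute.
#'
#' @param breaths Output of [detect_neural_breaths()] (or anything with a
#'   row per breath).
#' @param duration_s Duration of the analysed signal in seconds.
#' @return Breaths per minute.
#' @export
neural_respiratory_rate <- function(breaths, duration_s) {
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("'duration_s' must be positive", call. = FALSE)
  nrow(as.data.frame(breaths)) * 60 / duration_s
}

#' Signal-quality gate for automated interaction analysis
#'
#' An EAdi signal qualifies for automated patient-ventilator interaction
#' analysis only if the median detected peak amplitude reaches a minimum
#' (default 1 uV above tonic) and at least `min_breaths` breaths were
#' detected.
#'
#' @param breaths Output of [detect_neural_breaths()].
#' @param min_median_peak_uV Minimum median peak prominence (uV).
#' @param min_breaths Minimum number of detected breaths.
#' @return A list of class `ns_quality` with elements `ok`,
#'   `median_peak_uV`, `n_breaths` and `reason`.
#' @export
check_signal_quality <- function(breaths, min_median_peak_uV = 1.0,
                                 min_breaths = 10L) {
  br <- as.data.frame(breaths)
  med <- if (nrow(br)) stats::median(br$peak_uV) else NA_real_
  ok <- TRUE; reason <- "signal quality adequate"
  if (nrow(br) < min_breaths) {
    ok <- FALSE
    reason <- sprintf("only %d breaths detected (minimum %d)",
                      nrow(br), min_breaths)
  } else if (med < min_median_peak_uV) {
    ok <- FALSE
    reason <- sprintf(
      "median peak EAdi amplitude %.2f uV below the %.2f uV minimum",
      med, min_median_peak_uV)
  }
  structure(list(ok = ok, median_peak_uV = med, n_breaths = nrow(br),
                 reason = reason), class = "ns_quality")
}

#' @export
print.ns_quality <- function(x, ...) {
  cat(sprintf("<signal quality> %s: %s\n",
              if (x$ok) "PASS" else "FAIL", x$reason))
  invisible(x)
}
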