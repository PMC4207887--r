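# Waveform simulator: quasi-periodic EAdi bursts + ventilator Paw response
# with controllable timing errors and injected asynchronies, plus exhaustive
# ground truth. Stands in for (undeposited) patient recordings.

#' Simulation configuration
#'
#' Parameters of the synthetic EAdi/Paw/flow generator. Defaults describe a
#' COPD-like NIV recording: ~25 neural breaths/min with mild period and
#' amplitude variability, peak EAdi around 25 uV over a small tonic
#' baseline, pressure support of 10 cmH2O above a PEEP of 5 cmH2O, and
#' modest additive Gaussian noise.
#'
#' @param fs Sampling rate in Hz.
#' @param duration_s Recording length in seconds.
#' @param rr_bpm Neural respiratory rate, breaths/min.
#' @param rr_cv Coefficient of variation of the breath period.
#' @param eadi_peak_uV Mean absolute peak EAdi, uV.
#' @param eadi_peak_cv Coefficient of variation of peak EAdi.
#' @param eadi_tonic_uV Tonic (baseline) EAdi level, uV; must be below
#'   `eadi_peak_uV`.
#' @param ti_n_s Neural inspiratory time in seconds: onset to the
#'   post-peak 70%-of-peak decay point.
#' @param trigger_delay_ms,trigger_delay_sd_ms Mean and SD of the
#'   ventilator trigger delay relative to neural onset (ms; may be
#'   slightly negative for auto-lead).
#' @param cycleoff_error_ms,cycleoff_error_sd_ms Mean and SD of the
#'   pneumatic-minus-neural cycle-off difference (ms; positive = late
#'   cycling off, negative = early).
#' @param ps_cmH2O Pressure-support level above PEEP, cmH2O.
#' @param peep_cmH2O PEEP baseline, cmH2O.
#' @param rise_time_s Pressurization ramp time, seconds.
#' @param p_wasted Probability that a neural effort receives no assist.
#' @param p_autotrigger Rate (events/min) of assists without neural effort.
#' @param p_double Probability a neural effort receives two assists.
#' @param p_multi_eadi Probability two EAdi bursts fall under one assist.
#' @param noise_uV,noise_cmH2O Additive Gaussian noise SDs on EAdi and Paw.
#' @param pneumatic_trigger_uV Optional absolute EAdi level (uV) emulating a
#'   closed-loop pneumatic trigger: when set, each assist triggers at the
#'   time the EAdi ramp crosses this level (overriding `trigger_delay_ms`),
#'   and efforts whose peak never reaches it become wasted. `NA` (default)
#'   disables the mechanism.
#' @param seed Optional RNG seed; identical configurations (including seed)
#'   reproduce bit-identical output.
#' @return A validated list of class `ns_sim_config`.
#' @export
sim_config <- function(fs = 62.5, duration_s = 300, rr_bpm = 25,
                       rr_cv = 0.08, eadi_peak_uV = 25, eadi_peak_cv = 0.15,
                       eadi_tonic_uV = 0.5, ti_n_s = 1.0,
                       trigger_delay_ms = 100, trigger_delay_sd_ms = 20,
                       cycleoff_error_ms = 0, cycleoff_error_sd_ms = 20,
                       ps_cmH2O = 10, peep_cmH2O = 5, rise_time_s = 0.10,
                       p_wasted = 0, p_autotrigger = 0, p_double = 0,
                       p_multi_eadi = 0, noise_uV = 0.5, noise_cmH2O = 0.3,
                       pneumatic_trigger_uV = NA_real_, seed = NULL) {
  cfg <- list(fs = fs, duration_s = duration_s, rr_bpm = rr_bpm,
              rr_cv = rr_cv, eadi_peak_uV = eadi_peak_uV,
              eadi_peak_cv = eadi_peak_cv, eadi_tonic_uV = eadi_tonic_uV,
              ti_n_s = ti_n_s, trigger_delay_ms = trigger_delay_ms,
              trigger_delay_sd_ms = trigger_delay_sd_ms,
              cycleoff_error_ms = cycleoff_error_ms,
              cycleoff_error_sd_ms = cycleoff_error_sd_ms,
              ps_cmH2O = ps_cmH2O, peep_cmH2O = peep_cmH2O,
              rise_time_s = rise_time_s, p_wasted = p_wasted,
              p_autotrigger = p_autotrigger, p_double = p_double,
              p_multi_eadi = p_multi_eadi, noise_uV = noise_uV,
              noise_cmH2O = noise_cmH2O,
              pneumatic_trigger_uV = pneumatic_trigger_uV, seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "ns_sim_config")
}

validate_sim_config <- function(cfg) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L
  pos <- c("fs", "duration_s", "rr_bpm", "eadi_peak_uV", "ti_n_s",
           "ps_cmH2O", "rise_time_s")
  for (nm in pos)
    if (!num1(cfg[[nm]]) || !is.finite(cfg[[nm]]) || cfg[[nm]] <= 0)
      stop("config error: '", nm, "' must be a positive number",
           call. = FALSE)
  nneg <- c("rr_cv", "eadi_peak_cv", "eadi_tonic_uV", "trigger_delay_sd_ms",
            "cycleoff_error_sd_ms", "noise_uV", "noise_cmH2O",
            "p_autotrigger")
  for (nm in nneg)
    if (!num1(cfg[[nm]]) || !is.finite(cfg[[nm]]) || cfg[[nm]] < 0)
      stop("config error: '", nm, "' must be non-negative", call. = FALSE)
  for (nm in c("p_wasted", "p_double", "p_multi_eadi"))
    if (!num1(cfg[[nm]]) || !is.finite(cfg[[nm]]) ||
        cfg[[nm]] < 0 || cfg[[nm]] > 1)
      stop("config error: '", nm, "' must be a probability in [0, 1]",
           call. = FALSE)
  if (cfg$eadi_tonic_uV >= cfg$eadi_peak_uV)
    stop("config error: 'eadi_tonic_uV' must be below 'eadi_peak_uV'",
         call. = FALSE)
  if (cfg$ti_n_s >= 60 / cfg$rr_bpm)
    stop("config error: 'ti_n_s' >= breath period (60/rr_bpm); ",
         "breaths would overlap", call. = FALSE)
  invisible(cfg)
}

#' Preset simulator configurations echoing ventilator-mode contrasts
#'
#' `"NAVA-like"` reflects neurally triggered and cycled assist: ~50 ms
#' trigger delay and +12 +/- 6 ms cycling-off error, no wasted efforts,
#' rare auto-triggering. `"PSV-like"` reflects pneumatically controlled
#' non-invasive assist: long and variable trigger delay (250 +/- 80 ms),
#' large early-biased cycling-off error (-95 +/- 60 ms), and 4.3% wasted
#' efforts.
#'
#' @param mode `"NAVA-like"` or `"PSV-like"`.
#' @param ... Overrides passed on to [sim_config()].
#' @return A `ns_sim_config`.
#' @export
preset_mode_config <- function(mode = c("NAVA-like", "PSV-like"), ...) {
  mode <- tryCatch(match.arg(mode), error = function(e)
    stop("config error: unknown mode '", paste(mode, collapse = ","),
         "'; expected \"NAVA-like\" or \"PSV-like\"", call. = FALSE))
  base <- switch(mode,
    "NAVA-like" = list(rr_bpm = 25, eadi_peak_uV = 24,
                       trigger_delay_ms = 50, trigger_delay_sd_ms = 15,
                       cycleoff_error_ms = 12, cycleoff_error_sd_ms = 6,
                       p_wasted = 0, p_autotrigger = 0.3,
                       p_double = 0, p_multi_eadi = 0),
    "PSV-like"  = list(rr_bpm = 23, eadi_peak_uV = 26,
                       trigger_delay_ms = 250, trigger_delay_sd_ms = 80,
                       cycleoff_error_ms = -95, cycleoff_error_sd_ms = 60,
                       p_wasted = 0.043, p_autotrigger = 0.2,
                       p_double = 0.01, p_multi_eadi = 0.01)
  )
  args <- utils::modifyList(base, list(...))
  cfg <- do.call(sim_config, args)
  attr(cfg, "preset") <- mode
  cfg
}

# run expr with a locally seeded RNG, restoring global state afterwards
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# amplitude-above-tonic of one burst evaluated at times tt (>= onset).
# Linear rise over 0.75*ti to amplitude A, exponential decay with the slow
# constant tau1 (chosen so the 70% crossing falls exactly at onset + ti),
# then a fast constant tau2 from the 55% level so the signal returns to
# tonic well before the next onset.
burst_amplitude <- function(tt, onset, ti, A) {
  rise_end <- onset + 0.75 * ti
  tau1 <- 0.25 * ti / log(1 / 0.7)
  t55 <- onset + ti + tau1 * log(0.7 / 0.55)
  tau2 <- 0.12 * ti
  out <- numeric(length(tt))
  r <- tt >= onset & tt <= rise_end
  out[r] <- A * (tt[r] - onset) / (0.75 * ti)
  d1 <- tt > rise_end & tt <= t55
  out[d1] <- A * exp(-(tt[d1] - rise_end) / tau1)
  d2 <- tt > t55
  out[d2] <- 0.55 * A * exp(-(tt[d2] - t55) / tau2)
  out
}

# place a trapezoid (above-baseline amplitude) into segment times tt
trapezoid_amplitude <- function(tt, t_on, t_off, amp, rise_s, release_s) {
  out <- numeric(length(tt))
  up <- tt >= t_on & tt < t_on + rise_s
  out[up] <- amp * (tt[up] - t_on) / rise_s
  hold <- tt >= t_on + rise_s & tt <= t_off
  out[hold] <- amp
  dn <- tt > t_off & tt < t_off + release_s
  out[dn] <- amp * (1 - (tt[dn] - t_off) / release_s)
  out
}

#' Simulate a recording with ground truth
#'
#' Generates synchronized EAdi/Paw/flow waveforms according to a
#' [sim_config()] and returns both the [recording()] and a ground-truth
#' annotation set recording every neural effort, every assist, every
#' injected asynchrony and the true per-breath trigger delay and cycle-off
#' error. Asynchrony injections are mutually exclusive per breath with
#' priority wasted > double > multiple-EAdi. The flow channel is a
#' cosmetic first-order response to (Paw - PEEP) and is never used by the
#' analysis.
#'
#' @param cfg A [sim_config()] (or [preset_mode_config()]).
#' @return A list with elements `recording` (a [recording()]) and `truth`,
#'   a list of class `ns_ground_truth` with data frames `neural_events`
#'   (`onset_s`, `peak_s`, `cycleoff_s`, `peak_uV`, `klass`), `vent_events`
#'   (`trigger_s`, `cycleoff_s`, `klass`), `labels` (`time_s`, `class`,
#'   injected asynchronies only) and `matched` (`neural_idx`, `vent_idx`,
#'   `true_trigger_delay_ms`, `true_cycleoff_error_ms`).
#' @export
simulate_recording <- function(cfg) {
  stopifnot(inherits(cfg, "ns_sim_config") || is.list(cfg))
  validate_sim_config(cfg)
  with_local_seed(cfg$seed, simulate_recording_impl(cfg))
}

simulate_recording_impl <- function(cfg) {
  fs <- cfg$fs; dt <- 1 / fs
  n <- round(cfg$duration_s * fs)
  tt <- (seq_len(n) - 1) * dt
  ti <- cfg$ti_n_s
  period <- 60 / cfg$rr_bpm

  # --- breath timing ------------------------------------------------------
  n_max <- ceiling(cfg$duration_s / period * 1.6) + 8L
  z_per <- stats::rnorm(n_max)
  periods <- pmax(period * (1 + cfg$rr_cv * z_per), ti * 1.15)
  onsets_all <- 0.5 + cumsum(c(0, periods[-n_max]))
  keep <- onsets_all <= cfg$duration_s - ti - 0.5
  onsets <- onsets_all[keep]
  K <- length(onsets)
  if (K < 1L)
    stop("config error: recording too short for a single breath",
         call. = FALSE)
  next_onset <- c(onsets[-1L], cfg$duration_s)

  # --- per-breath draws (fixed order so parameter changes do not shift
  #     the RNG stream; probabilities compared against uniforms for
  #     monotone coupling across parameter grids) -------------------------
  z_amp    <- stats::rnorm(n_max)[seq_len(K)]
  u_wasted <- stats::runif(n_max)[seq_len(K)]
  u_double <- stats::runif(n_max)[seq_len(K)]
  u_multi  <- stats::runif(n_max)[seq_len(K)]
  u_auto   <- stats::runif(n_max)[seq_len(K)]
  u_apos   <- stats::runif(n_max)[seq_len(K)]
  z_delay  <- stats::rnorm(n_max)[seq_len(K)]
  z_coff   <- stats::rnorm(n_max)[seq_len(K)]

  tonic <- cfg$eadi_tonic_uV
  A <- pmax(cfg$eadi_peak_uV * (1 + cfg$eadi_peak_cv * z_amp) - tonic, 0.25)
  peaks_abs <- tonic + A

  delay_s <- (cfg$trigger_delay_ms + cfg$trigger_delay_sd_ms * z_delay) / 1000
  coff_s  <- (cfg$cycleoff_error_ms + cfg$cycleoff_error_sd_ms * z_coff) / 1000

  # closed-loop pneumatic trigger: assist fires when the EAdi ramp crosses
  # an absolute level; efforts that never reach it are wasted
  closed_loop <- is.finite(cfg$pneumatic_trigger_uV)
  cl_wasted <- rep(FALSE, K)
  if (closed_loop) {
    thr <- cfg$pneumatic_trigger_uV
    cl_wasted <- peaks_abs <= thr
    frac <- pmax((thr - tonic) / A, 0)
    delay_s <- 0.75 * ti * pmin(frac, 1)
  }

  wasted <- (u_wasted < cfg$p_wasted) | cl_wasted
  te_k <- next_onset - (onsets + ti)
  dbl <- !wasted & (u_double < cfg$p_double)
  # second burst starts 0.4 s after neural cycle-off (brief pause, so the
  # two bursts are separated by a real valley) and must fit in expiration
  multi_ok <- te_k >= 0.4 + 0.6 * ti + 0.45
  multi <- !wasted & !dbl & (u_multi < cfg$p_multi_eadi) & multi_ok
  p_auto_gap <- min(cfg$p_autotrigger / cfg$rr_bpm, 1)
  auto <- (u_auto < p_auto_gap) & !multi

  # --- EAdi assembly ------------------------------------------------------
  amp <- numeric(n)
  add_burst <- function(amp, onset, ti_b, A_b) {
    t_end <- min(onset + ti_b + 0.169 * ti_b + 0.12 * ti_b *
                   log(max(0.55 * A_b, 1e-6) / 1e-3), cfg$duration_s)
    i0 <- max(1L, floor(onset * fs) + 1L)
    i1 <- min(n, ceiling(t_end * fs) + 1L)
    idx <- i0:i1
    amp[idx] <- pmax(amp[idx], burst_amplitude(tt[idx], onset, ti_b, A_b))
    amp
  }
  for (k in seq_len(K)) amp <- add_burst(amp, onsets[k], ti, A[k])

  # second EAdi burst under one long assist (multiple-EAdi injection)
  ti2 <- 0.6 * ti
  o2 <- onsets + ti + 0.4
  A2 <- 0.8 * A
  for (k in which(multi)) amp <- add_burst(amp, o2[k], ti2, A2[k])

  # --- ventilator events --------------------------------------------------
  rise <- cfg$rise_time_s
  release <- max(0.08, rise)
  vt <- list()  # trigger_s, cycleoff_s, klass, neural_idx
  add_vent <- function(trig, coff, klass, nidx) {
    coff <- max(coff, trig + rise + 2 * dt)
    vt[[length(vt) + 1L]] <<- list(trigger_s = trig, cycleoff_s = coff,
                                   klass = klass, neural_idx = nidx,
                                   rise_s = rise, release_s = release)
  }
  for (k in seq_len(K)) {
    if (wasted[k]) next
    trig <- onsets[k] + delay_s[k]
    ncoff <- onsets[k] + ti
    vcoff <- ncoff + coff_s[k]
    if (multi[k]) vcoff <- max(vcoff, o2[k] + ti2)
    if (dbl[k]) {
      span <- vcoff - trig
      h1 <- max(0.35 * span, rise + 3 * dt)
      gap <- 0.2
      t2 <- trig + h1 + release + gap
      if (t2 + rise + 2 * dt < vcoff) {
        add_vent(trig, trig + h1, "double_trigger", k)
        add_vent(t2, vcoff, "double_trigger", k)
      } else {
        add_vent(trig, vcoff, "matched", k)  # too tight; degrade to single
        dbl[k] <- FALSE
      }
    } else {
      add_vent(trig, vcoff, if (multi[k]) "multi_eadi" else "matched", k)
    }
  }
  # auto-triggered assists in expiratory gaps, dissociated from EAdi
  for (k in seq_len(K)) {
    if (!auto[k]) next
    ncoff <- onsets[k] + ti
    g0 <- ncoff + (0.55 + 0.25 * u_apos[k]) * te_k[k]
    g_end <- g0 + 0.08 + 0.15 + 0.10
    prev_end <- if (wasted[k]) ncoff else ncoff + max(coff_s[k], 0) + release
    if (g0 > prev_end + 0.1 && g_end < next_onset[k] - 0.15) {
      vt[[length(vt) + 1L]] <- list(trigger_s = g0, cycleoff_s = g0 + 0.23,
                                    klass = "auto_trigger", neural_idx = NA,
                                    rise_s = 0.08, release_s = 0.10)
    } else auto[k] <- FALSE
  }

  # --- Paw assembly -------------------------------------------------------
  paw_amp <- numeric(n)
  for (v in vt) {
    i0 <- max(1L, floor(v$trigger_s * fs) + 1L)
    i1 <- min(n, ceiling((v$cycleoff_s + v$release_s) * fs) + 1L)
    if (i0 > n) next
    idx <- i0:i1
    paw_amp[idx] <- pmax(paw_amp[idx],
                         trapezoid_amplitude(tt[idx], v$trigger_s,
                                             v$cycleoff_s, cfg$ps_cmH2O,
                                             v$rise_s, v$release_s))
  }

  eadi <- tonic + amp
  if (cfg$noise_uV > 0) eadi <- eadi + stats::rnorm(n, 0, cfg$noise_uV)
  eadi <- pmax(eadi, 0)
  paw <- cfg$peep_cmH2O + paw_amp
  if (cfg$noise_cmH2O > 0) paw <- paw + stats::rnorm(n, 0, cfg$noise_cmH2O)

  # cosmetic flow: first-order response to (Paw - PEEP)
  tau_f <- 0.1
  alpha <- exp(-dt / tau_f)
  flow <- as.numeric(stats::filter((1 - alpha) * 6 * paw_amp, alpha,
                                   method = "recursive"))

  # --- ground truth -------------------------------------------------------
  nklass <- ifelse(wasted, "wasted_effort",
            ifelse(dbl, "double_trigger",
            ifelse(multi, "multi_eadi", "matched")))
  neural <- data.frame(
    onset_s = onsets, peak_s = onsets + 0.75 * ti,
    cycleoff_s = onsets + ti, peak_uV = peaks_abs, klass = nklass,
    stringsAsFactors = FALSE
  )
  if (any(multi)) {
    extra <- data.frame(
      onset_s = o2[multi], peak_s = o2[multi] + 0.75 * ti2,
      cycleoff_s = o2[multi] + ti2, peak_uV = tonic + A2[multi],
      klass = "multi_eadi", stringsAsFactors = FALSE
    )
    neural <- rbind(neural, extra)
    neural <- neural[order(neural$onset_s), , drop = FALSE]
    rownames(neural) <- NULL
  }
  vent <- if (length(vt)) data.frame(
    trigger_s = vapply(vt, `[[`, numeric(1), "trigger_s"),
    cycleoff_s = vapply(vt, `[[`, numeric(1), "cycleoff_s"),
    klass = vapply(vt, `[[`, character(1), "klass"),
    neural_idx = vapply(vt, function(v) as.numeric(v$neural_idx), numeric(1)),
    stringsAsFactors = FALSE
  ) else data.frame(trigger_s = numeric(0), cycleoff_s = numeric(0),
                    klass = character(0), neural_idx = numeric(0))
  vent <- vent[order(vent$trigger_s), , drop = FALSE]
  rownames(vent) <- NULL

  m_idx <- which(nklass == "matched")
  matched <- data.frame(
    neural_idx = m_idx,
    vent_idx = match(m_idx, vent$neural_idx),
    true_trigger_delay_ms = 1000 * delay_s[m_idx],
    true_cycleoff_error_ms = 1000 * coff_s[m_idx]
  )
  lab_n <- neural[neural$klass != "matched", c("onset_s", "klass")]
  lab_v <- vent[vent$klass == "auto_trigger", c("trigger_s", "klass")]
  labels <- rbind(
    data.frame(time_s = lab_n$onset_s, class = lab_n$klass,
               stringsAsFactors = FALSE),
    data.frame(time_s = lab_v$trigger_s, class = lab_v$klass,
               stringsAsFactors = FALSE)
  )
  labels <- labels[order(labels$time_s), , drop = FALSE]
  rownames(labels) <- NULL

  truth <- structure(
    list(neural_events = neural, vent_events = vent, labels = labels,
         matched = matched,
         counts = c(n_neural = nrow(neural), n_vent = nrow(vent),
                    n_matched = nrow(matched),
                    n_wasted = sum(nklass == "wasted_effort"),
                    n_auto = sum(vent$klass == "auto_trigger"),
                    n_double = sum(dbl), n_multi = sum(multi))),
    class = "ns_ground_truth"
  )

  rec <- recording(
    eadi = eadi, paw = paw, flow = flow, fs = fs, t0 = 0,
    meta = list(fs_hz = fs, peep_cmh2o = cfg$peep_cmH2O,
                mode = attr(cfg, "preset") %||% "simulated",
                subject = NA_character_, simulated = TRUE)
  )
  list(recording = rec, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
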