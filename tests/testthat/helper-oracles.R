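# Shared fixtures and independent oracle implementations used by the
# tests. Oracles deliberately use straightforward loops, separate from
# the package's vectorised code paths.

# build a consistent neural-breath table from onset/cycle-off vectors
make_neural <- function(onset, cycleoff, peak = NULL, peak_uV = 20) {
  stopifnot(length(onset) == length(cycleoff))
  if (is.null(peak)) peak <- (onset + cycleoff) / 2
  data.frame(
    onset_s = onset, peak_s = peak, cycleoff_s = cycleoff,
    peak_uV = peak_uV, tonic_uV = 0,
    ti_n_s = cycleoff - onset,
    te_n_s = c(onset[-1L], NA_real_) - cycleoff
  )
}

make_vent <- function(trigger, cycleoff, peak_paw = 15) {
  data.frame(trigger_s = trigger, cycleoff_s = cycleoff,
             peak_paw_cmH2O = rep_len(peak_paw, length(trigger)),
             peak_flow_lmin = rep_len(NA_real_, length(trigger)))
}

# n_match perfectly timed matched breaths followed by n_wasted efforts
perfect_records <- function(n_match, n_wasted, period = 3, ti = 1) {
  n <- n_match + n_wasted
  onset <- period * (seq_len(n) - 1)
  nb <- make_neural(onset, onset + ti)
  keep <- seq_len(n_match)
  vb <- make_vent(nb$onset_s[keep], nb$cycleoff_s[keep])
  score_breaths(match_events(nb, vb))
}

# simple trapezoid waveform for detector arithmetic tests
trapezoid_wave <- function(tt, on, off, amp, rise, release) {
  out <- numeric(length(tt))
  up <- tt >= on & tt < on + rise
  out[up] <- amp * (tt[up] - on) / rise
  out[tt >= on + rise & tt <= off] <- amp
  dn <- tt > off & tt < off + release
  out[dn] <- amp * (1 - (tt[dn] - off) / release)
  out
}

# independent rule-based classifier (plain loops over events)
brute_match <- function(nb, vb, slack = 0.15, af = 0.5) {
  Kn <- nrow(nb); Kv <- nrow(vb)
  assigned <- rep(NA_integer_, Kv)
  for (v in seq_len(Kv)) {
    trig <- vb$trigger_s[v]
    i_cand <- NA_integer_
    for (i in seq_len(Kn))
      if (nb$onset_s[i] - slack <= trig) i_cand <- i
    if (is.na(i_cand)) next  # before first interval -> auto
    te_i <- nb$te_n_s[i_cand]
    if (is.finite(te_i) && trig > nb$cycleoff_s[i_cand] + af * te_i)
      next                   # dissociated -> auto
    assigned[v] <- i_cand
  }
  klass <- character(Kn)
  for (i in seq_len(Kn)) {
    nv <- sum(assigned == i, na.rm = TRUE)
    klass[i] <- if (nv == 0L) "wasted_effort"
                else if (nv >= 2L) "double_trigger" else "matched"
  }
  for (i in seq_len(Kn)) {
    if (klass[i] != "matched") next
    v <- which(assigned == i)[1L]
    covered <- which(nb$peak_s >= vb$trigger_s[v] &
                     nb$peak_s <= vb$cycleoff_s[v])
    if (length(covered) >= 2L) {
      klass[i] <- "multi_eadi"
      for (j in setdiff(covered, i))
        if (klass[j] == "wasted_effort") klass[j] <- "multi_eadi"
    }
  }
  list(klass = klass, assigned = assigned,
       n_auto = sum(is.na(assigned)))
}

# maximum-cardinality legal matching by exhaustive recursion
max_matching_size <- function(legal) {
  Kn <- nrow(legal); Kv <- ncol(legal)
  if (Kn == 0L || Kv == 0L) return(0L)
  best <- 0L
  recurse <- function(v, used_n, size) {
    if (v > Kv) { best <<- max(best, size); return(invisible()) }
    recurse(v + 1L, used_n, size)  # leave v unmatched
    for (i in seq_len(Kn))
      if (legal[i, v] && !used_n[i]) {
        used_n[i] <- TRUE
        recurse(v + 1L, used_n, size + 1L)
        used_n[i] <- FALSE
      }
  }
  recurse(1L, rep(FALSE, Kn), 0L)
  best
}

# random small matching instance with consistent neural geometry
random_instance <- function(n_max = 6L, v_max = 6L) {
  Kn <- sample.int(n_max, 1L)
  Kv <- sample.int(v_max + 1L, 1L) - 1L
  onset <- sort(stats::runif(Kn, 0, 20))
  gaps <- diff(c(onset, 22))
  ti <- pmin(0.5 * gaps, stats::runif(Kn, 0.3, 1.2))
  nb <- make_neural(onset, onset + ti)
  if (Kv > 0L) {
    trig <- sort(stats::runif(Kv, -1, 22))
    vb <- make_vent(trig, trig + stats::runif(Kv, 0.2, 1))
  } else vb <- make_vent(numeric(0), numeric(0))
  list(nb = nb, vb = vb)
}

# exact Friedman permutation p-value by expand.grid enumeration
# (independent of the package's odometer loop)
brute_friedman_exact <- function(ranks) {
  n <- nrow(ranks); k <- ncol(ranks)
  stat_of <- function(rm) {
    Rj <- colSums(rm)
    12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
  }
  obs <- stat_of(ranks)
  perms <- as.matrix(expand.grid(rep(list(seq_len(factorial(k))), n)))
  all_orders <- matrix(unlist(combinat_perms(seq_len(k))), ncol = k,
                       byrow = TRUE)
  cnt <- 0L
  for (r in seq_len(nrow(perms))) {
    rm <- ranks
    for (b in seq_len(n)) rm[b, ] <- ranks[b, all_orders[perms[r, b], ]]
    if (stat_of(rm) >= obs - 1e-12) cnt <- cnt + 1L
  }
  cnt / nrow(perms)
}

combinat_perms <- function(v) {
  if (length(v) == 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in combinat_perms(v[-i])) out <- c(out, list(c(v[i], p)))
  out
}
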