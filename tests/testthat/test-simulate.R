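test_that("perfect-synchrony construction yields one assist per effort", {
  cfg <- sim_config(duration_s = 60, rr_bpm = 20, rr_cv = 0,
                    trigger_delay_ms = 0, trigger_delay_sd_ms = 0,
                    cycleoff_error_ms = 0, cycleoff_error_sd_ms = 0,
                    noise_uV = 0, noise_cmH2O = 0, seed = 1)
  sim <- simulate_recording(cfg)
  expect_equal(nrow(sim$truth$neural_events), 20L)
  expect_equal(nrow(sim$truth$vent_events), 20L)
  expect_equal(sim$truth$matched$true_trigger_delay_ms, rep(0, 20))
  expect_equal(sim$truth$matched$true_cycleoff_error_ms, rep(0, 20))
})

test_that("degenerate delay distribution injects exactly the configured delay", {
  cfg <- sim_config(duration_s = 120, trigger_delay_ms = 100,
                    trigger_delay_sd_ms = 0, noise_uV = 0,
                    noise_cmH2O = 0, seed = 2)
  sim <- simulate_recording(cfg)
  expect_true(all(sim$truth$matched$true_trigger_delay_ms == 100))
})

test_that("wasted-effort injection matches its probability and bookkeeping", {
  cfg <- sim_config(duration_s = 300, rr_bpm = 20, p_wasted = 0.5, seed = 7)
  sim <- simulate_recording(cfg)
  tr <- sim$truth
  n <- nrow(tr$neural_events)
  nw <- sum(tr$neural_events$klass == "wasted_effort")
  # binomial 95% band around p = 0.5
  expect_lt(abs(nw / n - 0.5), 1.96 * sqrt(0.25 / n) + 0.5 / n)
  # wasted efforts have no paired vent event
  expect_false(any(tr$matched$neural_idx %in%
                     which(tr$neural_events$klass == "wasted_effort")))
  # event bookkeeping: vent events = matched + 2*doubles + autos
  cnt <- tr$counts
  expect_equal(unname(cnt["n_vent"]),
               unname(cnt["n_matched"] + 2 * cnt["n_double"] +
                        cnt["n_multi"] + cnt["n_auto"]))
  expect_equal(unname(cnt["n_neural"]),
               unname(cnt["n_matched"] + cnt["n_wasted"] +
                        cnt["n_double"] + 2 * cnt["n_multi"]))
})

test_that("identical configurations reproduce bit-identical output", {
  cfg <- preset_mode_config("PSV-like", seed = 11, duration_s = 60)
  a <- simulate_recording(cfg)
  b <- simulate_recording(cfg)
  expect_identical(a$recording$eadi$values, b$recording$eadi$values)
  expect_identical(a$recording$paw$values, b$recording$paw$values)
  expect_identical(a$truth, b$truth)
})

test_that("noiseless EAdi crosses 70% of peak exactly at onset + ti_n", {
  cfg <- sim_config(duration_s = 60, rr_bpm = 15, rr_cv = 0,
                    eadi_peak_cv = 0, noise_uV = 0, noise_cmH2O = 0,
                    seed = 3)
  sim <- simulate_recording(cfg)
  e <- sim$recording$eadi
  tt <- signal_times(e)
  tonic <- cfg$eadi_tonic_uV
  for (k in seq_len(nrow(sim$truth$neural_events))) {
    ev <- sim$truth$neural_events[k, ]
    target <- tonic + 0.70 * (ev$peak_uV - tonic)
    v <- stats::approx(tt, e$values, xout = ev$cycleoff_s)$y
    # within one sample's interpolation error on the exponential decay
    slope <- 0.70 * (ev$peak_uV - tonic) / (0.25 * cfg$ti_n_s / log(1 / 0.7))
    expect_lt(abs(v - target), slope / e$fs)
  }
})

test_that("preset configurations encode the mode contrast", {
  nava <- preset_mode_config("NAVA-like")
  expect_equal(nava$trigger_delay_ms, 50)
  expect_equal(nava$cycleoff_error_ms, 12)
  expect_equal(nava$p_wasted, 0)
  psv <- preset_mode_config("PSV-like")
  expect_gt(psv$trigger_delay_ms, nava$trigger_delay_ms)
  expect_gt(psv$p_wasted, 0)
  expect_equal(abs(psv$cycleoff_error_ms), 95)
  expect_error(preset_mode_config("HFO"), "config error")
})

test_that("invalid configurations are rejected before simulation", {
  expect_error(sim_config(p_wasted = 1.5), "probability")
  expect_error(sim_config(ti_n_s = 3, rr_bpm = 25), "overlap")
  expect_error(sim_config(eadi_tonic_uV = 30, eadi_peak_uV = 25), "below")
  expect_error(sim_config(fs = -1), "positive")
})

test_that("closed-loop pneumatic trigger converts weak efforts into wasted ones", {
  cfg <- sim_config(duration_s = 120, eadi_peak_uV = 15, eadi_peak_cv = 0.3,
                    pneumatic_trigger_uV = 14, seed = 5)
  sim <- simulate_recording(cfg)
  tr <- sim$truth
  weak <- tr$neural_events$peak_uV <= 14
  expect_equal(tr$neural_events$klass[weak],
               rep("wasted_effort", sum(weak)))
  expect_gt(sum(weak), 0)
  # triggered assists fire when the ramp reaches the threshold
  m <- tr$matched
  ne <- tr$neural_events[m$neural_idx, ]
  frac <- (14 - cfg$eadi_tonic_uV) / (ne$peak_uV - cfg$eadi_tonic_uV)
  expect_equal(m$true_trigger_delay_ms,
               1000 * 0.75 * cfg$ti_n_s * pmax(pmin(frac, 1), 0),
               tolerance = 1e-9)
})
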