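test_that("neural cycle-off falls at the 70%-of-peak descending crossing", {
  # triangular pulse 0 -> 10 -> 0 uV over 1 s, zero tonic baseline
  fs <- 62.5
  tt <- seq(0, 3, by = 1 / fs)
  x <- pmax(0, 10 * (1 - abs(tt - 1.5) / 0.5))
  nb <- detect_neural_breaths(x, detector_params(smoothing_ms = 1), fs = fs)
  expect_equal(nrow(nb), 1L)
  # descending limb passes 7.0 uV at t = 1.65 s
  expect_equal(nb$cycleoff_s, 1.65, tolerance = 1 / fs)
  expect_equal(nb$peak_s, 1.5, tolerance = 1 / fs)
})

test_that("a flat signal yields no breaths and non-finite input errors", {
  expect_equal(nrow(detect_neural_breaths(rep(0, 1000))), 0L)
  expect_equal(nrow(detect_neural_breaths(rep(3.7, 1000))), 0L)
  expect_error(detect_neural_breaths(c(rep(0, 10), NaN)), "non-finite")
})

test_that("pneumatic cycle-off uses the configured driving-pressure fraction", {
  # trapezoid: PEEP 5 -> 15 cmH2O, steep ramps; crossing of
  # 5 + 0.25 * 10 = 7.5 cmH2O on the way down
  fs <- 62.5
  tt <- seq(0, 10, by = 1 / fs)
  paw <- 5 + trapezoid_wave(tt, on = 4, off = 5.5, amp = 10,
                            rise = 0.1, release = 0.4)
  p_cross <- detector_params(refine = "crossing", smoothing_ms = 1)
  vb <- detect_vent_breaths(paw, peep = 5, params = p_cross, fs = fs)
  expect_equal(nrow(vb), 1L)
  # release starts at 5.5 s, falls to 7.5 at 5.5 + 0.4*(1-0.25) = 5.8 s
  expect_equal(vb$cycleoff_s, 5.8, tolerance = 1.5 / fs)
  expect_equal(vb$peak_paw_cmH2O, 15, tolerance = 0.1)

  # foot refinement recovers the ramp start and release onset themselves
  vb2 <- detect_vent_breaths(paw, peep = 5,
                             params = detector_params(smoothing_ms = 1),
                             fs = fs)
  expect_equal(vb2$trigger_s, 4.0, tolerance = 1 / fs)
  expect_equal(vb2$cycleoff_s, 5.5, tolerance = 1.5 / fs)
})

test_that("constant Paw has no assists and flags absent pressurization", {
  expect_error(detect_vent_breaths(rep(5, 1000), peep = "auto"),
               "no pressurization")
  expect_error(detect_vent_breaths(rep(5, 1000), peep = 5),
               "no pressurization")
})

test_that("detection is invariant to Paw offset and EAdi scaling", {
  sim <- simulate_recording(preset_mode_config("PSV-like", seed = 9,
                                               duration_s = 120))
  paw <- sim$recording$paw$values
  vb0 <- detect_vent_breaths(paw, peep = "auto")
  vb1 <- detect_vent_breaths(paw + 3.2, peep = "auto")
  # the auto PEEP estimate quantizes at 0.5 cmH2O, so event times agree
  # at sub-sample (not floating-point) precision
  expect_lt(max(abs(vb1$trigger_s - vb0$trigger_s)), 0.005)
  expect_lt(max(abs(vb1$cycleoff_s - vb0$cycleoff_s)), 0.005)

  eadi <- sim$recording$eadi$values
  nb0 <- detect_neural_breaths(eadi)
  for (sc in c(0.5, 2, 10)) {
    nbs <- detect_neural_breaths(eadi * sc)
    expect_equal(nbs$onset_s, nb0$onset_s, tolerance = 1e-6)
    expect_equal(nbs$cycleoff_s, nb0$cycleoff_s, tolerance = 1e-6)
    expect_equal(nbs$peak_uV, nb0$peak_uV * sc, tolerance = 1e-6)
  }
})

test_that("breath count matches ground truth with noise up to 5% of peak", {
  for (mode in c("NAVA-like", "PSV-like")) {
    peak <- if (mode == "NAVA-like") 24 else 26
    for (sd in 1:3) {
      cfg <- preset_mode_config(mode, seed = sd, duration_s = 120,
                                noise_uV = 0.05 * peak, p_wasted = 0,
                                p_autotrigger = 0, p_double = 0,
                                p_multi_eadi = 0)
      sim <- simulate_recording(cfg)
      nb <- detect_neural_breaths(sim$recording$eadi)
      expect_equal(nrow(nb), nrow(sim$truth$neural_events),
                   info = paste(mode, "seed", sd))
      expect_true(all(nb$cycleoff_s > nb$peak_s))
    }
  }
})

test_that("neural respiratory rate is peaks per minute", {
  br <- make_neural(seq(0, by = 2.4, length.out = 125),
                    seq(1, by = 2.4, length.out = 125))
  expect_equal(neural_respiratory_rate(br, 300), 25.0)
  expect_equal(neural_respiratory_rate(br[0, ], 300), 0.0)
  expect_error(neural_respiratory_rate(br, 0), "positive")

  cfg <- sim_config(duration_s = 300, rr_bpm = 22.7, rr_cv = 0, seed = 1)
  sim <- simulate_recording(cfg)
  nb <- detect_neural_breaths(sim$recording$eadi)
  expect_equal(neural_respiratory_rate(nb, 300), 22.7,
               tolerance = 0.3)  # one-breath quantization at the edges
})

test_that("the quality gate screens amplitude and breath count", {
  good <- make_neural(seq(0, by = 3, length.out = 20),
                      seq(1, by = 3, length.out = 20), peak_uV = 25.6)
  expect_true(check_signal_quality(good)$ok)

  faint <- good; faint$peak_uV <- 0.3
  v <- check_signal_quality(faint)
  expect_false(v$ok)
  expect_match(v$reason, "amplitude")

  few <- good[1:5, ]
  v2 <- check_signal_quality(few)
  expect_false(v2$ok)
  expect_match(v2$reason, "breaths")
})
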