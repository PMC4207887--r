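test_that("one-to-one, wasted and double assignments classify correctly", {
  nb <- make_neural(c(0), c(1))
  vb <- make_vent(0.2, 1.1)
  r <- match_events(nb, vb)
  expect_equal(r$klass, "matched")

  r2 <- match_events(nb, make_vent(numeric(0), numeric(0)))
  expect_equal(r2$klass, "wasted_effort")
  expect_equal(score_breaths(r2)$breath_error_pct, 100)

  # 3 neural breaths, 4 triggers with two in breath 2's interval
  nb3 <- make_neural(c(0, 3, 6), c(1, 4, 7))
  vb4 <- make_vent(c(0.2, 3.2, 3.9, 6.2), c(1, 3.7, 4.4, 7))
  r3 <- match_events(nb3, vb4)
  expect_equal(r3$klass, c("matched", "double_trigger", "matched"))
  expect_equal(r3$n_vent, c(1L, 2L, 1L))
})

test_that("dissociated and uncovered assists become auto-triggers", {
  nb <- make_neural(c(0, 4), c(1, 5))
  # trigger in breath 1's expiration beyond cycleoff + te/2 (te = 3)
  vb <- make_vent(c(0.1, 2.8), c(0.9, 3.2))
  r <- match_events(nb, vb)
  expect_equal(sort(r$klass),
               c("auto_trigger", "matched", "wasted_effort"))
  # trigger before any neural interval
  r2 <- match_events(nb, make_vent(-2, -1.5))
  expect_true("auto_trigger" %in% r2$klass)
})

test_that("two neural peaks under one assist mark multiple-EAdi", {
  nb <- make_neural(c(0, 1.8), c(1, 2.8))
  vb <- make_vent(0.2, 3.0)  # single long assist covering both peaks
  r <- match_events(nb, vb)
  expect_equal(r$klass, c("multi_eadi", "multi_eadi"))
  expect_equal(score_breaths(r)$breath_error_pct, c(100, 100))
})

test_that("trigger error follows the percentage-of-ti definition", {
  r <- perfect_records(2, 0)
  r$trigger_s[1] <- 0.2  # onset 0, ti 1
  te <- trigger_error(r[1, ])
  expect_equal(te$trigger_error_pct, 20)
  expect_equal(te$trigger_delay_ms, 200)
  expect_equal(trigger_error(r[2, ])$trigger_error_pct, 0)
  ww <- match_events(make_neural(0, 1), make_vent(numeric(0), numeric(0)))
  expect_error(trigger_error(ww[1, ]), "matched")
})

test_that("cycle-off error is signed: positive late, negative early", {
  r <- perfect_records(2, 0)  # neural cycle-off 1.0, te 2.0
  r$vent_cycleoff_s[1] <- 0.9
  ce <- cycleoff_error(r[1, ])
  expect_equal(ce$cycleoff_error_pct, -5)   # early
  expect_equal(ce$cycleoff_error_ms, -100)
  r$vent_cycleoff_s[1] <- 1.3
  expect_equal(cycleoff_error(r[1, ])$cycleoff_error_pct, 15)  # late
  r$vent_cycleoff_s[1] <- 1.0
  expect_equal(cycleoff_error(r[1, ])$cycleoff_error_pct, 0)
  expect_error(cycleoff_error(r[2, ]), "te_n")  # last breath undefined
})

test_that("per-breath error combines magnitudes and caps at 100", {
  r <- perfect_records(2, 0)[1, ]
  r$trigger_error_pct <- 20; r$cycleoff_error_pct <- -10
  expect_equal(breath_error(r), 15)
  expect_equal(breath_error(r, combine = "max"), 20)
  r$trigger_error_pct <- 0; r$cycleoff_error_pct <- 0
  expect_equal(breath_error(r), 0)
  w <- match_events(make_neural(0, 1), make_vent(numeric(0), numeric(0)))
  expect_equal(breath_error(w[1, ]), 100)
})

test_that("the NeuroSync index is the mean per-breath error", {
  r <- perfect_records(3, 0)
  r$breath_error_pct <- c(0, 0, 100)
  expect_equal(neurosync_index(r), 100 / 3)
  r$breath_error_pct <- c(0, 0, 0)
  expect_equal(neurosync_index(r), 0)
  expect_error(neurosync_index(r[0, ]), "undefined")
})

test_that("classification counts survive order shuffling of the inputs", {
  sim <- simulate_recording(preset_mode_config("PSV-like", seed = 21,
                                               duration_s = 120))
  nb <- detect_neural_breaths(sim$recording$eadi)
  vb <- detect_vent_breaths(sim$recording$paw)
  r0 <- match_events(nb, vb)
  set.seed(1)
  nb2 <- nb[sample(nrow(nb)), ]; nb2 <- nb2[order(nb2$onset_s), ]
  vb2 <- vb[sample(nrow(vb)), ]; vb2 <- vb2[order(vb2$trigger_s), ]
  r1 <- match_events(nb2, vb2)
  expect_equal(table(r1$klass), table(r0$klass))
  expect_error(match_events(nb[rev(seq_len(nrow(nb))), ], vb), "ordered")
})

test_that("build_report aggregates counts, proportions and density", {
  r <- perfect_records(90, 10)
  rep <- build_report(r, duration_s = 300)
  expect_equal(rep$n_breaths, 100L)
  expect_equal(unname(rep$counts["matched"]), 90L)
  expect_equal(unname(rep$counts["wasted_effort"]), 10L)
  expect_equal(rep$neurosync_pct, 10.0)
  expect_equal(rep$neurosync_no_wasted_pct, 0.0)
  expect_equal(rep$pct_synchronous, 90)
  expect_equal(rep$pct_dyssynchronous, 0)
  expect_equal(rep$pct_asynchronous, 10)
  expect_equal(rep$wasted_per_min, 2)
  expect_equal(sum(rep$density_grid$counts), 90L)
  expect_equal(rep$pct_synchronous + rep$pct_dyssynchronous +
                 rep$pct_asynchronous, 100)

  # recomputing the mean of per-breath errors reproduces the index
  expect_equal(mean(rep$per_breath$breath_error_pct), rep$neurosync_pct,
               tolerance = 1e-9)

  empty <- build_report(r[0, ], duration_s = 300)
  expect_equal(empty$n_breaths, 0L)
  expect_true(is.na(empty$neurosync_pct))
})

test_that("every simulated asynchrony type is recovered end to end", {
  cfg <- sim_config(duration_s = 300, p_double = 0.15, p_multi_eadi = 0.15,
                    p_wasted = 0.1, p_autotrigger = 2,
                    trigger_delay_ms = 120, trigger_delay_sd_ms = 30,
                    cycleoff_error_ms = -50, cycleoff_error_sd_ms = 30,
                    seed = 5)
  sim <- simulate_recording(cfg)
  fit <- neurosync(sim$recording, window_s = 300)
  cnt <- sim$truth$counts
  expect_equal(unname(fit$counts["wasted_effort"]),
               unname(cnt["n_wasted"]))
  expect_equal(unname(fit$counts["auto_trigger"]), unname(cnt["n_auto"]))
  expect_equal(unname(fit$counts["double_trigger"]),
               unname(cnt["n_double"]))
  expect_equal(unname(fit$counts["multi_eadi"]),
               unname(2 * cnt["n_multi"]))
  expect_equal(unname(fit$counts["matched"]), unname(cnt["n_matched"]))
})
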