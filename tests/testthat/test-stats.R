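test_that("summarize_mode contrasts presets and refuses poor signals", {
  nava <- simulate_recording(preset_mode_config("NAVA-like", seed = 31,
                                                duration_s = 320))
  psv <- simulate_recording(preset_mode_config("PSV-like", seed = 31,
                                               duration_s = 320))
  mn <- summarize_mode(nava$recording, window_s = 300)
  mp <- summarize_mode(psv$recording, window_s = 300)
  expect_lt(mn$report$neurosync_pct, 10)
  expect_gt(mp$report$neurosync_pct, mn$report$neurosync_pct)
  expect_equal(mn$mode_label, "NAVA-like")
  expect_gt(mn$pattern$peak_eadi_uV, 15)

  # amplitude too low for automated analysis -> refusal with verdict
  faint <- recording(eadi = nava$recording$eadi$values * 0.02,
                     paw = nava$recording$paw$values, fs = 62.5)
  err <- tryCatch(summarize_mode(faint, window_s = 300),
                  ns_quality_error = function(e) e)
  expect_s3_class(err, "ns_quality_error")
  expect_false(err$quality$ok)
})

test_that("Friedman test handles no-variation and dominated-mode designs", {
  d <- expand.grid(subject = 1:11, mode = c("A", "B", "C"))
  d$value <- 5
  cm <- compare_modes(d)
  expect_equal(cm$statistic, 0)
  expect_equal(cm$p_value, 1)

  # mode C always smallest across 11 subjects
  set.seed(4)
  d$value <- stats::runif(33, 10, 20)
  d$value[d$mode == "C"] <- stats::runif(11, 0, 5)
  cm2 <- compare_modes(d)
  expect_lt(cm2$p_value, 0.05)
  flagged <- cm2$dunn$significant
  has_c <- grepl("C", cm2$dunn$comparison)
  expect_true(all(flagged[has_c]))
  expect_false(any(flagged[!has_c]))
  # agrees with the base-R Friedman statistic
  ft <- stats::friedman.test(value ~ mode | subject, data = d)
  expect_equal(cm2$statistic, unname(ft$statistic))
  expect_equal(cm2$p_value, ft$p.value)

  expect_error(compare_modes(d[d$subject <= 2, ]), "3 subjects")
  expect_error(compare_modes(d[-1, ]), "incomplete block")
})

test_that("exact Friedman permutation p agrees with brute-force enumeration", {
  set.seed(99)
  for (rep in 1:8) {
    n <- sample(3:5, 1)
    d <- expand.grid(subject = seq_len(n), mode = c("A", "B", "C"))
    d$value <- stats::rnorm(nrow(d))
    cm <- compare_modes(d, exact = TRUE)
    expect_equal(cm$p_exact, brute_friedman_exact(cm$ranks),
                 tolerance = 1e-12)
    expect_gte(cm$p_exact, 0)
    expect_lte(cm$p_exact, 1)
  }
})

test_that("D'Agostino-Pearson test matches its reference implementation", {
  # expected values frozen from an independent reference run of the
  # omnibus K2 test on these exact draws
  set.seed(42)
  x1 <- round(stats::rnorm(60, 10, 2), 6)
  x2 <- round(stats::rexp(60, 1), 6)
  x3 <- round(c(1:15, 40), 6)
  r1 <- test_normality(x1)
  expect_equal(r1$statistic, 2.9564294074, tolerance = 1e-8)
  expect_equal(r1$p_value, 0.2280444521, tolerance = 1e-8)
  r2 <- test_normality(x2)
  expect_equal(r2$statistic, 16.0873126223, tolerance = 1e-8)
  expect_equal(r2$p_value, 0.0003211326, tolerance = 1e-6)
  r3 <- test_normality(x3)
  expect_equal(r3$statistic, 25.6579643622, tolerance = 1e-8)

  set.seed(7)
  expect_gt(test_normality(stats::rnorm(500))$p_value, 0.05)
  expect_lt(test_normality(stats::rexp(500))$p_value, 0.05)
  expect_error(test_normality(1:5), "n >= 8")
})

test_that("exponential regression recovers parameters and degrades gracefully", {
  x <- seq(0, 40, length.out = 33)
  y <- 0.5 * exp(0.1 * x)
  f <- fit_exponential(x, y)
  expect_equal(f$a, 0.5, tolerance = 1e-6)
  expect_equal(f$b, 0.1, tolerance = 1e-6)
  expect_equal(f$r2, 1.0, tolerance = 1e-6)
  expect_equal(unname(coef(f)), c(0.5, 0.1), tolerance = 1e-6)
  expect_equal(predict(f, newdata = list(x = 0)), 0.5, tolerance = 1e-6)

  # noiseless data: original-space and log-linear fits coincide
  fl <- fit_exponential(x, y, method = "log-linear")
  expect_equal(coef(fl), coef(f), tolerance = 1e-6)

  set.seed(12)
  yn <- y * (1 + 0.1 * stats::rnorm(33))
  fn <- fit_exponential(x, yn)
  expect_gt(fn$r2, 0.8)

  expect_error(fit_exponential(1:2, c(1, 2)), "3 points")
  expect_warning(fz <- fit_exponential(x, rep(0, 33)), "degenerate")
  expect_equal(fz$a, 0)
  expect_true(is.na(fz$r2))
})

test_that("render_report writes a complete, re-readable summary", {
  sims <- lapply(c(41, 42, 43), function(s)
    simulate_recording(preset_mode_config(
      if (s == 41) "NAVA-like" else "PSV-like", seed = s,
      duration_s = 120)))
  results <- lapply(seq_along(sims), function(i)
    summarize_mode(sims[[i]]$recording, window_s = 120,
                   mode_label = paste0("mode", i)))
  dir <- withr::local_tempdir()
  render_report(results, dir = dir)
  expect_true(file.exists(file.path(dir, "summary.json")))
  expect_true(file.exists(file.path(dir, "summary.txt")))
  for (i in 1:3)
    expect_true(file.exists(file.path(dir,
                                      paste0("breaths_mode", i, ".csv"))))
  js <- jsonlite::read_json(file.path(dir, "summary.json"),
                            simplifyVector = TRUE)
  expect_equal(length(js$modes$mode), 3L)
  expect_equal(js$modes$neurosync_pct,
               vapply(results, function(m) m$report$neurosync_pct,
                      numeric(1)),
               tolerance = 1e-9)
  # provenance embeds every detector parameter
  prov <- js$modes$provenance$detector
  expect_true(all(names(detector_params()) %in% names(prov)))
  txt <- readLines(file.path(dir, "summary.txt"))
  expect_true(any(grepl("NeuroSync", txt)))
})
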