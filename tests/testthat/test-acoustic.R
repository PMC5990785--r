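triangle_contour <- function(d = 1.0, tp = 0.3, f0_start = 400,
                             f0_max = 500, f0_end = 350, dt = 0.005,
                             t0 = 0) {
  times <- sort(unique(c(seq(0, d, by = dt), tp)))
  f0 <- ifelse(times <= tp,
               f0_start + (times / tp) * (f0_max - f0_start),
               f0_end + ((d - times) / (d - tp)) * (f0_max - f0_end))
  f0_contour(times + t0, f0)
}

test_that("flat contour yields zero drop and zero slope", {
  ct <- f0_contour(seq(0, 0.5, by = 0.005), rep(400, 101))
  m <- measure_call(ct)
  expect_equal(m$duration_s, 0.5)
  expect_equal(m$f0_max_hz, 400)
  expect_equal(m$f0_start_hz, 400)
  expect_equal(m$f0_end_hz, 400)
  expect_equal(m$f0_drop_hz, 0)
  expect_equal(m$slope_steepness_hz_per_s, 0)
  expect_equal(m$t_f0max_s, 0)   # earliest sample attaining the maximum
  expect_equal(m$pos_f0max, 0)
})

test_that("rise-fall contour is measured to its analytic values", {
  m <- measure_call(triangle_contour())
  expect_equal(m$f0_max_hz, 500)
  expect_equal(m$t_f0max_s, 0.3)
  expect_equal(m$pos_f0max, 0.3, tolerance = 1e-9)
  # medians of the linear edge windows = value at the window midpoint
  expect_equal(m$f0_start_hz, 400 + (0.025 / 0.3) * 100, tolerance = 1e-9)
  expect_equal(m$f0_end_hz, 350 + (0.025 / 0.7) * 150, tolerance = 1e-9)
  expect_equal(m$f0_drop_hz, m$f0_max_hz - m$f0_end_hz)
  expect_equal(m$slope_steepness_hz_per_s, m$f0_drop_hz / 0.7,
               tolerance = 1e-9)
})

test_that("measurement is invariant to time translation and scales with frequency", {
  base <- measure_call(triangle_contour())
  shifted <- measure_call(triangle_contour(t0 = 17.3))
  expect_equal(shifted, base, tolerance = 1e-9)

  ct2 <- triangle_contour(f0_start = 800, f0_max = 1000, f0_end = 700)
  doubled <- measure_call(ct2)
  for (v in c("f0_start_hz", "f0_end_hz", "f0_max_hz", "f0_drop_hz"))
    expect_equal(doubled[[v]], 2 * base[[v]], tolerance = 1e-9)
  expect_equal(doubled$pos_f0max, base$pos_f0max, tolerance = 1e-9)
  expect_equal(doubled$duration_s, base$duration_s)
})

test_that("start and end F0 never exceed the maximum; positions in [0, 1]", {
  tr <- small_truth(seed = 4)
  for (i in 1:10) {
    g <- generate_call_bout(sample(c("rest", "travel", "alert"), 1), tr,
                            seed = 300 + i, spectra = FALSE)
    for (cl in g$bout$calls) {
      m <- measure_call(cl$contour)
      expect_lte(m$f0_start_hz, m$f0_max_hz)
      expect_lte(m$f0_end_hz, m$f0_max_hz)
      expect_gte(m$pos_f0max, 0); expect_lte(m$pos_f0max, 1)
    }
  }
})

test_that("calls shorter than 0.1 s truncate edge windows with a warning", {
  ct <- f0_contour(seq(0, 0.08, by = 0.005), seq(400, 432, by = 2))
  expect_warning(m <- measure_call(ct), "shorter than 0.1")
  expect_equal(m$duration_s, 0.08)
  expect_equal(m$f0_max_hz, 432)
})

test_that("contour constructor enforces spacing, ordering and positivity", {
  expect_error(f0_contour(c(0, 0.02), c(400, 410)), "spacing")
  expect_error(f0_contour(c(0.01, 0.0), c(400, 410)), "increase")
  expect_error(f0_contour(c(0, 0.005), c(400, -1)), "positive")
  expect_error(f0_contour(0, 400), ">= 2 samples")
})

test_that("peak frequency comes from the maximum-intensity frame", {
  # plant energy at the second harmonic at 60% of a 1 s call
  ct <- triangle_contour()
  ft <- seq(0, 1, length.out = 400)
  freqs <- (0:128) * (44100 / 256)
  f0t <- stats::approx(ct$times_s, ct$f0_hz, xout = ft)$y
  env <- exp(-((ft - 0.6) / 0.25)^2)
  amp <- exp(-outer(2 * f0t, freqs, function(a, b) (b - a)^2) / (2 * 120^2))
  amp <- amp * (env / sqrt(rowSums(amp^2)))
  sp <- spectrum_series(ft, freqs, amp)
  m <- measure_call(ct, sp)
  f0_at_peak <- f0t[which.min(abs(ft - 0.6))]
  expect_lte(abs(m$peak_freq_hz - 2 * f0_at_peak), 44100 / 256)
  expect_equal(m$pos_peakfreq, 0.6, tolerance = 1.5 / 400)
})

test_that("inter-call intervals are gaps between call offsets and onsets", {
  one <- call_bout(list(list(contour = triangle_contour(d = 0.2, tp = 0.08))))
  expect_identical(inter_call_intervals(one), numeric(0))

  two <- call_bout(list(
    list(contour = triangle_contour(d = 0.2, tp = 0.08)),
    list(contour = triangle_contour(d = 0.2, tp = 0.08, t0 = 1.2))))
  expect_equal(inter_call_intervals(two), 1.0, tolerance = 1e-9)

  expect_error(call_bout(list(
    list(contour = triangle_contour(d = 0.5, tp = 0.2)),
    list(contour = triangle_contour(d = 0.5, tp = 0.2, t0 = 0.3)))),
    "overlap")
})

test_that("measured bout gaps agree with the configured Gamma mean", {
  tr <- synthetic_truth(seed = 31)
  gaps <- unlist(lapply(1:200, function(i)
    inter_call_intervals(generate_call_bout("travel", tr, seed = i,
                                            spectra = FALSE)$bout)))
  se <- stats::sd(gaps) / sqrt(length(gaps))
  expect_lt(abs(mean(gaps) - tr$interval$mean[["travel"]]), 3 * se)

  # alert gaps run longer than travel gaps (directionality of the presets)
  gaps_a <- unlist(lapply(1:200, function(i)
    inter_call_intervals(generate_call_bout("alert", tr, seed = i,
                                            spectra = FALSE)$bout)))
  expect_gt(mean(gaps_a), mean(gaps))
})
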