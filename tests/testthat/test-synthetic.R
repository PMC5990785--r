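test_that("study-design preset reproduces the roster margins exactly", {
  tab <- study_table(seed = 1)
  expect_equal(nrow(tab), 271)
  expect_equal(length(unique(tab$subject_id)), 29)
  expect_equal(unname(table(tab$context)[c("alert", "rest", "travel")]),
               c(40, 137, 94), ignore_attr = TRUE)

  # per-caller per-context counts equal the configured roster exactly
  roster <- default_roster()
  counts <- table(tab$subject_id, tab$context)
  for (i in seq_len(nrow(roster))) {
    s <- roster$subject[i]
    expect_equal(unname(counts[s, c("alert", "rest", "travel")]),
                 unname(unlist(roster[i, c("n_alert", "n_rest", "n_travel")])),
                 ignore_attr = TRUE)
  }

  n3 <- sum(tapply(tab$context, tab$subject_id,
                   function(x) length(unique(x))) == 3)
  expect_equal(n3, 11)

  # sex and age-class composition of the roster
  subj <- tab[!duplicated(tab$subject_id), ]
  expect_equal(sum(subj$sex == "male"), 14)
  expect_equal(sum(subj$sex == "male" & subj$age_class == "adult"), 9)
  expect_equal(sum(subj$sex == "female" & subj$age_class == "subadult"), 4)
})

test_that("bout structure follows the configured per-context quotas", {
  tab <- study_table(seed = 1)
  rest <- tab$context == "rest"
  expect_equal(sum(rest & is.na(tab$inter_call_interval_s)), 134)
  expect_equal(sum(rest), 137)
  # travel/alert calls with measurable intervals: 79 + 38 - 5 unmeasurable
  expect_equal(sum(tab$context %in% c("travel", "alert") &
                     !is.na(tab$inter_call_interval_s)), 112)
  # observers follow the allocation: alert by CC, travel by TG
  expect_true(all(tab$observer[tab$context == "alert"] == "CC"))
  expect_true(all(tab$observer[tab$context == "travel"] == "TG"))
})

test_that("generated tables always satisfy the call-record invariants", {
  for (s in c(2, 17, 23)) {
    tab <- generate_feature_table(synthetic_truth(seed = s))$table
    expect_s3_class(validate_call_table(tab), "call_table")
    expect_equal(tab$f0_drop_hz, tab$f0_max_hz - tab$f0_end_hz)
    expect_true(all(tab$f0_max_hz >= tab$f0_start_hz))
    expect_true(all(tab$pos_f0max >= 0 & tab$pos_f0max <= 1))
  }
})

test_that("the generator is a pure function of its seed", {
  a <- generate_feature_table(synthetic_truth(seed = 8))$table
  b <- generate_feature_table(synthetic_truth(seed = 8))$table
  expect_identical(a, b)
  c <- generate_feature_table(synthetic_truth(seed = 9))$table
  expect_false(identical(a$duration_s, c$duration_s))
})

test_that("per-context sample means track the configured means", {
  # large roster so standard errors are small
  roster <- default_roster()
  roster[, c("n_alert", "n_rest", "n_travel")] <-
    roster[, c("n_alert", "n_rest", "n_travel")] * 8
  # caller intercepts off: 29 callers would dominate the standard error
  tr <- synthetic_truth(seed = 5, roster = roster, subject_sd_scale = 0)
  tab <- generate_feature_table(tr)$table
  for (ctx in c("rest", "travel", "alert")) {
    y <- log(tab$duration_s[tab$context == ctx])
    # expected transformed-scale mean includes observer/device/sex terms;
    # compare against the realized linear predictor instead of bare betas
    g <- tr$gaussian$duration_s
    mu <- g$intercept + g$context[[ctx]] +
      mean(g$observer_tg * (tab$observer[tab$context == ctx] == "TG")) +
      mean(g$device_cs * (tab$device[tab$context == ctx] == "cs")) +
      mean(g$device_s * (tab$device[tab$context == ctx] == "s")) +
      mean(g$sex_male * (tab$sex[tab$context == ctx] == "male"))
    se <- stats::sd(y) / sqrt(length(y))
    expect_lt(abs(mean(y) - mu), 4 * se)
  }
})

test_that("degenerate generator produces identical calls at the grand mean", {
  tab <- generate_feature_table(degenerate_truth(seed = 6))$table
  acoustic <- c("duration_s", "f0_start_hz", "f0_end_hz", "f0_max_hz",
                "f0_drop_hz", "peak_freq_hz", "pos_f0max", "pos_peakfreq")
  for (v in acoustic)
    expect_lt(diff(range(tab[[v]])), 1e-9)
  expect_equal(unique(tab$duration_s), exp(-1.62), tolerance = 1e-9)
  iv <- tab$inter_call_interval_s
  expect_lt(diff(range(iv[!is.na(iv)])), 1e-9)
})

test_that("confound scenarios control allocation and warn when unidentifiable", {
  out <- generate_confound_scenario(
    allocation = c(rest = 0.5, travel = 0.05, alert = 0.95),
    effects = list(variable = "duration_s", observer_tg = -0.3),
    truth = synthetic_truth(seed = 12))
  tab <- out$table
  expect_lt(mean(tab$observer[tab$context == "travel"] == "CC"), 0.3)
  expect_gt(mean(tab$observer[tab$context == "alert"] == "CC"), 0.7)
  expect_equal(out$truth$gaussian$duration_s$observer_tg, -0.3)

  expect_warning(
    generate_confound_scenario(
      allocation = c(rest = 1, travel = 0, alert = 1),
      truth = synthetic_truth(seed = 12)),
    "confounded")
})

test_that("bout audio is deterministic and well-formed WAV", {
  tr <- small_truth(seed = 3)
  b1 <- generate_call_bout("alert", tr, seed = 5)$bout
  b2 <- generate_call_bout("alert", tr, seed = 5)$bout
  a1 <- bout_audio(b1, tr); a2 <- bout_audio(b2, tr)
  expect_identical(a1, a2)
  expect_true(all(abs(a1) <= 32767))

  p <- withr::local_tempfile(fileext = ".wav")
  write_wav(a1, p)
  hdr <- readBin(p, "raw", 44)
  expect_identical(rawToChar(hdr[1:4]), "RIFF")
  expect_identical(rawToChar(hdr[9:16]), "WAVEfmt ")
  expect_equal(file.size(p), 44 + 2 * length(a1))
})
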