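lmm_fm <- function(tab, vars = setdiff(candidate_variables(),
                                       "inter_call_interval_s")) {
  apply_transforms(feature_matrix(tab, vars), default_transforms()[vars])
}

test_that("zero between-caller variance collapses to ordinary least squares", {
  tr <- synthetic_truth(seed = 5, subject_sd_scale = 0)
  tab <- generate_feature_table(tr)$table
  fm <- lmm_fm(tab)
  fit <- fit_lmm(fm, lmm_spec("duration_s"))
  expect_lt(fit$random_intercept_variance, 1e-3)

  df <- data.frame(y = fm$values[, "duration_s"],
                   context = stats::relevel(factor(tab$context), "alert"),
                   sex = factor(tab$sex), age = tab$age_years,
                   observer = factor(tab$observer),
                   device = factor(tab$device, levels = c("c", "cs", "s")))
  ols <- stats::lm(y ~ context + sex + age + observer + device, df)
  expect_equal(stats::setNames(fit$fixed_effects$estimate,
                               fit$fixed_effects$term),
               coef(ols), tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("context effects are recovered on a single large table", {
  tab <- study_table(seed = 6)
  fit <- fit_lmm(lmm_fm(tab), lmm_spec("f0_max_hz"))
  fe <- stats::setNames(fit$fixed_effects$estimate, fit$fixed_effects$term)
  se <- stats::setNames(fit$fixed_effects$se, fit$fixed_effects$term)
  tr <- synthetic_truth(seed = 6)$gaussian$f0_max_hz
  expect_lt(abs(fe[["contextrest"]] - tr$context[["rest"]]),
            3.5 * se[["contextrest"]])
  expect_lt(abs(fe[["contexttravel"]] - tr$context[["travel"]]),
            3.5 * se[["contexttravel"]])
})

test_that("likelihood-ratio tests match a direct marginal-likelihood oracle", {
  tab <- study_table(seed = 2)
  fm <- lmm_fm(tab)
  spec <- lmm_spec("duration_s", controls = c("sex", "age"))
  full <- fit_lmm(fm, spec)
  null <- fit_lmm(fm, spec, drop_test = TRUE)

  # oracle: evaluate the marginal Gaussian log-likelihood by hand,
  # y ~ N(X beta, sigma^2 I + tau^2 Z Z')
  manual_ll <- function(fit) {
    df <- fit$frame
    form <- if (fit$drop_test) y ~ sex + age else y ~ context + sex + age
    X <- stats::model.matrix(form, df)
    beta <- fit$fixed_effects$estimate
    Z <- stats::model.matrix(~ 0 + factor(subject), df)
    V <- fit$residual_variance * diag(nrow(df)) +
      fit$random_intercept_variance * tcrossprod(Z)
    r <- df$y - as.numeric(X %*% beta)
    -0.5 * (nrow(df) * log(2 * pi) +
              as.numeric(determinant(V)$modulus) +
              as.numeric(r %*% solve(V, r)))
  }
  expect_equal(full$log_likelihood, manual_ll(full), tolerance = 1e-6)
  expect_equal(null$log_likelihood, manual_ll(null), tolerance = 1e-6)

  out <- lrt(full, null)
  expect_equal(out$chisq, 2 * (full$log_likelihood - null$log_likelihood),
               tolerance = 1e-10)
  expect_equal(out$df, 2)
  expect_equal(out$p, stats::pchisq(out$chisq, 2, lower.tail = FALSE))

  # identical models: chi-square 0, p = 1
  same <- lrt(full, full)
  expect_equal(same$chisq, 0)
  expect_equal(same$p, 1)

  # full-model likelihood always dominates the nested model's
  expect_gte(full$log_likelihood, null$log_likelihood)
})

test_that("null-response permutation keeps the LRT near its reference law", {
  tab <- study_table(seed = 3)
  fm <- lmm_fm(tab)
  spec <- lmm_spec("duration_s", controls = c("sex", "age"))
  set.seed(4)
  ps <- replicate(60, {
    fmp <- fm
    fmp$values[, "duration_s"] <- sample(fmp$values[, "duration_s"])
    lrt(fit_lmm(fmp, spec), fit_lmm(fmp, spec, drop_test = TRUE))$p
  })
  # rejection close to nominal and p-values not pathologically skewed
  expect_lt(mean(ps < 0.05), 0.17)
  expect_gt(mean(ps), 0.3)
})

test_that("Bonferroni gate uses a strict threshold of alpha over n", {
  g <- bonferroni_gate(c(0.016, 0.02, 0.5), n_tests = 3)
  expect_equal(g$threshold_reported, 0.017)
  expect_identical(unname(g$significant), c(TRUE, FALSE, FALSE))
  g1 <- bonferroni_gate(0.05, n_tests = 1)
  expect_identical(unname(g1$significant), FALSE)  # strict inequality
  expect_equal(g1$threshold, 0.05)
})

test_that("estimates are invariant to row order and caller relabelling", {
  tab <- study_table(seed = 7)
  fm <- lmm_fm(tab)
  spec <- lmm_spec("f0_max_hz")
  base <- fit_lmm(fm, spec)

  set.seed(8)
  perm <- sample(nrow(fm$values))
  fmp <- fm
  fmp$data <- fm$data[perm, , drop = FALSE]
  fmp$values <- fm$values[perm, , drop = FALSE]
  shuf <- fit_lmm(fmp, spec)
  expect_equal(shuf$fixed_effects$estimate, base$fixed_effects$estimate,
               tolerance = 1e-6)

  fmr <- fm
  fmr$data$subject_id <- paste0("relabel_", fm$data$subject_id)
  rel <- fit_lmm(fmr, spec)
  expect_equal(rel$fixed_effects$estimate, base$fixed_effects$estimate,
               tolerance = 1e-8)
  expect_equal(rel$log_likelihood, base$log_likelihood, tolerance = 1e-8)
})

test_that("aliased or single-level designs raise identifiability errors", {
  tab <- study_table(seed = 1)
  # all travel/alert calls of one observer each: drop rest -> observer
  # aliases context
  ta <- tab[tab$context != "rest", ]
  fm <- lmm_fm(ta)
  expect_error(fit_lmm(fm, lmm_spec("duration_s",
                                    controls = c("sex", "age", "observer"),
                                    contexts = c("travel", "alert"))),
               "rank deficient|single level")
  # single-level factor
  cc <- tab[tab$observer == "CC", ]
  expect_error(fit_lmm(lmm_fm(cc), lmm_spec("duration_s",
                                            controls = "observer")),
               "single level")
})

test_that("stability check flags a planted outlier caller and not balanced data", {
  # full study-size table: no single caller is influential
  full_fm <- lmm_fm(study_table(seed = 9))
  stab_full <- stability_check(full_fm,
                               lmm_spec("duration_s",
                                        controls = c("sex", "age")))
  expect_equal(stab_full$verdict, "stable")
  expect_length(stab_full$failed, 0)

  tr <- small_truth(seed = 9, subject_sd_scale = 0.5,
                    residual_sd_scale = 0.5)
  tab <- generate_feature_table(tr)$table
  fm <- lmm_fm(tab)
  spec <- lmm_spec("duration_s", controls = c("sex", "age"))
  stab <- stability_check(fm, spec)

  # shift one caller's responses by ten within-caller SDs
  fm_out <- fm
  hit <- fm$data$subject_id == "S2"
  fm_out$values[hit, "duration_s"] <-
    fm_out$values[hit, "duration_s"] + 10 * 0.2
  stab_out <- stability_check(fm_out, spec)
  expect_equal(stab_out$verdict, "influential")
  expect_true(stab_out$influential[["S2"]])

  # deltas equal hand-computed leave-one-caller-out refits
  s <- "S1"
  keep <- fm$data$subject_id != s
  fm_s <- fm
  fm_s$data <- fm$data[keep, , drop = FALSE]
  fm_s$values <- fm$values[keep, , drop = FALSE]
  ref <- fit_lmm(fm, spec)
  man <- fit_lmm(fm_s, spec)
  scale <- pmax(abs(ref$fixed_effects$estimate),
                0.1 * stats::sd(ref$frame$y))
  expect_equal(unname(stab$deltas[s, ]),
               abs(man$fixed_effects$estimate -
                     ref$fixed_effects$estimate) / scale,
               tolerance = 1e-8)
})
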