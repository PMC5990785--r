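fm_of <- function(tab, vars = setdiff(analysis_variables(),
                                      "inter_call_interval_s")) {
  apply_transforms(feature_matrix(tab, vars),
                   default_transforms()[vars])
}

test_that("balanced selection reproduces the crossed-design call accounting", {
  tab <- study_table(seed = 1)
  fm <- fm_of(tab)
  set.seed(2)
  sel <- select_balanced_training(fm)
  expect_length(sel$eligible_subjects, 11)
  expect_length(sel$training, 33)    # one call per caller per context
  expect_length(sel$heldout, 129)    # remaining calls of training callers
  expect_length(sel$novel, 109)      # calls of callers absent from training
  # exact partition
  expect_setequal(c(sel$training, sel$heldout, sel$novel),
                  seq_len(nrow(fm$values)))
  # training holds exactly one call per eligible caller and context
  tr <- fm$data[sel$training, ]
  expect_true(all(table(tr$subject_id, tr$context) == 1))
  # a caller lacking any context never enters training
  partial <- names(which(tapply(fm$data$context, fm$data$subject_id,
                                function(x) length(unique(x))) < 3))
  expect_false(any(fm$data$subject_id[sel$training] %in% partial))
  expect_true(all(fm$data$subject_id[sel$novel] %in% partial))
})

test_that("bout-level selection mirrors the two-context design", {
  tab <- study_table(seed = 1)
  bt <- tab[tab$context %in% c("travel", "alert"), ]
  fm <- apply_transforms(feature_matrix(bt, analysis_variables()))
  expect_equal(nrow(fm$values), 112)
  set.seed(3)
  sel <- select_balanced_training(fm, c("travel", "alert"))
  expect_length(sel$eligible_subjects, 11)
  expect_length(sel$training, 22)
  expect_equal(length(sel$training) + length(sel$heldout) +
                 length(sel$novel), 112)
})

test_that("within-subject permutation conserves per-caller label multisets", {
  set.seed(7)
  for (rep in 1:50) {
    n <- sample(10:60, 1)
    subj <- sample(paste0("s", 1:8), n, replace = TRUE)
    lab <- sample(c("rest", "travel", "alert"), n, replace = TRUE)
    perm <- permute_within_subjects(lab, subj)
    for (s in unique(subj))
      expect_identical(sort(perm[subj == s]), sort(lab[subj == s]))
  }
  # a caller with a single context keeps its labels verbatim
  lab <- c("rest", "rest", "travel")
  subj <- c("a", "a", "b")
  expect_identical(permute_within_subjects(lab, subj)[1:2],
                   c("rest", "rest"))
})

test_that("permutation is uniform over a caller's label orderings", {
  lab <- c("rest", "travel", "alert")
  subj <- rep("s", 3)
  set.seed(11)
  draws <- replicate(6000, paste(permute_within_subjects(lab, subj),
                                 collapse = "|"))
  freq <- table(draws) / length(draws)
  expect_length(freq, 6)
  se <- sqrt((1 / 6) * (5 / 6) / length(draws))
  expect_true(all(abs(freq - 1 / 6) < 3.5 * se))
})

test_that("features unrelated to labels classify at chance", {
  set.seed(13)
  n <- 120
  tabish <- data.frame(subject_id = rep(paste0("s", 1:10), each = 12),
                       context = rep(c("rest", "travel", "alert"), 40))
  fm <- structure(list(data = tabish, variables = c("u", "v"),
                       transforms = c(u = "none", v = "none"),
                       values = matrix(rnorm(2 * n), n, 2,
                                       dimnames = list(NULL, c("u", "v"))),
                       n_excluded = 0L),
                  class = "feature_matrix")
  res <- cross_classification_rate(fm, config = pdfa_config(
    n_selections = 40, seed = 5))
  expect_lt(abs(res$rate - 1 / 3), 0.08)
})

test_that("pDFA is deterministic in its seed and separates planted effects", {
  tr <- small_truth(seed = 2, subject_sd_scale = 0.05,
                    residual_sd_scale = 0.05, observer_effect_scale = 0)
  tab <- generate_feature_table(tr)$table
  fm <- fm_of(tab)
  cfg <- pdfa_config(n_selections = 10, n_permutations = 60, seed = 42)
  r1 <- run_pdfa(fm, config = cfg)
  r2 <- run_pdfa(fm, config = cfg)
  expect_identical(r1$observed_rate, r2$observed_rate)
  expect_identical(r1$null_rates, r2$null_rates)
  expect_identical(r1$p_value, r2$p_value)

  # near-noiseless context effects: perfect classification, extreme p
  expect_gt(r1$observed_rate, 0.95)
  expect_equal(r1$p_value, 1 / 61)
  expect_gt(r1$observed_rate, r1$expected_rate)
})

test_that("p-values use the add-one estimator and valid accounting", {
  tab <- study_table(seed = 4)
  fm <- fm_of(tab)
  res <- run_pdfa(fm, config = pdfa_config(n_selections = 5,
                                           n_permutations = 40, seed = 9))
  expect_gt(res$p_value, 0)
  expect_lte(res$p_value, 1)
  expect_equal(res$p_value * 41, round(res$p_value * 41))
  expect_equal(sum(res$accounting[c("training", "heldout", "novel")]),
               nrow(fm$values))
  expect_match(res$null_policy, "one balanced selection")
})

test_that("too few multi-context callers is a design error", {
  tab <- study_table(seed = 1)
  one <- tab[tab$subject_id %in% c("KL", "BB"), ]
  fm <- fm_of(one)
  expect_error(run_pdfa(fm, config = pdfa_config(n_selections = 2,
                                                 n_permutations = 2)),
               "fewer than 2 callers")
})
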