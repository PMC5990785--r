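#' pDFA configuration
#'
#' @param n_selections Number of random balanced training selections
#'   averaged for the observed rate (default 100).
#' @param n_permutations Number of within-subject label permutations for
#'   the null distribution (default 10000).
#' @param seed Integer seed; selections and permutations use independent
#'   child streams, so changing one count never reshuffles the other.
#' @param priors \code{"training"} or \code{"equal"} (the balanced design
#'   makes them coincide in training).
#' @return An object of class \code{pdfa_config}.
#' @export
pdfa_config <- function(n_selections = 100L, n_permutations = 10000L,
                        seed = 1L, priors = c("training", "equal")) {
  stopifnot(n_selections >= 1, n_permutations >= 1)
  structure(list(n_selections = as.integer(n_selections),
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), priors = match.arg(priors)),
            class = "pdfa_config")
}

#' Balanced training selection for the crossed design
#'
#' Only callers contributing at least one call to every requested context
#' are eligible for training; the training set is exactly one uniformly
#' chosen call per eligible caller per context. Remaining calls of eligible
#' callers form the held-out set; all calls of ineligible callers form the
#' novel-caller set. The three sets partition the rows.
#'
#' @param fm A \code{feature_matrix} whose rows all belong to
#'   \code{contexts}.
#' @param contexts Character vector of contexts in declared order.
#' @return List of integer row indices \code{training}, \code{heldout},
#'   \code{novel}, plus \code{eligible_subjects}.
#' @export
select_balanced_training <- function(fm, contexts = CONTEXTS) {
  stopifnot(inherits(fm, "feature_matrix"))
  labels <- fm$data$context
  subjects <- fm$data$subject_id
  if (!all(labels %in% contexts))
    stop("rows outside the requested contexts; filter first", call. = FALSE)
  eligible <- names(which(vapply(
    split(labels, subjects),
    function(l) all(contexts %in% l), logical(1))))
  if (length(eligible) == 0)
    stop("no caller has calls in every context", call. = FALSE)
  training <- integer(0)
  for (s in eligible) for (ctx in contexts) {
    idx <- which(subjects == s & labels == ctx)
    training <- c(training, idx[sample.int(length(idx), 1)])
  }
  is_eligible <- subjects %in% eligible
  list(training = sort(training),
       heldout = setdiff(which(is_eligible), training),
       novel = which(!is_eligible),
       eligible_subjects = eligible)
}

#' Cross-classification rate averaged over balanced selections
#'
#' For each random selection: draw a balanced training set, fit the
#' discriminant functions to it, classify every non-training call
#' (held-out calls of training callers and all calls of novel callers) and
#' record the proportion correct, overall and per true context. Results
#' are averaged over selections so they do not depend unduly on one random
#' selection.
#'
#' @param fm A \code{feature_matrix} restricted to \code{contexts}.
#' @param contexts Contexts in declared order.
#' @param config A \code{\link{pdfa_config}}.
#' @param labels Optional label vector overriding the table's contexts
#'   (used for permutation nulls).
#' @param stream RNG stream tag (selections and permutations stay
#'   independent).
#' @return List with \code{rate}, \code{per_context}, \code{accounting}.
#' @export
cross_classification_rate <- function(fm, contexts = CONTEXTS,
                                      config = pdfa_config(),
                                      labels = NULL, stream = "selection") {
  stopifnot(inherits(fm, "feature_matrix"))
  if (is.null(labels)) labels <- fm$data$context
  x <- fm$values
  rates <- numeric(config$n_selections)
  per <- matrix(0, config$n_selections, length(contexts),
                dimnames = list(NULL, contexts))
  acct <- NULL
  for (i in seq_len(config$n_selections)) {
    sel <- with_seed(child_seed(config$seed, stream, i), {
      fm_lab <- fm; fm_lab$data$context <- labels
      select_balanced_training(fm_lab, contexts)
    })
    if (is.null(acct))
      acct <- c(training = length(sel$training),
                heldout = length(sel$heldout), novel = length(sel$novel),
                eligible_subjects = length(sel$eligible_subjects))
    model <- fit_lda(x[sel$training, , drop = FALSE], labels[sel$training],
                     priors = config$priors, group_order = contexts)
    test <- c(sel$heldout, sel$novel)
    pred <- classify(model, x[test, , drop = FALSE])$class
    truth <- labels[test]
    rates[i] <- mean(pred == truth)
    per[i, ] <- vapply(contexts, function(k) mean(pred[truth == k] == k),
                       numeric(1))
  }
  list(rate = mean(rates), per_context = colMeans(per, na.rm = TRUE),
       accounting = acct, selection_rates = rates)
}

#' Permute context labels within callers
#'
#' Uniformly shuffles the assignment of each caller's own context labels
#' to that caller's calls, leaving the per-caller label multiset -- and
#' hence all across-caller structure -- untouched. This is the null move of
#' the crossed permuted DFA: under it, any systematic within-caller
#' association between acoustics and context is destroyed while repeated
#' measures and caller-level differences are preserved.
#'
#' @param labels Character vector of context labels.
#' @param subject_ids Aligned caller identifiers.
#' @return Permuted label vector.
#' @export
permute_within_subjects <- function(labels, subject_ids) {
  if (length(labels) != length(subject_ids))
    stop("labels and subject_ids do not align", call. = FALSE)
  out <- labels
  for (idx in split(seq_along(labels), subject_ids)) {
    if (length(idx) > 1) out[idx] <- labels[idx][sample.int(length(idx))]
  }
  out
}

#' Run a crossed permuted discriminant function analysis
#'
#' The full pDFA: the observed cross-classification rate is the average
#' over \code{n_selections} balanced selections; the null distribution is
#' built from \code{n_permutations} within-subject label shuffles, each
#' evaluated with one fresh balanced selection (permutation variance
#' dominates selection variance, so the null does not re-average over
#' selections; the observed statistic keeps the full average). The p-value
#' uses the add-one estimator \eqn{(1 + \#\{null \ge observed\}) /
#' (1 + n_{perm})}, never exactly zero. Caller eligibility is computed once
#' from the observed labels; within-subject shuffling preserves per-caller
#' context counts, so eligibility is permutation-invariant (asserted on
#' every shuffle).
#'
#' @param fm A \code{feature_matrix} already screened and restricted to the
#'   analysis variables; for the bout-level analysis (travel/alert with
#'   inter-call interval active) interval-less calls must already be
#'   excluded (\code{\link{feature_matrix}} does this).
#' @param contexts Contexts in declared order.
#' @param config A \code{\link{pdfa_config}}.
#' @return An object of class \code{pdfa_result}: observed and
#'   permutation-expected rates, p-value, per-context rates, call
#'   accounting, the null rates, and a config echo (including the
#'   one-selection-per-permutation null policy flag).
#' @export
run_pdfa <- function(fm, contexts = CONTEXTS, config = pdfa_config()) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(config, "pdfa_config"))
  keep <- fm$data$context %in% contexts
  if (!all(keep)) {
    fm$data <- fm$data[keep, , drop = FALSE]
    fm$values <- fm$values[keep, , drop = FALSE]
  }
  labels <- fm$data$context
  subjects <- fm$data$subject_id
  eligible0 <- names(which(vapply(split(labels, subjects),
                                  function(l) all(contexts %in% l),
                                  logical(1))))
  if (length(eligible0) < 2)
    stop("fewer than 2 callers contribute to every context", call. = FALSE)

  obs <- cross_classification_rate(fm, contexts, config, stream = "selection")

  null_rates <- numeric(config$n_permutations)
  one_sel <- pdfa_config(n_selections = 1L, n_permutations = 1L,
                         seed = config$seed, priors = config$priors)
  subj_split <- split(seq_along(labels), subjects)
  base_ms <- lapply(subj_split, function(i) sort(labels[i]))
  for (j in seq_len(config$n_permutations)) {
    perm <- with_seed(child_seed(config$seed, "permutation", j),
                      permute_within_subjects(labels, subjects))
    # per-caller label multisets must be conserved by the shuffle
    stopifnot(identical(lapply(subj_split, function(i) sort(perm[i])),
                        base_ms))
    one_sel$seed <- child_seed(config$seed, "null_selection", j)
    null_rates[j] <- cross_classification_rate(
      fm, contexts, one_sel, labels = perm, stream = "selection")$rate
  }

  structure(list(
    observed_rate = obs$rate,
    expected_rate = mean(null_rates),
    p_value = (1 + sum(null_rates >= obs$rate)) / (1 + config$n_permutations),
    per_context_rates = obs$per_context,
    accounting = obs$accounting,
    null_rates = null_rates,
    selection_rates = obs$selection_rates,
    contexts = contexts,
    config = config,
    null_policy = "one balanced selection per permutation"
  ), class = "pdfa_result")
}

#' @exportS3Method base::print
print.pdfa_result <- function(x, ...) {
  cat(sprintf("crossed pDFA over {%s}\n", paste(x$contexts, collapse = ", ")))
  cat(sprintf("  observed cross-classification: %.1f%%\n",
              100 * x$observed_rate))
  cat(sprintf("  permutation-expected:          %.1f%%\n",
              100 * x$expected_rate))
  cat(sprintf("  p = %.4g  (%d permutations, %d selections)\n",
              x$p_value, x$config$n_permutations, x$config$n_selections))
  cat("  per-context: ",
      paste(sprintf("%s %.1f%%", names(x$per_context_rates),
                    100 * x$per_context_rates), collapse = ", "), "\n")
  cat(sprintf("  calls: %d training, %d held-out, %d novel (%d eligible callers)\n",
              x$accounting[["training"]], x$accounting[["heldout"]],
              x$accounting[["novel"]], x$accounting[["eligible_subjects"]]))
  invisible(x)
}
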