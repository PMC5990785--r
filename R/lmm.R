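#' Specification of one context mixed model
#'
#' One Gaussian linear mixed model: a transformed acoustic variable as
#' response, context as the test predictor (treatment contrasts, alert as
#' the reference level), a configurable subset of control predictors, and
#' a random intercept per caller. The bout-level interval model uses only
#' sex and age as controls (observer and device separate completely from
#' context there).
#'
#' @param response Name of an active (transformed) variable.
#' @param controls Subset of \code{c("sex", "age", "observer", "device")}.
#' @param contexts Contexts whose calls enter the model.
#' @param reference Reference context for the treatment contrasts.
#' @return An object of class \code{lmm_spec}.
#' @export
lmm_spec <- function(response,
                     controls = c("sex", "age", "observer", "device"),
                     contexts = CONTEXTS, reference = "alert") {
  if (length(controls) > 0)
    controls <- match.arg(controls, c("sex", "age", "observer", "device"),
                          several.ok = TRUE)
  stopifnot(reference %in% contexts)
  structure(list(response = response, controls = controls,
                 contexts = contexts, reference = reference),
            class = "lmm_spec")
}

lmm_frame <- function(fm, spec) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(spec, "lmm_spec"))
  if (!spec$response %in% fm$variables)
    stop("response not among active variables: ", spec$response,
         call. = FALSE)
  keep <- fm$data$context %in% spec$contexts
  df <- data.frame(
    y = fm$values[keep, spec$response],
    context = stats::relevel(factor(fm$data$context[keep],
                                    levels = c(spec$reference,
                                               setdiff(spec$contexts,
                                                       spec$reference))),
                             ref = spec$reference),
    sex = factor(fm$data$sex[keep], levels = SEXES),
    age = fm$data$age_years[keep],
    observer = factor(fm$data$observer[keep], levels = OBSERVERS),
    device = factor(fm$data$device[keep], levels = c("c", "cs", "s")),
    subject = fm$data$subject_id[keep],
    stringsAsFactors = FALSE)
  droplevels(df)
}

lmm_formula <- function(controls, test = TRUE) {
  terms <- c(if (test) "context", controls,
             "(1 | subject)")
  stats::as.formula(paste("y ~", paste(terms, collapse = " + ")))
}

#' Fit a Gaussian linear mixed model by maximum likelihood
#'
#' Fits \code{response ~ context + controls + (1 | caller)} with a
#' Gaussian error structure and identity link, by maximum likelihood (not
#' REML: the likelihood-ratio tests downstream compare models differing in
#' fixed effects). The fixed-effects design is rank-checked first; aliased
#' terms are an identifiability error rather than a silent drop.
#'
#' @param fm A transformed \code{feature_matrix}.
#' @param spec An \code{\link{lmm_spec}}.
#' @param drop_test Drop the test predictor (context), giving the null
#'   model.
#' @return An object of class \code{lmm_fit}: fixed-effect table
#'   (estimate, standard error, t), random-intercept and residual
#'   variances, log-likelihood, parameter count and the underlying fit.
#' @export
fit_lmm <- function(fm, spec, drop_test = FALSE) {
  df <- lmm_frame(fm, spec)
  if (length(unique(df$subject)) < 2)
    stop("need >= 2 callers", call. = FALSE)
  for (v in intersect(c("context", "sex", "observer", "device"),
                      c(if (!drop_test) "context", spec$controls))) {
    if (nlevels(df[[v]]) < 2)
      stop("predictor '", v, "' has a single level in these rows; ",
           "not identifiable", call. = FALSE)
  }
  form <- lmm_formula(spec$controls, test = !drop_test)
  fixed_form <- stats::reformulate(attr(stats::terms(
    lme4::nobars(form)), "term.labels"), response = "y")
  X <- stats::model.matrix(fixed_form, df)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("fixed-effects design is rank deficient; aliased term(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  fit <- lme4::lmer(form, data = df, REML = FALSE,
                    control = lme4::lmerControl(calc.derivs = FALSE))
  if (length(fit@optinfo$conv$lme4$messages) > 0 &&
      any(grepl("failed to converge", fit@optinfo$conv$lme4$messages)))
    stop("mixed-model fit did not converge: ",
         paste(fit@optinfo$conv$lme4$messages, collapse = "; "),
         call. = FALSE)
  co <- as.data.frame(summary(fit)$coefficients)
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(
    fixed_effects = data.frame(term = rownames(co), estimate = co[, 1],
                               se = co[, 2], t = co[, 3],
                               row.names = NULL),
    random_intercept_variance = vc$vcov[vc$grp == "subject"],
    residual_variance = vc$vcov[vc$grp == "Residual"],
    log_likelihood = as.numeric(stats::logLik(fit)),
    n_fixed = ncol(X), n_obs = nrow(df), spec = spec,
    drop_test = drop_test, model = fit, frame = df
  ), class = "lmm_fit")
}

#' Likelihood-ratio test between nested mixed models
#'
#' \eqn{\chi^2 = 2(\ell_{full} - \ell_{reduced})} (clipped at zero),
#' degrees of freedom the difference in fixed-effect parameter count,
#' p-value from the central chi-square upper tail (both models are ML fits
#' with identical random structure, so no boundary correction applies).
#'
#' @param full,reduced \code{lmm_fit} objects on the same rows, the
#'   reduced model's fixed terms a subset of the full model's.
#' @return List with \code{chisq}, \code{df}, \code{p}.
#' @export
lrt <- function(full, reduced) {
  stopifnot(inherits(full, "lmm_fit"), inherits(reduced, "lmm_fit"))
  if (full$n_obs != reduced$n_obs)
    stop("models were fitted to different row sets", call. = FALSE)
  if (reduced$n_fixed > full$n_fixed)
    stop("reduced model has more fixed parameters than the full model",
         call. = FALSE)
  chisq <- max(0, 2 * (full$log_likelihood - reduced$log_likelihood))
  df <- full$n_fixed - reduced$n_fixed
  p <- if (df == 0) 1 else stats::pchisq(chisq, df, lower.tail = FALSE)
  list(chisq = chisq, df = df, p = p)
}

#' Bonferroni significance gate
#'
#' Flags each p-value as significant when strictly below
#' \code{alpha / n_tests}; with the default three tests the threshold is
#' reported as 0.017 (the conventional rounding).
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @param n_tests Number of tests sharing the family (default 3).
#' @param alpha Family-wise level (default 0.05).
#' @return List with \code{threshold} (exact), \code{threshold_reported}
#'   (rounded to 3 decimals) and \code{significant} (logical vector).
#' @export
bonferroni_gate <- function(p_values, n_tests = 3, alpha = 0.05) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  thr <- alpha / n_tests
  list(threshold = thr, threshold_reported = round(thr, 3),
       significant = p_values < thr)
}

#' Full context mixed-model analysis of one acoustic variable
#'
#' Fits the full model, the null model without the test predictor
#' (context), and one reduced model per fixed term, reporting the
#' full-versus-null likelihood-ratio test and a per-term LRT table
#' alongside the fixed-effect estimates.
#'
#' @param fm A transformed \code{feature_matrix}.
#' @param spec An \code{\link{lmm_spec}}.
#' @param n_tests Bonferroni family size for the context test (default 3).
#' @return An object of class \code{lmm_result}.
#' @export
context_lmm <- function(fm, spec, n_tests = 3) {
  full <- fit_lmm(fm, spec)
  null <- fit_lmm(fm, spec, drop_test = TRUE)
  full_null <- lrt(full, null)

  term_lrt <- list(context = full_null)
  for (ctl in spec$controls) {
    red_spec <- spec
    red_spec$controls <- setdiff(spec$controls, ctl)
    red <- fit_lmm(fm, red_spec)
    term_lrt[[ctl]] <- lrt(full, red)
  }
  gate <- bonferroni_gate(full_null$p, n_tests = n_tests)
  structure(list(full = full, null = null, full_null = full_null,
                 term_lrt = term_lrt,
                 bonferroni = gate,
                 response = spec$response),
            class = "lmm_result")
}

#' @exportS3Method base::print
print.lmm_result <- function(x, ...) {
  cat(sprintf("LMM for %s (ML, random intercept per caller, n = %d)\n",
              x$response, x$full$n_obs))
  cat(sprintf("  full vs null: chi^2 = %.2f, d.f. = %d, p = %.3g%s\n",
              x$full_null$chisq, x$full_null$df, x$full_null$p,
              if (x$bonferroni$significant) sprintf(
                "  (significant at Bonferroni %0.3f)",
                x$bonferroni$threshold_reported) else ""))
  fe <- x$full$fixed_effects
  for (i in seq_len(nrow(fe)))
    cat(sprintf("  %-22s beta = %7.3f  se = %6.3f  t = %6.2f\n",
                fe$term[i], fe$estimate[i], fe$se[i], fe$t[i]))
  invisible(x)
}

#' Leave-one-caller-out stability check
#'
#' Refits the full model with each caller excluded and reports, per fixed
#' effect, the maximum absolute change in the estimate relative to the
#' full-data estimate (changes are scaled by the larger of the estimate's
#' magnitude and one-tenth of the response SD, so near-zero estimates do
#' not blow up the ratio). A caller whose exclusion moves any estimate by
#' more than \code{threshold} is flagged influential. A failed refit is
#' recorded for that caller, not fatal.
#'
#' @param fm A transformed \code{feature_matrix}.
#' @param spec An \code{\link{lmm_spec}}.
#' @param threshold Relative-change threshold for the influence verdict
#'   (default 0.5).
#' @return List with \code{deltas} (callers x terms matrix of relative
#'   changes), \code{influential} (named logical), \code{failed}
#'   (character vector of callers whose refit failed) and \code{verdict}.
#' @export
stability_check <- function(fm, spec, threshold = 0.5) {
  full <- fit_lmm(fm, spec)
  subjects <- unique(full$frame$subject)
  if (length(subjects) < 3) stop("need >= 3 callers", call. = FALSE)
  ref <- stats::setNames(full$fixed_effects$estimate,
                         full$fixed_effects$term)
  scale <- pmax(abs(ref), 0.1 * stats::sd(full$frame$y))
  deltas <- matrix(NA_real_, length(subjects), length(ref),
                   dimnames = list(subjects, names(ref)))
  failed <- character(0)
  for (s in subjects) {
    sub_fm <- fm
    keep <- fm$data$subject_id != s
    sub_fm$data <- fm$data[keep, , drop = FALSE]
    sub_fm$values <- fm$values[keep, , drop = FALSE]
    fit_s <- tryCatch(fit_lmm(sub_fm, spec), error = function(e) NULL)
    if (is.null(fit_s)) { failed <- c(failed, s); next }
    est <- stats::setNames(fit_s$fixed_effects$estimate,
                           fit_s$fixed_effects$term)
    common <- intersect(names(ref), names(est))
    deltas[s, common] <- abs(est[common] - ref[common]) / scale[common]
  }
  influential <- apply(deltas, 1, function(d) any(d > threshold, na.rm = TRUE))
  list(deltas = deltas, influential = influential, failed = failed,
       verdict = if (any(influential)) "influential" else "stable",
       threshold = threshold)
}
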