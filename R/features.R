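#' Build a feature matrix from a call table
#'
#' Extracts the active predictor variables into a numeric matrix aligned to
#' the table rows. Rows with an absent value in any active variable (in
#' practice: calls without an inter-call interval when that variable is
#' active) are excluded; the number excluded is recorded.
#'
#' @param tab A \code{call_table} data frame (see
#'   \code{\link{validate_call_table}}).
#' @param variables Character vector of active predictor names; defaults to
#'   the screening candidates.
#' @return An object of class \code{feature_matrix}: a list with \code{data}
#'   (the retained rows), \code{variables}, \code{transforms} (named tags,
#'   initially \code{"none"}), \code{values} (numeric matrix) and
#'   \code{n_excluded}.
#' @export
feature_matrix <- function(tab, variables = candidate_variables()) {
  bad <- setdiff(variables, names(tab))
  if (length(bad) > 0)
    stop("unknown variable(s): ", paste(bad, collapse = ", "), call. = FALSE)
  vals <- as.matrix(as.data.frame(tab)[, variables, drop = FALSE])
  storage.mode(vals) <- "double"
  keep <- stats::complete.cases(vals)
  structure(list(
    data = as.data.frame(tab)[keep, , drop = FALSE],
    variables = variables,
    transforms = stats::setNames(rep("none", length(variables)), variables),
    values = vals[keep, , drop = FALSE],
    n_excluded = sum(!keep)
  ), class = "feature_matrix")
}

#' @exportS3Method base::print
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d calls x %d variables (%d excluded)\n",
              nrow(x$values), length(x$variables), x$n_excluded))
  tags <- ifelse(x$transforms == "none", x$variables,
                 sprintf("%s (%s)", x$variables, x$transforms))
  cat(" ", paste(tags, collapse = ", "), "\n")
  invisible(x)
}

#' Default transformation specification
#'
#' The transformations applied before analysis: log for call duration,
#' maximum F0 and (under the default reading) position of maximum F0;
#' square root for F0 drop, position of peak frequency and inter-call
#' interval. The two position variables carry transformation annotations in
#' the analysis tables yet the methods prose also describes them as
#' untransformed; both readings are supported via \code{positions}.
#'
#' @param positions \code{"annotated"} (default; positions log/sqrt
#'   transformed) or \code{"untransformed"}.
#' @return Named character vector over the screening candidates with values
#'   in \code{{"log", "sqrt", "none"}}.
#' @export
default_transforms <- function(positions = c("annotated", "untransformed")) {
  positions <- match.arg(positions)
  spec <- c(duration_s = "log", f0_start_hz = "none", f0_end_hz = "none",
            f0_max_hz = "log", f0_drop_hz = "sqrt",
            slope_steepness_hz_per_s = "none",
            pos_f0max = "log", pos_peakfreq = "sqrt",
            inter_call_interval_s = "sqrt")
  if (positions == "untransformed")
    spec[c("pos_f0max", "pos_peakfreq")] <- "none"
  spec
}

#' Apply variable transformations
#'
#' Replaces the value matrix of a feature matrix by its transformed version
#' and records the transformation tag on each variable. \code{log} (natural
#' logarithm) requires strictly positive values and \code{sqrt} non-negative
#' values; a domain violation is an error naming the variable and row.
#'
#' @param fm A \code{feature_matrix}.
#' @param spec Named character vector mapping each active variable to
#'   \code{"log"}, \code{"sqrt"} or \code{"none"}.
#' @return The transformed \code{feature_matrix}; \code{fm$data} is untouched.
#' @export
apply_transforms <- function(fm, spec = default_transforms()) {
  stopifnot(inherits(fm, "feature_matrix"))
  missing_spec <- setdiff(fm$variables, names(spec))
  if (length(missing_spec) > 0)
    stop("transform spec does not cover: ",
         paste(missing_spec, collapse = ", "), call. = FALSE)
  if (any(fm$transforms != "none"))
    stop("feature matrix is already transformed", call. = FALSE)
  vals <- fm$values
  for (v in fm$variables) {
    tf <- match.arg(spec[[v]], c("log", "sqrt", "none"))
    x <- vals[, v]
    if (tf == "log") {
      bad <- which(x <= 0)
      if (length(bad) > 0)
        stop_rows(sprintf("log transform of non-positive value in '%s'", v), bad)
      vals[, v] <- log(x)
    } else if (tf == "sqrt") {
      bad <- which(x < 0)
      if (length(bad) > 0)
        stop_rows(sprintf("sqrt transform of negative value in '%s'", v), bad)
      vals[, v] <- sqrt(x)
    }
    fm$transforms[[v]] <- tf
  }
  fm$values <- vals
  fm
}

#' Invert the recorded transformations
#'
#' Back-transforms the value matrix (exp for log, squaring for sqrt),
#' recovering the original values; used for round-trip checks.
#'
#' @param fm A transformed \code{feature_matrix}.
#' @return The back-transformed \code{feature_matrix}.
#' @export
invert_transforms <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  for (v in fm$variables) {
    if (fm$transforms[[v]] == "log") fm$values[, v] <- exp(fm$values[, v])
    if (fm$transforms[[v]] == "sqrt") fm$values[, v] <- fm$values[, v]^2
    fm$transforms[[v]] <- "none"
  }
  fm
}

#' Restrict a feature matrix to a variable subset
#'
#' @param fm A \code{feature_matrix}.
#' @param variables Variables to keep (must be active in \code{fm}).
#' @return A \code{feature_matrix} over the subset; rows that were excluded
#'   only because of a variable now dropped are \emph{not} restored.
#' @export
subset_variables <- function(fm, variables) {
  stopifnot(inherits(fm, "feature_matrix"))
  bad <- setdiff(variables, fm$variables)
  if (length(bad) > 0)
    stop("variables not active: ", paste(bad, collapse = ", "), call. = FALSE)
  fm$variables <- variables
  fm$transforms <- fm$transforms[variables]
  fm$values <- fm$values[, variables, drop = FALSE]
  fm
}

#' Variance inflation factors
#'
#' VIF of each column of a numeric matrix: \code{1 / (1 - R^2)} from the
#' ordinary least-squares regression of that column on all the others. A
#' single-column matrix has VIF 1 by convention.
#'
#' @param x Numeric matrix with named columns.
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(x) {
  p <- ncol(x)
  if (p == 1) return(stats::setNames(1, colnames(x)))
  out <- stats::setNames(numeric(p), colnames(x))
  for (j in seq_len(p)) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((x[, j] - mean(x[, j]))^2)
    if (tss == 0) stop("constant variable: ", colnames(x)[j], call. = FALSE)
    r2 <- 1 - rss / tss
    out[j] <- if (r2 >= 1) Inf else 1 / (1 - r2)
  }
  out
}

#' Collinearity screening
#'
#' Two-stage predictor screening on the (transformed) feature matrix.
#' First, any pair with \code{|r| > r_threshold} (Pearson) is resolved by
#' discarding one member: a variable on the \code{prefer_discard} list takes
#' precedence (covering the named victims of the original analysis -- slope
#' steepness, start and end F0); otherwise the member with the larger mean
#' absolute correlation to all remaining variables is discarded. This
#' repeats until no violating pair remains. Second, variance inflation
#' factors are computed on the survivors and the largest is discarded until
#' all are below \code{vif_threshold}.
#'
#' @param fm A \code{feature_matrix} (screen after transformation).
#' @param r_threshold Pairwise absolute-correlation threshold (default 0.7).
#' @param vif_threshold VIF threshold (default 2).
#' @param prefer_discard Ordered character vector of preferred victims.
#' @return An object of class \code{screening_result}: list with
#'   \code{pairwise_r} (full candidate correlation matrix), \code{discarded},
#'   \code{vif} (on the retained set) and \code{retained}.
#' @export
screen_correlations <- function(fm, r_threshold = 0.7, vif_threshold = 2.0,
                                prefer_discard = c("slope_steepness_hz_per_s",
                                                   "f0_start_hz",
                                                   "f0_end_hz")) {
  stopifnot(inherits(fm, "feature_matrix"))
  x <- fm$values
  if (ncol(x) < 2) stop("need at least two candidate variables", call. = FALSE)
  if (nrow(x) < 3) stop("need at least three rows", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("constant (singular) variable(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  full_r <- stats::cor(x)
  discarded <- character(0)
  keep <- colnames(x)

  repeat {
    r <- full_r[keep, keep, drop = FALSE]
    off <- abs(r); diag(off) <- 0
    if (max(off) <= r_threshold) break
    involved <- keep[apply(off > r_threshold, 1, any)]
    pref <- intersect(prefer_discard, involved)
    victim <- if (length(pref) > 0) pref[1] else {
      mac <- rowMeans(off[involved, , drop = FALSE])
      involved[which.max(mac)]
    }
    discarded <- c(discarded, victim)
    keep <- setdiff(keep, victim)
    if (length(keep) < 2) break
  }

  v <- vif(x[, keep, drop = FALSE])
  while (any(v >= vif_threshold) && length(keep) > 2) {
    victim <- names(v)[which.max(v)]
    discarded <- c(discarded, victim)
    keep <- setdiff(keep, victim)
    v <- vif(x[, keep, drop = FALSE])
  }

  structure(list(pairwise_r = full_r, discarded = discarded, vif = v,
                 retained = keep, r_threshold = r_threshold,
                 vif_threshold = vif_threshold),
            class = "screening_result")
}

#' @exportS3Method base::print
print.screening_result <- function(x, ...) {
  cat(sprintf("screening: retained %d of %d variables (|r| <= %g, VIF < %g)\n",
              length(x$retained), ncol(x$pairwise_r), x$r_threshold,
              x$vif_threshold))
  if (length(x$discarded) > 0)
    cat("  discarded:", paste(x$discarded, collapse = ", "), "\n")
  for (v in x$retained) cat(sprintf("  %-26s VIF %.3f\n", v, x$vif[[v]]))
  invisible(x)
}

#' Write a screening report
#'
#' Writes the screening result as a per-variable CSV (variable, vif,
#' retained flag) and a JSON summary with thresholds, discards and the
#' retained set.
#'
#' @param sr A \code{screening_result}.
#' @param csv_path,json_path Output paths (either may be \code{NULL}).
#' @return Invisibly, the report data frame.
#' @export
write_screening_report <- function(sr, csv_path = NULL, json_path = NULL) {
  vars <- colnames(sr$pairwise_r)
  rep_df <- data.frame(
    variable = vars,
    vif = unname(sr$vif[vars]),
    retained = vars %in% sr$retained
  )
  if (!is.null(csv_path))
    utils::write.csv(rep_df, csv_path, row.names = FALSE, na = "")
  if (!is.null(json_path))
    jsonlite::write_json(list(r_threshold = sr$r_threshold,
                              vif_threshold = sr$vif_threshold,
                              discarded = sr$discarded,
                              retained = sr$retained,
                              vif = as.list(sr$vif)),
                         json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(rep_df)
}
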