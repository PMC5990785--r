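# condition-number threshold above which the pooled covariance is treated
# as numerically singular (no silent ridge regularization)
COND_LIMIT <- 1e10

as_values <- function(fm) {
  if (inherits(fm, "feature_matrix")) fm$values
  else if (is.matrix(fm)) fm
  else stop("need a feature_matrix or numeric matrix", call. = FALSE)
}

#' Fit linear discriminant functions
#'
#' Fisher's linear discriminant analysis, computed from scatter matrices:
#' the pooled within-group covariance \eqn{S_W} uses group-centred
#' deviations with divisor \eqn{N - g}; the discriminant coefficients solve
#' the generalized eigenproblem of between- versus within-group scatter
#' (via a Cholesky whitening of \eqn{S_W}) and are scaled so every
#' discriminant score has unit within-group variance. The number of
#' functions is \code{min(groups - 1, variables)}.
#'
#' @param fm A \code{feature_matrix} or numeric matrix (rows = calls).
#' @param labels Group label per row (character or factor).
#' @param priors \code{"training"} (group proportions in the training data)
#'   or \code{"equal"}.
#' @param group_order Optional explicit ordering of the group labels; ties
#'   in classification break towards the first label in this order.
#' @return An object of class \code{dfa_model}: group labels and means,
#'   pooled covariance, loadings (variables x functions), eigenvalues,
#'   priors, and group centroids in discriminant space.
#' @export
fit_lda <- function(fm, labels, priors = c("training", "equal"),
                    group_order = NULL) {
  priors <- match.arg(priors)
  x <- as_values(fm)
  labels <- as.character(labels)
  if (nrow(x) != length(labels)) stop("labels do not align with rows",
                                      call. = FALSE)
  groups <- if (is.null(group_order)) unique(labels) else group_order
  if (!all(labels %in% groups)) stop("labels outside group_order",
                                     call. = FALSE)
  g <- length(groups)
  p <- ncol(x)
  n <- nrow(x)
  counts <- table(factor(labels, levels = groups))
  if (g < 2 || any(counts < 2))
    stop("need >= 2 groups with >= 2 rows each", call. = FALSE)
  if (n < p + g)
    stop("need at least variables + groups rows", call. = FALSE)

  means <- t(matrix(vapply(groups,
                           function(k) colMeans(x[labels == k, , drop = FALSE]),
                           numeric(p)), nrow = p))
  centred <- x - means[match(labels, groups), , drop = FALSE]
  Sw <- crossprod(centred) / (n - g)
  if (!all(is.finite(Sw)) || kappa(Sw, exact = TRUE) > COND_LIMIT) {
    v <- tryCatch(vif(x), error = function(e) NULL)
    culprits <- if (is.null(v)) colnames(x) else
      colnames(x)[v > COND_LIMIT / 10 | !is.finite(v)]
    stop("pooled within-group covariance is numerically singular; ",
         "collinear variable(s): ",
         paste(if (length(culprits)) culprits else colnames(x),
               collapse = ", "), call. = FALSE)
  }

  grand <- colMeans(x)
  dev <- means - matrix(grand, g, p, byrow = TRUE)
  B <- crossprod(dev * sqrt(as.numeric(counts)))  # between-group scatter

  U <- chol(Sw)
  Ui <- backsolve(U, diag(p))
  A <- t(Ui) %*% B %*% Ui
  A <- (A + t(A)) / 2
  ev <- eigen(A, symmetric = TRUE)
  r <- min(g - 1, p)
  loadings <- Ui %*% ev$vectors[, seq_len(r), drop = FALSE]
  dimnames(loadings) <- list(colnames(x), paste0("LD", seq_len(r)))

  pri <- if (priors == "equal") rep(1 / g, g) else as.numeric(counts) / n
  structure(list(group_labels = groups,
                 group_means = means,
                 pooled_cov = Sw,
                 loadings = loadings,
                 eigenvalues = ev$values[seq_len(r)],
                 priors = stats::setNames(pri, groups),
                 centroids = means %*% loadings,
                 variables = colnames(x)),
            class = "dfa_model")
}

#' @exportS3Method base::print
print.dfa_model <- function(x, ...) {
  cat(sprintf("dfa_model: %d groups (%s), %d variables, %d function(s)\n",
              length(x$group_labels), paste(x$group_labels, collapse = "/"),
              length(x$variables), ncol(x$loadings)))
  print(round(x$loadings, 3))
  invisible(x)
}

#' Classify calls with fitted discriminant functions
#'
#' Assigns each row the group maximizing the Gaussian equal-covariance
#' posterior (equivalently, minimal Mahalanobis distance to the group mean
#' adjusted by the log prior). Posteriors sum to 1 per row. Exact posterior
#' ties break to the first group in the model's label order and are
#' flagged.
#'
#' @param model A \code{\link{dfa_model}}.
#' @param fm A \code{feature_matrix} or matrix with the model's variables.
#' @return List with \code{class} (character vector), \code{posterior}
#'   (rows x groups matrix) and \code{tie} (logical vector).
#' @export
classify <- function(model, fm) {
  stopifnot(inherits(model, "dfa_model"))
  x <- as_values(fm)
  if (!identical(colnames(x), model$variables))
    stop("variables do not match the fitted model", call. = FALSE)
  Sinv_Mt <- solve(model$pooled_cov, t(model$group_means))
  delta <- x %*% Sinv_Mt -
    matrix(0.5 * colSums(t(model$group_means) * Sinv_Mt),
           nrow(x), length(model$group_labels), byrow = TRUE) +
    matrix(log(model$priors), nrow(x), length(model$group_labels),
           byrow = TRUE)
  colnames(delta) <- model$group_labels
  post <- exp(delta - apply(delta, 1, max))
  post <- post / rowSums(post)
  best <- max.col(post, ties.method = "first")
  tie <- vapply(seq_len(nrow(post)),
                function(i) sum(post[i, ] == post[i, best[i]]) > 1, logical(1))
  list(class = model$group_labels[best], posterior = post, tie = tie)
}

#' Leave-one-out cross-validated classification rates
#'
#' Classifies each call with a model fitted to all remaining calls and
#' reports the proportion correct per true group and overall.
#'
#' @inheritParams fit_lda
#' @return List with \code{per_context} (named proportions), \code{overall}
#'   and \code{predicted} (the per-call assignments).
#' @export
loo_crossvalidated_rates <- function(fm, labels,
                                     priors = c("training", "equal"),
                                     group_order = NULL) {
  priors <- match.arg(priors)
  x <- as_values(fm)
  labels <- as.character(labels)
  groups <- if (is.null(group_order)) unique(labels) else group_order
  pred <- character(nrow(x))
  for (i in seq_len(nrow(x))) {
    m <- fit_lda(x[-i, , drop = FALSE], labels[-i], priors = priors,
                 group_order = groups)
    pred[i] <- classify(m, x[i, , drop = FALSE])$class
  }
  per <- vapply(groups, function(k) mean(pred[labels == k] == k), numeric(1))
  list(per_context = per, overall = mean(pred == labels), predicted = pred)
}
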