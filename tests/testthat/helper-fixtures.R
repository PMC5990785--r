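# Shared fixtures: everything is generated in code at test time.

# small unbalanced roster: 3 callers cover all contexts, one does not
tiny_roster <- function() {
  data.frame(subject = c("S1", "S2", "S3", "S4"),
             sex = c("female", "male", "female", "male"),
             age_class = c("adult", "adult", "subadult", "adult"),
             n_alert = c(3, 2, 2, 0),
             n_rest = c(3, 3, 2, 2),
             n_travel = c(3, 2, 2, 0),
             stringsAsFactors = FALSE)
}

small_truth <- function(seed = 1, ...) {
  synthetic_truth(seed = seed, roster = tiny_roster(), ...)
}

study_table <- local({
  cache <- new.env()
  function(seed = 1) {
    key <- paste0("s", seed)
    if (is.null(cache[[key]]))
      cache[[key]] <- generate_feature_table(synthetic_truth(seed = seed))$table
    cache[[key]]
  }
})

# a generator with every stochastic component switched off
degenerate_truth <- function(seed = 1) {
  tr <- synthetic_truth(seed = seed, context_effect_scale = 0,
                        observer_effect_scale = 0, subject_sd_scale = 0,
                        residual_sd_scale = 0)
  for (v in names(tr$gaussian)) {
    tr$gaussian[[v]]$sex_male <- 0
    tr$gaussian[[v]]$age_slope <- 0
  }
  tr$u_range <- c(0.75, 0.75)
  tr$peak_freq_log_sd <- 0
  tr$peak_harmonic_probs <- 1
  tr$interval$shape <- Inf
  tr$interval$subject_sd_log <- 0
  tr
}

# random small Gaussian classification instance for oracle comparisons
gauss_instance <- function(seed) {
  set.seed(seed)
  p <- sample(2:4, 1)
  g <- sample(2:3, 1)
  A <- matrix(rnorm(p * p), p)
  sigma <- crossprod(A) + diag(p)          # SPD
  means <- matrix(rnorm(g * p, sd = 2), g, p)
  priors <- as.numeric(stats::rgamma(g, 2)); priors <- priors / sum(priors)
  x <- matrix(rnorm(5 * p), 5, p) + means[sample(g, 5, replace = TRUE), ]
  list(p = p, g = g, sigma = sigma, means = means, priors = priors, x = x)
}

# brute-force equal-covariance Gaussian posterior: full density per group
oracle_posterior <- function(x, means, sigma, priors) {
  p <- ncol(means)
  dens <- vapply(seq_len(nrow(means)), function(k) {
    d <- sweep(x, 2, means[k, ])
    q <- rowSums((d %*% solve(sigma)) * d)
    priors[k] * exp(-0.5 * q) /
      sqrt((2 * pi)^p * det(sigma))
  }, numeric(nrow(x)))
  dens <- matrix(dens, nrow(x))
  list(class = max.col(dens, ties.method = "first"),
       posterior = dens / rowSums(dens))
}

# hand-built dfa_model around known means/covariance (bypasses fitting)
manual_model <- function(means, sigma, priors, labels, vars) {
  dimnames(means) <- list(labels, vars)
  dimnames(sigma) <- list(vars, vars)
  structure(list(group_labels = labels, group_means = means,
                 pooled_cov = sigma, loadings = NULL, eigenvalues = NULL,
                 priors = stats::setNames(priors, labels),
                 centroids = NULL, variables = vars),
            class = "dfa_model")
}
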