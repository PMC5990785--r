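#' Default caller roster
#'
#' The study-design roster the generator emulates: 29 wild chimpanzees (14
#' males: 9 adult / 5 subadult; 15 females: 11 adult / 4 subadult) with
#' unbalanced call counts over the three contexts, totalling 271 calls
#' (alert 40, rest 137, travel 94). Eleven callers contribute calls to all
#' three contexts (162 calls); the remaining 18 contribute 109.
#'
#' @return Data frame with columns \code{subject}, \code{sex},
#'   \code{age_class}, \code{n_alert}, \code{n_rest}, \code{n_travel}.
#' @export
default_roster <- function() {
  tab <- c(
    "BB,male,adult,2,0,0",    "FD,male,adult,0,5,5",
    "FK,male,subadult,0,4,5", "HT,female,adult,1,1,0",
    "HW,male,adult,0,7,5",    "JN,female,adult,0,6,4",
    "KA,female,subadult,2,0,0", "KL,female,adult,3,4,5",
    "KT,male,adult,5,9,5",    "KU,female,adult,0,6,5",
    "KW,female,adult,2,8,5",  "KY,female,adult,2,2,0",
    "KZ,male,subadult,2,12,5", "MK,female,adult,0,2,0",
    "ML,female,adult,0,5,5",  "MS,male,adult,1,7,5",
    "NB,female,adult,1,7,5",  "NK,male,adult,2,11,5",
    "NR,female,subadult,1,1,0", "OK,female,adult,3,0,0",
    "PS,male,subadult,2,6,5", "RE,female,subadult,2,4,5",
    "SQ,male,adult,4,7,5",    "TK,male,adult,2,1,0",
    "VR,female,subadult,0,2,0", "ZF,male,adult,0,7,5",
    "ZG,male,subadult,1,2,0", "ZL,male,subadult,2,6,5",
    "ZM,female,adult,0,5,5")
  out <- utils::read.csv(text = paste(tab, collapse = "\n"), header = FALSE,
                         col.names = c("subject", "sex", "age_class",
                                       "n_alert", "n_rest", "n_travel"),
                         stringsAsFactors = FALSE)
  out
}

#' Ground-truth parameters for the synthetic call generator
#'
#' Defines the statistical structure the generator emulates. Continuous
#' acoustic variables are Gaussian on their transformed scale (so the
#' mixed-model stage's assumptions hold by construction):
#' \deqn{y = \mu + \beta_{context} + \beta_{observer} + \beta_{device} +
#'   \beta_{sex} + \beta_{age}\,age + b_{subject} + \epsilon}
#' with \eqn{b_{subject} \sim N(0, \sigma_s^2)} and
#' \eqn{\epsilon \sim N(0, \sigma_r^2)}. Inter-call gaps are Gamma
#' (positive, right-skewed) with per-context means and a log-normal
#' per-caller factor. Context-effect defaults (alert as reference) follow
#' the directions and magnitudes of the original field analysis: rest hoos
#' longest, travel shortest; alert hoos with the highest maximum F0; alert
#' inter-call gaps longer than travel gaps. Between-caller and residual SDs
#' are plausibility choices (no published values exist) calibrated so that
#' start/end F0 correlate strongly (r > 0.7) with maximum F0 and slope
#' steepness with F0 drop, as observed in the real data.
#'
#' Bout structure: rest hoos are almost always single calls (in-bout
#' proportion 3/137), travel (79/94) and alert (38/40) hoos mostly come in
#' bouts; a handful of in-bout intervals (default 5) are marked
#' unmeasurable. Observers are allocated by context (alert recorded by CC,
#' travel by TG, rest split), and recording devices conditionally on
#' observer, reproducing the observer-by-context imbalance of the study
#' design.
#'
#' @param seed Integer master seed; all component generators derive child
#'   seeds from it.
#' @param roster Caller roster (see \code{\link{default_roster}}).
#' @param context_effect_scale Multiplier on every context effect (0 gives
#'   a null generator with no context differences, including equal
#'   inter-call gap means).
#' @param observer_effect_scale Multiplier on observer and device effects.
#' @param subject_sd_scale,residual_sd_scale Multipliers on the
#'   between-caller and residual SDs.
#' @param p_cc_rest Probability that a rest bout is recorded by observer CC.
#' @return An object of class \code{synthetic_truth}.
#' @export
synthetic_truth <- function(seed = 1L,
                            roster = default_roster(),
                            context_effect_scale = 1,
                            observer_effect_scale = 1,
                            subject_sd_scale = 1,
                            residual_sd_scale = 1,
                            p_cc_rest = 0.5) {
  if (nrow(roster) == 0) stop("roster is empty", call. = FALSE)
  counts <- as.matrix(roster[, c("n_alert", "n_rest", "n_travel")])
  if (any(counts < 0) || any(counts != round(counts)))
    stop("roster call counts must be non-negative integers", call. = FALSE)
  if (all(counts == 0)) stop("roster schedules no calls", call. = FALSE)

  gvar <- function(transform, intercept, rest, travel, observer_tg = 0,
                   device_cs = 0, device_s = 0, sex_male = 0, age_slope = 0,
                   subject_sd, residual_sd)
    list(transform = transform, intercept = intercept,
         context = c(rest = rest * context_effect_scale,
                     travel = travel * context_effect_scale, alert = 0),
         observer_tg = observer_tg * observer_effect_scale,
         device_cs = device_cs * observer_effect_scale,
         device_s = device_s * observer_effect_scale,
         sex_male = sex_male, age_slope = age_slope,
         subject_sd = subject_sd * subject_sd_scale,
         residual_sd = residual_sd * residual_sd_scale)

  gaussian <- list(
    duration_s = gvar("log", -1.62, rest = 0.63, travel = -0.28,
                      observer_tg = -0.24, device_cs = -0.12,
                      device_s = -0.10, sex_male = 0.12,
                      subject_sd = 0.15, residual_sd = 0.40),
    f0_max_hz = gvar("log", 5.74, rest = -0.31, travel = -0.42,
                     observer_tg = -0.13, device_cs = -0.15,
                     device_s = 0.12,
                     subject_sd = 0.08, residual_sd = 0.17),
    f0_drop_hz = gvar("sqrt", 7.5, rest = 0, travel = 0,
                      subject_sd = 1.0, residual_sd = 3.0),
    pos_f0max = gvar("log", log(0.30), rest = 0, travel = 0,
                     subject_sd = 0.10, residual_sd = 0.20),
    pos_peakfreq = gvar("sqrt", sqrt(0.5), rest = 0, travel = 0,
                        subject_sd = 0.05, residual_sd = 0.12)
  )

  means <- c(rest = 3.5, travel = 0.45, alert = 1.9)
  lm0 <- mean(log(means))
  means <- exp(lm0 + context_effect_scale * (log(means) - lm0))

  structure(list(
    seed = as.integer(seed),
    roster = roster,
    gaussian = gaussian,
    interval = list(mean = means, shape = 2, subject_sd_log = 0.15),
    bout = list(in_bout_prop = c(rest = 3 / 137, travel = 79 / 94,
                                 alert = 38 / 40),
                n_unmeasured = 5L,
                size_dist = list(
                  rest = c(134 / 137, 3 / 137),
                  travel = c(0.16, 0.50, 0.34),
                  alert = c(0.05, 0.45, 0.50))),
    observer_alloc = c(rest = p_cc_rest, travel = 0, alert = 1),
    device_probs = list(CC = c(s = 0.7, cs = 0.3, c = 0),
                        TG = c(s = 0, cs = 0.4, c = 0.6)),
    u_range = c(0.55, 0.95),
    peak_harmonic_probs = c(0.6, 0.4),
    peak_freq_log_sd = 0.08,
    contour = list(dt = 0.005, min_duration = 0.15, edge_margin = 0.06,
                   harmonic_amps = c(1, 0.6, 0.3), sigma_f_hz = 120,
                   frames_per_call = 1000, env_width_frac = 0.3,
                   sample_rate_hz = 44100, n_fft = 256)
  ), class = "synthetic_truth")
}

# per-context observer draw for one bout
draw_observer <- function(context, truth) {
  if (stats::runif(1) < truth$observer_alloc[[context]]) "CC" else "TG"
}

draw_device <- function(observer, truth) {
  p <- truth$device_probs[[observer]]
  sample(names(p), 1, prob = p)
}

#' Generate a synthetic call feature table
#'
#' Simulates one call table under the generator model of
#' \code{\link{synthetic_truth}}: the roster schedules the calls; bout
#' membership is allocated by exact per-context quota (so the default
#' roster reproduces 134/137 single rest hoos exactly), with single calls
#' placed preferentially on callers that do not contribute to all contexts,
#' keeping the balanced-training eligibility of the flagged callers intact;
#' observers and devices are drawn per bout; each acoustic variable is
#' context mean plus caller intercept plus observer/device/sex/age terms
#' plus Gaussian noise on its transformed scale, then back-transformed and
#' clipped to its domain; inter-call gaps are Gamma. Derived fields
#' (F0 drop, positions, slope) are constructed to satisfy the call-record
#' invariants exactly.
#'
#' @param truth A \code{\link{synthetic_truth}}.
#' @return List with \code{table} (a validated \code{call_table}) and
#'   \code{truth} (the generator parameters, for recovery tests).
#' @export
generate_feature_table <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  with_seed(child_seed(truth$seed, "feature_table"), {
    roster <- truth$roster
    counts <- as.matrix(roster[, c("n_alert", "n_rest", "n_travel")])
    colnames(counts) <- c("alert", "rest", "travel")
    eligible <- rowSums(counts > 0) == ncol(counts)

    rows <- do.call(rbind, lapply(seq_len(nrow(roster)), function(i) {
      ctx <- rep(colnames(counts), counts[i, ])
      if (length(ctx) == 0) return(NULL)
      data.frame(subject_id = roster$subject[i], sex = roster$sex[i],
                 age_class = roster$age_class[i], context = ctx,
                 eligible = eligible[i], stringsAsFactors = FALSE)
    }))
    n <- nrow(rows)

    # caller ages by sex/age class (years)
    age_lim <- list(male_adult = c(15, 40), male_subadult = c(10, 14),
                    female_adult = c(14, 40), female_subadult = c(10, 13))
    subj <- unique(rows$subject_id)
    age_map <- stats::setNames(numeric(length(subj)), subj)
    for (s in subj) {
      i <- match(s, rows$subject_id)
      lim <- age_lim[[paste(rows$sex[i], rows$age_class[i], sep = "_")]]
      age_map[s] <- round(stats::runif(1, lim[1], lim[2]))
    }
    rows$age_years <- age_map[rows$subject_id]

    # bout membership: exact quota per context, singles preferentially on
    # non-eligible callers so flagged callers keep measurable calls in
    # every context
    rows$in_bout <- FALSE
    for (ctx in CONTEXTS) {
      idx <- which(rows$context == ctx)
      if (length(idx) == 0) next
      n_in <- round(truth$bout$in_bout_prop[[ctx]] * length(idx))
      n_single <- length(idx) - n_in
      pool_single <- idx[!rows$eligible[idx]]
      if (length(pool_single) < n_single)
        pool_single <- idx  # roster too small to protect; fall back
      singles <- if (n_single > 0)
        resample(pool_single, min(n_single, length(pool_single))) else integer(0)
      rows$in_bout[setdiff(idx, singles)] <- TRUE
    }

    # group in-bout calls of one caller x context into bouts of two
    # measured calls (measured calls are never sequential neighbours, so
    # they sit at positions 1 and 3 of the underlying bout)
    rows$bout_id <- NA_character_
    rows$position_in_bout <- 1L
    for (s in subj) for (ctx in CONTEXTS) {
      idx <- which(rows$subject_id == s & rows$context == ctx)
      inb <- resample(idx[rows$in_bout[idx]])
      k <- 0L
      while (length(inb) > 0) {
        k <- k + 1L
        take <- utils::head(inb, 2)
        inb <- utils::tail(inb, -length(take))
        rows$bout_id[take] <- sprintf("%s_%s_b%02d", s, ctx, k)
        rows$position_in_bout[take] <- c(1L, 3L)[seq_along(take)]
      }
      sing <- idx[!rows$in_bout[idx]]
      for (j in seq_along(sing)) {
        rows$bout_id[sing[j]] <- sprintf("%s_%s_s%02d", s, ctx, j)
      }
    }

    # observer and device per bout
    bouts <- unique(rows$bout_id)
    obs_map <- dev_map <- stats::setNames(character(length(bouts)), bouts)
    for (b in bouts) {
      ctx <- rows$context[match(b, rows$bout_id)]
      obs_map[b] <- draw_observer(ctx, truth)
      dev_map[b] <- draw_device(obs_map[b], truth)
    }
    rows$observer <- obs_map[rows$bout_id]
    rows$device <- dev_map[rows$bout_id]

    # Gaussian variables on the transformed scale
    tvals <- matrix(NA_real_, n, length(truth$gaussian),
                    dimnames = list(NULL, names(truth$gaussian)))
    for (v in names(truth$gaussian)) {
      g <- truth$gaussian[[v]]
      b_subj <- stats::setNames(stats::rnorm(length(subj), 0, g$subject_sd),
                                subj)
      tvals[, v] <- g$intercept + g$context[rows$context] +
        g$observer_tg * (rows$observer == "TG") +
        g$device_cs * (rows$device == "cs") +
        g$device_s * (rows$device == "s") +
        g$sex_male * (rows$sex == "male") +
        g$age_slope * rows$age_years +
        b_subj[rows$subject_id] +
        stats::rnorm(n, 0, g$residual_sd)
    }

    duration <- exp(tvals[, "duration_s"])
    f0_max <- exp(tvals[, "f0_max_hz"])
    # clip the drop so end F0 stays comfortably positive
    s_drop <- pmin(pmax(tvals[, "f0_drop_hz"], 0.5), sqrt(0.8 * f0_max))
    f0_drop <- s_drop^2
    f0_end <- f0_max - f0_drop
    u <- stats::runif(n, truth$u_range[1], truth$u_range[2])
    f0_start <- f0_end + u * f0_drop
    pos_f0max <- pmin(pmax(exp(tvals[, "pos_f0max"]), 0.02), 0.95)
    pos_peak <- pmin(pmax(tvals[, "pos_peakfreq"], sqrt(0.02)),
                     sqrt(0.98))^2
    t_f0max <- pos_f0max * duration
    t_peak <- pos_peak * duration
    slope <- f0_drop / ((1 - pos_f0max) * duration)
    harmonic <- sample(seq_along(truth$peak_harmonic_probs), n, replace = TRUE,
                       prob = truth$peak_harmonic_probs)
    peak_freq <- harmonic * f0_max *
      exp(stats::rnorm(n, 0, truth$peak_freq_log_sd))

    # inter-call intervals: Gamma with per-context mean and a log-normal
    # caller factor; in-bout calls only, minus the unmeasurable quota
    interval <- rep(NA_real_, n)
    subj_f <- stats::setNames(
      exp(stats::rnorm(length(subj), 0, truth$interval$subject_sd_log)), subj)
    inb <- which(rows$in_bout)
    if (length(inb) > 0) {
      m <- truth$interval$mean[rows$context[inb]] * subj_f[rows$subject_id[inb]]
      interval[inb] <- if (is.infinite(truth$interval$shape)) m else
        stats::rgamma(length(inb), shape = truth$interval$shape,
                      scale = m / truth$interval$shape)
    }
    # unmeasurable intervals, protecting one measurable call per eligible
    # caller and context
    n_na <- min(truth$bout$n_unmeasured, length(inb))
    if (n_na > 0 && length(inb) > 0) {
      protected <- integer(0)
      for (s in subj[eligible[match(subj, roster$subject)]])
        for (ctx in CONTEXTS) {
          cand <- inb[rows$subject_id[inb] == s & rows$context[inb] == ctx]
          if (length(cand) > 0)
            protected <- c(protected, cand[sample.int(length(cand), 1)])
        }
      pool <- setdiff(inb[rows$context[inb] != "rest"], protected)
      drop_idx <- if (length(pool) >= n_na) resample(pool, n_na) else pool
      interval[drop_idx] <- NA_real_
    }

    tab <- data.frame(
      call_id = sprintf("c%04d", seq_len(n)),
      subject_id = rows$subject_id, sex = rows$sex,
      age_years = rows$age_years, age_class = rows$age_class,
      context = rows$context, observer = rows$observer, device = rows$device,
      bout_id = rows$bout_id, position_in_bout = rows$position_in_bout,
      duration_s = duration, f0_start_hz = f0_start, f0_end_hz = f0_end,
      f0_max_hz = f0_max, f0_drop_hz = f0_drop,
      slope_steepness_hz_per_s = slope, peak_freq_hz = peak_freq,
      t_f0max_s = t_f0max, t_peakfreq_s = t_peak,
      pos_f0max = pos_f0max, pos_peakfreq = pos_peak,
      inter_call_interval_s = interval,
      stringsAsFactors = FALSE)
    tab <- validate_call_table(tab)
    list(table = tab, truth = truth)
  })
}

#' Generate an observer-by-context confound scenario
#'
#' Produces a table in which the observer allocation follows a supplied
#' per-context probability of observer CC, with context and observer
#' effects injected at known values on a chosen response variable -- the
#' setting used to ask whether the mixed model can tease apart observer
#' and context when two contexts are each recorded (almost) exclusively by
#' one observer. If the allocation confounds observer with context
#' completely, the fixed-effects design of context + observer is rank
#' deficient and an identifiability warning is emitted.
#'
#' @param allocation Named numeric vector over contexts: probability that a
#'   bout in that context is recorded by CC.
#' @param effects List with elements \code{variable} (response name,
#'   default \code{"duration_s"}), \code{context} (named vector of betas on
#'   the transformed scale, alert as reference) and \code{observer_tg}.
#' @param truth Base \code{\link{synthetic_truth}} to modify.
#' @return List with \code{table} and \code{truth} (as modified).
#' @export
generate_confound_scenario <- function(allocation,
                                       effects = list(),
                                       truth = synthetic_truth()) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!all(CONTEXTS %in% names(allocation)))
    stop("allocation must name all contexts", call. = FALSE)
  if (any(allocation < 0 | allocation > 1))
    stop("allocation entries must be probabilities in [0, 1]", call. = FALSE)
  truth$observer_alloc[CONTEXTS] <- allocation[CONTEXTS]
  v <- if (is.null(effects$variable)) "duration_s" else effects$variable
  if (!v %in% names(truth$gaussian))
    stop("unknown response variable: ", v, call. = FALSE)
  if (!is.null(effects$context)) {
    truth$gaussian[[v]]$context[names(effects$context)] <- effects$context
  }
  if (!is.null(effects$observer_tg))
    truth$gaussian[[v]]$observer_tg <- effects$observer_tg
  out <- generate_feature_table(truth)
  X <- stats::model.matrix(~ context + observer, out$table)
  if (qr(X)$rank < ncol(X))
    warning("observer is completely confounded with context; ",
            "observer and context effects are not separately identifiable")
  out
}

# analytic F0 of the rise-fall contour used by generate_call_bout
contour_f0_at <- function(t, d, tp, f0_start, f0_max, f0_end) {
  ifelse(t <= tp,
         f0_start + (t / tp) * (f0_max - f0_start),
         f0_end + ((d - t) / (d - tp)) * (f0_max - f0_end))
}

#' Generate a synthetic call bout with ground truth
#'
#' Builds one bout of a given context: bout length drawn from the
#' configured per-context size distribution, each call a rise--fall F0
#' contour (linear rise to the maximum, linear fall to the end) with
#' context-dependent duration and maximum F0, Gamma-distributed gaps, and
#' framewise harmonic-stack spectra (Gaussian spectral bumps at the first
#' three harmonics under a smooth amplitude envelope). The call duration is
#' snapped to the contour sampling grid and the F0 peak kept clear of the
#' 0.05 s edge windows, so the generator can state the exact value every
#' acoustic measurement should recover: start/end F0 are the analytic
#' medians of the edge windows, F0 drop and slope follow from those, and
#' peak frequency is the spectral bin of the dominant harmonic at the
#' envelope peak.
#'
#' @param context One of \code{"rest"}, \code{"travel"}, \code{"alert"}.
#' @param truth A \code{\link{synthetic_truth}}.
#' @param seed Optional integer; defaults to a child of \code{truth$seed}.
#' @param spectra Logical: generate framewise spectra (needed for
#'   peak-frequency truth) or contours only.
#' @return List with \code{bout} (a \code{\link{call_bout}}),
#'   \code{truth_table} (data frame of per-call ground-truth acoustic
#'   values, one row per call) and \code{gaps} (the true inter-call gaps,
#'   length one less than the number of calls).
#' @export
generate_call_bout <- function(context, truth, seed = NULL, spectra = TRUE) {
  stopifnot(inherits(truth, "synthetic_truth"))
  context <- match.arg(context, CONTEXTS)
  if (is.null(seed)) seed <- child_seed(truth$seed, paste0("bout_", context))
  cc <- truth$contour
  with_seed(seed, {
    sizes <- truth$bout$size_dist[[context]]
    n_calls <- sample(seq_along(sizes), 1, prob = sizes)

    calls <- vector("list", n_calls)
    tt <- vector("list", n_calls)
    gaps <- numeric(0)
    onset <- 0
    for (i in seq_len(n_calls)) {
      g <- truth$gaussian
      d <- exp(g$duration_s$intercept + g$duration_s$context[[context]] +
                 stats::rnorm(1, 0, g$duration_s$residual_sd))
      d <- max(d, cc$min_duration)
      d <- round(d / cc$dt) * cc$dt       # snap to the sampling grid
      f0_max <- exp(g$f0_max_hz$intercept + g$f0_max_hz$context[[context]] +
                      stats::rnorm(1, 0, g$f0_max_hz$residual_sd))
      s_drop <- min(max(stats::rnorm(1, g$f0_drop_hz$intercept,
                                     g$f0_drop_hz$residual_sd), 0.5),
                    sqrt(0.8 * f0_max))
      f0_drop <- s_drop^2
      f0_end <- f0_max - f0_drop
      u <- stats::runif(1, truth$u_range[1], truth$u_range[2])
      f0_start <- f0_end + u * f0_drop
      pos <- exp(g$pos_f0max$intercept +
                   stats::rnorm(1, 0, g$pos_f0max$residual_sd))
      tp <- min(max(pos * d, cc$edge_margin), d - cc$edge_margin)
      pos_pk <- min(max(
        stats::rnorm(1, g$pos_peakfreq$intercept,
                     g$pos_peakfreq$residual_sd)^2, 0.1), 0.9)

      times <- sort(unique(c(seq(0, d, by = cc$dt), tp)))
      f0 <- contour_f0_at(times, d, tp, f0_start, f0_max, f0_end)
      contour <- f0_contour(times + onset, f0)

      spec <- NULL
      peak_truth <- c(NA_real_, NA_real_)
      if (spectra) {
        nyq_bins <- cc$n_fft / 2
        freqs <- (0:nyq_bins) * (cc$sample_rate_hz / cc$n_fft)
        ft <- seq(0, d, length.out = cc$frames_per_call)
        t_env <- pos_pk * d
        env <- exp(-((ft - t_env) / (cc$env_width_frac * d))^2)
        f0_fr <- contour_f0_at(ft, d, tp, f0_start, f0_max, f0_end)
        amp <- matrix(0, length(ft), length(freqs))
        for (k in seq_along(cc$harmonic_amps)) {
          ctr <- outer(k * f0_fr, freqs, function(a, b) (b - a)^2)
          amp <- amp + cc$harmonic_amps[k] * exp(-ctr / (2 * cc$sigma_f_hz^2))
        }
        # normalize each frame to unit power, then apply the envelope, so
        # total intensity follows the envelope exactly (peak at t_env)
        amp <- amp * (env / sqrt(rowSums(amp^2)))
        spec <- spectrum_series(ft + onset, freqs, amp)
        i_env <- which.min(abs(ft - t_env))
        k_dom <- which.max(cc$harmonic_amps)
        peak_truth <- c(freqs[which.min(abs(freqs - k_dom * f0_fr[i_env]))],
                        ft[i_env])
      }

      # exact expected measurements: medians of the linear edge segments
      w <- EDGE_WINDOW
      f0_start_m <- contour_f0_at(w / 2, d, tp, f0_start, f0_max, f0_end)
      f0_end_m <- contour_f0_at(d - w / 2, d, tp, f0_start, f0_max, f0_end)
      drop_m <- f0_max - f0_end_m
      tt[[i]] <- data.frame(
        duration_s = d, f0_start_hz = f0_start_m, f0_end_hz = f0_end_m,
        f0_max_hz = f0_max, f0_drop_hz = drop_m,
        slope_steepness_hz_per_s = drop_m / (d - tp),
        peak_freq_hz = peak_truth[1],
        t_f0max_s = tp, t_peakfreq_s = peak_truth[2],
        pos_f0max = tp / d, pos_peakfreq = peak_truth[2] / d)
      calls[[i]] <- list(contour = contour, spectra = spec)

      gap <- stats::rgamma(1, shape = truth$interval$shape,
                           scale = truth$interval$mean[[context]] /
                             truth$interval$shape)
      gaps <- c(gaps, gap)
      onset <- onset + d + gap
    }
    list(bout = call_bout(calls), truth_table = do.call(rbind, tt),
         gaps = gaps[seq_len(n_calls - 1)])
  })
}

#' Synthesize bout audio as 16-bit PCM
#'
#' Renders a generated bout as mono 44.1 kHz 16-bit samples: a stack of
#' three harmonics (fundamental strongest) following each call's F0
#' contour under a raised-cosine amplitude envelope, with silence in the
#' gaps. Not an imitation of real chimpanzee voice quality; it exists so
#' that the full measurement chain can be exercised on audio with known
#' ground truth.
#'
#' @param bout A \code{\link{call_bout}}.
#' @param truth A \code{\link{synthetic_truth}} (for harmonic amplitudes
#'   and sample rate).
#' @return Integer vector of 16-bit PCM samples.
#' @export
bout_audio <- function(bout, truth = synthetic_truth()) {
  stopifnot(inherits(bout, "call_bout"))
  sr <- truth$contour$sample_rate_hz
  amps <- truth$contour$harmonic_amps
  n_total <- ceiling(max(bout$offsets_s) * sr) + 1
  y <- numeric(n_total)
  for (cl in bout$calls) {
    tt <- cl$contour$times_s
    smp <- seq(floor(tt[1] * sr), floor(max(tt) * sr))
    ts <- smp / sr
    f0 <- stats::approx(tt, cl$contour$f0_hz, xout = ts, rule = 2)$y
    phase <- 2 * pi * cumsum(f0) / sr
    env <- 0.5 - 0.5 * cos(2 * pi * (ts - ts[1]) / (max(ts) - ts[1]))
    w <- numeric(length(ts))
    for (k in seq_along(amps)) w <- w + amps[k] * sin(k * phase)
    y[smp + 1] <- y[smp + 1] + env * w / sum(amps)
  }
  as.integer(round(32000 * y / max(1, max(abs(y)))))
}

#' Write PCM samples as a WAV file
#'
#' Minimal canonical RIFF/WAVE writer for mono 16-bit PCM.
#'
#' @param samples Integer vector in [-32768, 32767].
#' @param path Output path.
#' @param sample_rate_hz Sample rate (default 44100).
#' @return \code{path}, invisibly.
#' @export
write_wav <- function(samples, path, sample_rate_hz = 44100) {
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(samples)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(as.integer(16), con, size = 4, endian = "little")
  writeBin(as.integer(1), con, size = 2, endian = "little")   # PCM
  writeBin(as.integer(1), con, size = 2, endian = "little")   # mono
  writeBin(as.integer(sample_rate_hz), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate_hz * 2), con, size = 4, endian = "little")
  writeBin(as.integer(2), con, size = 2, endian = "little")   # block align
  writeBin(as.integer(16), con, size = 2, endian = "little")  # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(as.integer(samples), con, size = 2, endian = "little")
  invisible(path)
}
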