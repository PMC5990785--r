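#' Default pipeline configuration
#'
#' Configuration for the end-to-end analysis. \code{input} is either
#' \code{list(type = "synthetic", seed = ...)} (generator arguments are
#' passed to \code{\link{synthetic_truth}}) or \code{list(type = "csv",
#' path = ..., dialect = NULL)}. The two discriminant analyses use the
#' three-context single-call variable set and the travel/alert bout-level
#' set (adding inter-call interval); the mixed models test context on
#' maximum F0 and call duration (controls: sex, age, observer, device) and
#' on inter-call interval (controls: sex, age; travel/alert calls only).
#'
#' @param input Input description (see above).
#' @param seed Master seed for both analyses.
#' @param n_selections,n_permutations pDFA settings (defaults 100, 10000).
#' @param positions Position-variable transform reading (see
#'   \code{\link{default_transforms}}).
#' @param r_threshold,vif_threshold Screening thresholds.
#' @param out_dir Output directory, or \code{NULL} to skip writing files.
#' @param verbose Emit progress messages.
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(input = list(type = "synthetic", seed = 1L),
                            seed = 1L,
                            n_selections = 100L, n_permutations = 10000L,
                            positions = "annotated",
                            r_threshold = 0.7, vif_threshold = 2.0,
                            out_dir = NULL, verbose = TRUE) {
  structure(list(input = input, seed = as.integer(seed),
                 n_selections = as.integer(n_selections),
                 n_permutations = as.integer(n_permutations),
                 positions = positions, r_threshold = r_threshold,
                 vif_threshold = vif_threshold,
                 out_dir = out_dir, verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path Path to a YAML (requires the \pkg{yaml} package) or JSON
#'   file whose keys mirror the arguments of \code{\link{pipeline_config}}.
#' @return A \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
  else {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configs need the 'yaml' package; use JSON instead",
           call. = FALSE)
    yaml::read_yaml(path)
  }
  do.call(pipeline_config, raw)
}

# mean loadings over balanced selections, sign-aligned to the first
# selection (discriminant function signs are arbitrary)
average_loadings <- function(fm, contexts, config) {
  ref <- NULL
  acc <- NULL
  for (i in seq_len(config$n_selections)) {
    sel <- with_seed(child_seed(config$seed, "selection", i),
                     select_balanced_training(fm, contexts))
    m <- fit_lda(fm$values[sel$training, , drop = FALSE],
                 fm$data$context[sel$training], priors = config$priors,
                 group_order = contexts)
    L <- m$loadings
    if (is.null(ref)) { ref <- L; acc <- L * 0 }
    sgn <- sign(colSums(L * ref)); sgn[sgn == 0] <- 1
    acc <- acc + sweep(L, 2, sgn, `*`)
  }
  acc / config$n_selections
}

#' Run the full analysis pipeline
#'
#' Orchestrates read/generate, transformation, collinearity screening,
#' both permuted discriminant analyses, the three context mixed models
#' with Bonferroni control, and report writing:
#' \enumerate{
#'   \item single-call variables are screened over all calls; the
#'     three-context pDFA runs on the retained set;
#'   \item the bout-level analysis restricts to travel and alert calls
#'     with a measured inter-call interval (rest hoos are almost always
#'     single, so they carry no interval), adds the interval to the
#'     variable set, re-screens and runs the two-context pDFA;
#'   \item mixed models test the context effect on maximum F0, call
#'     duration and inter-call interval, with full-versus-null
#'     likelihood-ratio tests at the Bonferroni-corrected level.
#' }
#' When \code{out_dir} is set, writes \code{results.json},
#' \code{report.md}, \code{screening_single.csv}, \code{screening_bout.csv}
#' and (for synthetic input) \code{calls.csv}.
#'
#' @param config A \code{\link{pipeline_config}} (or a path accepted by
#'   \code{\link{read_pipeline_config}}).
#' @return Invisibly, a result bundle: the table, screening results, both
#'   \code{pdfa_result}s, the \code{lmm_result}s, averaged loadings and
#'   the config.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (config$verbose) message(sprintf(...))

  tab <- switch(config$input$type,
    synthetic = {
      args <- config$input[setdiff(names(config$input), "type")]
      if (is.null(args$seed)) args$seed <- config$seed
      truth <- do.call(synthetic_truth, args)
      say("generating synthetic call table (seed %d)", truth$seed)
      generate_feature_table(truth)$table
    },
    csv = {
      say("reading call table from %s", config$input$path)
      read_call_table(config$input$path, config$input$dialect)
    },
    stop("unknown input type: ", config$input$type, call. = FALSE))
  say("call table: %d calls, %d callers", nrow(tab),
      length(unique(tab$subject_id)))

  tf <- default_transforms(if (config$positions == "untransformed")
    "untransformed" else "annotated")

  # stage 1: single-call variables over all calls
  single_cand <- setdiff(candidate_variables(), "inter_call_interval_s")
  fm1 <- apply_transforms(feature_matrix(tab, single_cand), tf)
  scr1 <- screen_correlations(fm1, config$r_threshold, config$vif_threshold)
  say("screening (single-call): retained %s",
      paste(scr1$retained, collapse = ", "))
  fm1 <- subset_variables(fm1, scr1$retained)

  cfg1 <- pdfa_config(config$n_selections, config$n_permutations,
                      seed = child_seed(config$seed, "pdfa1"))
  say("pDFA 1 (rest/travel/alert): %d selections, %d permutations",
      cfg1$n_selections, cfg1$n_permutations)
  pdfa1 <- run_pdfa(fm1, CONTEXTS, cfg1)
  loadings1 <- average_loadings(fm1, CONTEXTS, cfg1)

  # stage 2: bout-level variables. Screening happens once: the pairwise
  # rule over all calls (stage 1), then the interval joins the retained
  # set and the VIFs are re-checked over every call with a measurable
  # interval. The analysis itself is then restricted to travel/alert calls
  # (pooled two-context correlations are inflated by the context
  # separation and are not a collinearity problem).
  fm2_screen <- apply_transforms(
    feature_matrix(tab, c(scr1$retained, "inter_call_interval_s")), tf)
  scr2 <- screen_correlations(fm2_screen, r_threshold = 1,
                              vif_threshold = config$vif_threshold)
  bout_tab <- tab[tab$context %in% c("travel", "alert"), , drop = FALSE]
  n_ta <- nrow(bout_tab)
  fm2 <- apply_transforms(feature_matrix(bout_tab, scr2$retained), tf)
  say("bout-level analysis: %d of %d travel/alert calls have intervals",
      nrow(fm2$values), n_ta)
  cfg2 <- pdfa_config(config$n_selections, config$n_permutations,
                      seed = child_seed(config$seed, "pdfa2"))
  pdfa2 <- run_pdfa(fm2, c("travel", "alert"), cfg2)
  loadings2 <- average_loadings(fm2, c("travel", "alert"), cfg2)

  # stage 3: mixed models on the influential variables
  fm_lmm <- apply_transforms(feature_matrix(
    tab, setdiff(candidate_variables(), "inter_call_interval_s")), tf)
  fm_lmm_int <- apply_transforms(feature_matrix(
    bout_tab, candidate_variables()), tf)
  say("fitting context mixed models")
  lmms <- list(
    f0_max_hz = context_lmm(fm_lmm, lmm_spec("f0_max_hz")),
    duration_s = context_lmm(fm_lmm, lmm_spec("duration_s")),
    inter_call_interval_s = context_lmm(
      fm_lmm_int, lmm_spec("inter_call_interval_s",
                           controls = c("sex", "age"),
                           contexts = c("travel", "alert"))))

  bundle <- list(table = tab, screening_single = scr1, screening_bout = scr2,
                 pdfa1 = pdfa1, pdfa2 = pdfa2,
                 loadings1 = loadings1, loadings2 = loadings2,
                 lmms = lmms, config = config)

  if (!is.null(config$out_dir)) write_pipeline_outputs(bundle)
  invisible(bundle)
}

pipeline_results_list <- function(bundle) {
  lmm_json <- lapply(bundle$lmms, function(r) list(
    full_null = r$full_null,
    bonferroni_threshold = r$bonferroni$threshold_reported,
    significant = unname(r$bonferroni$significant),
    fixed_effects = r$full$fixed_effects,
    random_intercept_variance = r$full$random_intercept_variance,
    term_lrt = r$term_lrt))
  pd <- function(p) list(
    observed_rate = p$observed_rate, expected_rate = p$expected_rate,
    p_value = p$p_value, per_context_rates = as.list(p$per_context_rates),
    accounting = as.list(p$accounting), null_policy = p$null_policy,
    n_selections = p$config$n_selections,
    n_permutations = p$config$n_permutations)
  list(
    n_calls = nrow(bundle$table),
    n_subjects = length(unique(bundle$table$subject_id)),
    screening = list(
      single = list(retained = bundle$screening_single$retained,
                    discarded = bundle$screening_single$discarded),
      bout = list(retained = bundle$screening_bout$retained,
                  discarded = bundle$screening_bout$discarded)),
    pdfa1 = pd(bundle$pdfa1), pdfa2 = pd(bundle$pdfa2),
    mean_loadings1 = as.data.frame(round(bundle$loadings1, 4)),
    mean_loadings2 = as.data.frame(round(bundle$loadings2, 4)),
    lmm = lmm_json,
    seed = bundle$config$seed)
}

write_pipeline_outputs <- function(bundle) {
  dir.create(bundle$config$out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(bundle$config$out_dir, f)
  jsonlite::write_json(pipeline_results_list(bundle), path("results.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  write_screening_report(bundle$screening_single,
                         csv_path = path("screening_single.csv"))
  write_screening_report(bundle$screening_bout,
                         csv_path = path("screening_bout.csv"))
  if (bundle$config$input$type == "synthetic")
    write_call_table(bundle$table, path("calls.csv"))
  writeLines(render_report(bundle), path("report.md"))
  invisible(bundle$config$out_dir)
}

render_report <- function(bundle) {
  p1 <- bundle$pdfa1; p2 <- bundle$pdfa2
  fmt_load <- function(L) {
    df <- as.data.frame(round(L, 2))
    c(paste0("| variable | ", paste(colnames(df), collapse = " | "), " |"),
      paste0("|", paste(rep("---", ncol(df) + 1), collapse = "|"), "|"),
      sprintf("| %s | %s |", rownames(df),
              apply(df, 1, paste, collapse = " | ")))
  }
  fmt_lmm <- function(name, r) {
    fe <- r$full$fixed_effects
    c(sprintf("### %s", name),
      sprintf("full vs null: chi^2 = %.2f, d.f. = %d, p = %.3g (Bonferroni alpha %.3f)%s",
              r$full_null$chisq, r$full_null$df, r$full_null$p,
              r$bonferroni$threshold_reported,
              if (r$bonferroni$significant) " *" else ""),
      "",
      "| term | estimate | s.e. | t |", "|---|---|---|---|",
      sprintf("| %s | %.3f | %.3f | %.2f |", fe$term, fe$estimate, fe$se,
              fe$t), "")
  }
  c("# Context-specific hoo variants: analysis report",
    "",
    sprintf("%d calls from %d callers; seed %d.", nrow(bundle$table),
            length(unique(bundle$table$subject_id)), bundle$config$seed),
    "",
    "## Screening",
    sprintf("- single-call set: retained %s (discarded %s)",
            paste(bundle$screening_single$retained, collapse = ", "),
            paste(bundle$screening_single$discarded, collapse = ", ")),
    sprintf("- bout-level set: retained %s (discarded %s)",
            paste(bundle$screening_bout$retained, collapse = ", "),
            paste(bundle$screening_bout$discarded, collapse = ", ")),
    "",
    "## pDFA 1 (rest / travel / alert)",
    sprintf("observed %.1f%%, expected %.1f%%, p = %.4g; per context: %s",
            100 * p1$observed_rate, 100 * p1$expected_rate, p1$p_value,
            paste(sprintf("%s %.1f%%", names(p1$per_context_rates),
                          100 * p1$per_context_rates), collapse = ", ")),
    sprintf("calls: %d training, %d held-out, %d novel-caller",
            p1$accounting[["training"]], p1$accounting[["heldout"]],
            p1$accounting[["novel"]]),
    "", "Mean discriminant loadings (sign-aligned over selections):", "",
    fmt_load(bundle$loadings1),
    "",
    "## pDFA 2 (travel / alert, bout-level)",
    sprintf("observed %.1f%%, expected %.1f%%, p = %.4g; per context: %s",
            100 * p2$observed_rate, 100 * p2$expected_rate, p2$p_value,
            paste(sprintf("%s %.1f%%", names(p2$per_context_rates),
                          100 * p2$per_context_rates), collapse = ", ")),
    "", fmt_load(bundle$loadings2), "",
    "## Context mixed models",
    unlist(lapply(names(bundle$lmms),
                  function(n) fmt_lmm(n, bundle$lmms[[n]]))))
}
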