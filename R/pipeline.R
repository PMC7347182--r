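# Orchestration: tie the stages into reproducible end-to-end runs.

#' Full-run configuration
#'
#' Bundles the cohort, preprocessing and model configurations. A single
#' `seed` is expanded into per-stage substreams (cohort generation and
#' permutation testing draw from distinct seeds), so adding or removing the
#' permutation stage never perturbs the cohort.
#'
#' @param cohort A [cohort_config()].
#' @param prep A [prep_config()].
#' @param model A [model_config()].
#' @param n_permutations Permutations for the `permtest` stage (default 200,
#'   the desk-scale choice; use 1000 for a full run).
#' @param seed If non-`NULL`, overrides the cohort seed and derives the
#'   permutation seed from it.
#' @return A list of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(), prep = prep_config(),
                       model = model_config(), n_permutations = 200L,
                       seed = NULL) {
  if (!is.null(seed)) {
    cohort$seed <- as.integer(seed)
    model$seed <- as.integer((seed * 7919 + 104729) %% .Machine$integer.max)
  }
  model$n_permutations <- as.integer(n_permutations)
  structure(list(cohort = cohort, prep = prep, model = model),
            class = "run_config")
}

PIPELINE_STAGES <- c("simulate", "preprocess", "label", "stats",
                     "train-eval", "permtest")

#' Run the analysis pipeline
#'
#' Executes a prefix of the stage sequence
#' `simulate -> preprocess -> label -> stats -> train-eval -> permtest`,
#' each stage reading only prior-stage outputs. Reruns with the same
#' configuration reproduce identical artifacts.
#'
#' @param config A [run_config()].
#' @param stages Character vector of stages, or `"all"`. Must form a
#'   contiguous prefix of the stage sequence: requesting a stage without its
#'   predecessor is an error naming the stage to run first.
#' @param out_dir If non-`NULL`, artifacts are written there as delimited
#'   text (plus a JSON config echo and summary); floats at 6 significant
#'   digits, and MD5 hashes of the written stage outputs are recorded in the
#'   summary.
#' @return A list of class `semg_run` with the stage artifacts (`manifest`,
#'   `features`, `labelled`, `stats`, `cv`, `final`, `permtest` as far as
#'   requested) and a `summary` list of the headline numbers.
#' @examples
#' \donttest{
#' cfg <- run_config(cohort = cohort_config(n_subjects = 4,
#'                                          n_excluded_tests = 0, seed = 2))
#' run <- run_pipeline(cfg, stages = c("simulate", "preprocess", "label"))
#' }
#' @export
run_pipeline <- function(config = run_config(), stages = "all",
                         out_dir = NULL) {
  if (identical(stages, "all")) stages <- PIPELINE_STAGES
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  idx <- sort(match(stages, PIPELINE_STAGES))
  for (i in seq_along(idx)) {
    if (idx[i] != i)
      stop("stage '", PIPELINE_STAGES[idx[i]], "' requires '",
           PIPELINE_STAGES[idx[i] - 1], "'; run it first")
  }
  last <- PIPELINE_STAGES[max(idx)]
  art <- list(config = config)
  summary <- list()

  sch <- cohort_schedule(config$cohort)
  art$manifest <- sch$manifest
  incl <- sch$manifest[sch$manifest$included, ]
  summary$n_tests <- nrow(incl)
  summary$mean_duration_s <- mean(incl$duration_s)
  summary$sd_duration_s <- sd(incl$duration_s)

  if (match(last, PIPELINE_STAGES) >= 2) {
    feats <- cohort_features(config$cohort, config$prep)
    art$features <- feats$features
  }
  if (match(last, PIPELINE_STAGES) >= 3) {
    art$labelled <- label_features(art$features, art$manifest)
  }
  if (match(last, PIPELINE_STAGES) >= 4) {
    med <- subject_period_medians(art$labelled)
    corr <- correlation_table(art$labelled)
    art$stats <- list(
      medians = med,
      wilcoxon = pairwise_period_tests(med),
      correlations = corr,
      durations = period_duration_summary(art$manifest),
      candidate_features = feature_screening()
    )
    summary$candidate_features <- art$stats$candidate_features
  }
  if (match(last, PIPELINE_STAGES) >= 5) {
    mc <- config$model
    mc$candidate_features <- if (!is.null(art$stats))
      art$stats$candidate_features else feature_screening()
    art$cv <- nested_loso_cv(art$labelled, mc)
    sel <- select_final_model(art$cv)
    art$final <- final_loso_evaluation(art$labelled, sel$features, sel$k)
    summary$meta_c_index <- attr(art$cv, "meta_c_index")
    summary$final_features <- sel$features
    summary$final_k <- sel$k
    summary$final_c_index <- attr(art$final, "mean_c_index")
  }
  if (match(last, PIPELINE_STAGES) >= 6) {
    mc <- config$model
    mc$candidate_features <- summary$candidate_features
    art$permtest <- permutation_test(art$labelled, mc)
    summary$permutation_p <- art$permtest$p.value
  }

  art$summary <- summary
  if (!is.null(out_dir)) art <- write_run(art, out_dir, last)
  class(art) <- "semg_run"
  art
}

write_run <- function(art, out_dir, last) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sig <- function(df) {
    df[] <- lapply(df, function(x) if (is.numeric(x)) signif(x, 6) else x)
    df
  }
  files <- character(0)
  put <- function(df, name) {
    path <- file.path(out_dir, name)
    write.csv(sig(as.data.frame(df)), path, row.names = FALSE)
    files <<- c(files, path)
  }
  put(art$manifest, "manifest.csv")
  jsonlite::write_json(config_echo(art$config$cohort),
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(art$features)) put(art$features, "features.csv")
  if (!is.null(art$labelled)) put(art$labelled, "labelled_features.csv")
  if (!is.null(art$stats)) {
    put(art$stats$medians, "subject_period_medians.csv")
    put(art$stats$wilcoxon, "wilcoxon_grid.csv")
    put(as.data.frame(art$stats$correlations), "correlations.csv")
    put(art$stats$durations, "period_durations.csv")
  }
  if (!is.null(art$cv)) put(art$cv, "cv_folds.csv")
  if (!is.null(art$final)) put(art$final, "final_per_subject.csv")
  if (!is.null(art$permtest))
    put(data.frame(null_c_index = art$permtest$null), "permutation_null.csv")
  art$summary$file_hashes <- as.list(tools::md5sum(files))
  jsonlite::write_json(art$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  art
}

#' @export
print.semg_run <- function(x, ...) {
  s <- x$summary
  cat("<semg_run>\n")
  cat(sprintf("  %d analyzed tests, mean duration %.1f s (SD %.1f)\n",
              s$n_tests, s$mean_duration_s, s$sd_duration_s))
  if (!is.null(s$meta_c_index))
    cat(sprintf("  meta c-index %.3f; final model {%s}, k = %d, c-index %.3f\n",
                s$meta_c_index, paste(s$final_features, collapse = ", "),
                s$final_k, s$final_c_index))
  if (!is.null(s$permutation_p))
    cat(sprintf("  permutation p = %.4g\n", s$permutation_p))
  invisible(x)
}
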