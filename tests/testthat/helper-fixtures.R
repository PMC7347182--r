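# Shared fixtures: scaled-down cohort configurations, fabricated feature
# tables, and memoized Monte-Carlo replicates reused across test files.

fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, fn) {
  if (is.null(fixture_cache[[key]])) fixture_cache[[key]] <- fn()
  fixture_cache[[key]]
}

# Short-duration cohort configuration: same signal model as the default,
# fewer subjects and shorter tests, so generator-driven tests stay fast.
small_cohort_config <- function(seed, n_subjects = 6, tests_per_subject = 2,
                                n_excluded_tests = 0, gain_scale = NULL,
                                fluct_sdlog = NULL, thr = c(30, 10),
                                tol = c(22, 8)) {
  dp <- default_duration_params()
  dp$heat$threshold <- c(mean = thr[1], sd = thr[2])
  dp$heat$tolerance <- c(mean = tol[1], sd = tol[2])
  dp$electrical$threshold <- c(mean = thr[1] - 5, sd = thr[2])
  dp$electrical$tolerance <- c(mean = tol[1] - 4, sd = tol[2])
  ep <- default_envelope_params()
  if (!is.null(gain_scale)) ep$gain_scale <- gain_scale
  if (!is.null(fluct_sdlog)) ep$fluct_sdlog <- fluct_sdlog
  cohort_config(n_subjects = n_subjects,
                tests_per_subject = tests_per_subject,
                n_excluded_tests = n_excluded_tests,
                duration_params = dp, envelope_params = ep, seed = seed)
}

small_labelled <- function(cfg) {
  feats <- cohort_features(cfg)
  label_features(feats$features, feats$manifest)
}

# Fabricated standardized labelled table: features drawn directly in feature
# space (signal strength `beta` couples them to the period index), skipping
# signal synthesis. Used for model-machinery tests where the generator's
# physiology is irrelevant.
fabricate_labelled <- function(n_subjects, tests_per_subject = 2,
                               rows_per_test = 24, beta = 0,
                               features = c("corrms", "corwl", "levwl",
                                            "orbwl"),
                               seed = 1) {
  set.seed(seed)
  rows <- list()
  for (s in seq_len(n_subjects)) {
    for (tst in seq_len(tests_per_subject)) {
      per <- sort(rep_len(1:4, rows_per_test))
      df <- tibble::tibble(
        subject_id = sprintf("S%02d", s),
        test_id = sprintf("S%02d_T%d", s, tst),
        time_s = seq_len(rows_per_test),
        period = factor(paste0("P", per), levels = semgpain:::PERIODS,
                        ordered = TRUE)
      )
      for (f in features) df[[f]] <- beta * per + rnorm(rows_per_test)
      rows[[length(rows) + 1]] <- df
    }
  }
  dplyr::bind_rows(rows)
}

# Twenty scaled-down calibrated cohorts shared by the descriptive-statistics
# Monte-Carlo checks and the acceptance property suite. Each replicate keeps
# the per-replicate labelled table plus its correlation matrix.
mc_small_cohorts <- function() {
  memo("mc_small_cohorts", function() {
    lapply(1:20, function(i) {
      cfg <- small_cohort_config(seed = 500 + i, n_subjects = 12,
                                 tests_per_subject = 2)
      lab <- small_labelled(cfg)
      list(lab = lab, corr = correlation_table(lab))
    })
  })
}

# Ten small null cohorts (all envelope gains zero).
null_small_cohorts <- function() {
  memo("null_small_cohorts", function() {
    lapply(1:10, function(i) {
      cfg <- small_cohort_config(seed = 700 + i, n_subjects = 8,
                                 tests_per_subject = 2, gain_scale = 0)
      small_labelled(cfg)
    })
  })
}
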