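# Ordinal kNN model, concordance index, nested CV and permutation test.

test_that("c-index matches enumeration, AUC and the random baseline", {
  expect_equal(c_index(c(1, 2, 3, 4), c(1, 2, 3, 4)), 1)
  expect_equal(c_index(c(1, 1, 2, 3), c(1, 2, 2, 3)), 0.9)

  set.seed(71)
  truth <- sample(1:4, 10000, replace = TRUE)
  pred <- sample(1:4, 10000, replace = TRUE)
  expect_lt(abs(c_index(truth, pred) - 0.5), 0.02)

  # pairwise enumeration oracle on small random cases
  for (i in 1:20) {
    tr <- sample(1:4, 30, replace = TRUE)
    pr <- sample(1:4, 30, replace = TRUE)
    expect_equal(c_index(tr, pr), ci_pair_oracle(tr, pr), tolerance = 1e-12)
  }

  # binary labels: c-index equals rank-statistic AUC, ties included
  for (i in 1:20) {
    tr <- sample(0:1, 40, replace = TRUE)
    if (length(unique(tr)) < 2) next
    sc <- sample(seq(0, 1, 0.25), 40, replace = TRUE)
    expect_equal(c_index(tr, sc), auc_rank_oracle(tr, sc), tolerance = 1e-12)
  }

  # invariance under strictly increasing relabelling of predictions
  tr <- sample(1:4, 50, replace = TRUE)
  sc <- rnorm(50)
  expect_equal(c_index(tr, sc), c_index(tr, exp(sc)), tolerance = 1e-12)

  expect_warning(r <- c_index(rep(2, 5), 1:5), "no pairs")
  expect_true(is.na(r))
})

test_that("kNN prediction follows majority vote with ordinal tie-breaks", {
  train <- matrix(c(0, 0, 1, 1, 2, 2, 3, 3), ncol = 2, byrow = TRUE)
  y <- factor(paste0("P", 1:4), ordered = TRUE)
  expect_equal(as.character(knn_predict(train, y, train[2, , drop = FALSE],
                                        k = 1)), "P2")

  # neighbour labels {P2, P2, P4} -> P2
  train <- matrix(c(0, 1, 2, 10), ncol = 1)
  y <- factor(c("P2", "P2", "P4", "P4"), levels = paste0("P", 1:4),
              ordered = TRUE)
  expect_equal(as.character(knn_predict(train, y,
                                        matrix(0.5), k = 3)), "P2")

  # vote tie {P1, P3} at k = 2 resolves to the lower ordinal label
  train <- matrix(c(0, 1), ncol = 1)
  y <- factor(c("P3", "P1"), levels = paste0("P", 1:4), ordered = TRUE)
  expect_equal(as.character(knn_predict(train, y, matrix(0.5), k = 2)), "P1")

  expect_error(knn_predict(matrix(numeric(0), ncol = 1), factor(character()),
                           matrix(1), k = 1), "empty training set")
})

test_that("kNN agrees with a brute-force oracle across the k grid", {
  set.seed(72)
  train <- matrix(rnorm(200 * 3), ncol = 3)
  y <- factor(paste0("P", sample(1:4, 200, replace = TRUE)), ordered = TRUE)
  test <- matrix(rnorm(30 * 3), ncol = 3)
  for (k in c(1, 3, 7, 15, 31)) {
    expect_equal(knn_predict(train, y, test, k),
                 knn_bruteforce_oracle(train, y, test, k))
  }
})

test_that("leave-subject-out folds partition the subjects", {
  folds <- loso_folds(sprintf("S%02d", rep(1:31, each = 3)))
  expect_length(folds, 31)
  held <- vapply(folds, function(f) f$test, character(1))
  expect_equal(sort(held), sprintf("S%02d", 1:31))
  for (f in folds) expect_false(f$test %in% f$train)
  expect_error(loso_folds(rep("S01", 5)), "at least 2")
})

test_that("the compiled nested CV matches a plain-R reference", {
  cfg <- model_config(candidate_features = c("corrms", "corwl"),
                      k_grid = c(1L, 3L, 5L), seed = 1)
  for (seed in 1:3) {
    lab <- fabricate_labelled(n_subjects = 4, tests_per_subject = 1,
                              rows_per_test = 16, beta = 0.4,
                              features = cfg$candidate_features, seed = seed)
    eng <- nested_loso_cv(lab, cfg)
    ref <- r_nested_cv_oracle(lab, cfg)
    subsets <- attr(eng, "subsets")
    expect_equal(match(eng$features,
                       vapply(subsets, paste, collapse = ",",
                              FUN.VALUE = character(1))),
                 ref$sel_subset)
    expect_equal(eng$k, ref$sel_k)
    expect_equal(eng$c_index, ref$fold_cindex, tolerance = 1e-12)
    expect_equal(attr(eng, "meta_c_index"), ref$meta, tolerance = 1e-12)
  }
})

test_that("nested CV separates a strongly expressive, low-noise cohort", {
  cfg <- small_cohort_config(seed = 73, n_subjects = 5, gain_scale = 2,
                             fluct_sdlog = 0.1)
  lab <- small_labelled(cfg)
  cv <- nested_loso_cv(lab, model_config(seed = 74))
  expect_gt(attr(cv, "meta_c_index"), 0.9)
})

test_that("null feature tables carry no ordinal information", {
  metas <- vapply(1:10, function(i) {
    lab <- fabricate_labelled(n_subjects = 8, beta = 0, seed = 80 + i)
    attr(nested_loso_cv(lab, model_config(k_grid = seq(1L, 15L, 2L),
                                          seed = i)), "meta_c_index")
  }, numeric(1))
  expect_lt(abs(mean(metas) - 0.5), 0.05)
})

test_that("final-model selection is modal with deterministic tie-breaks", {
  cv <- tibble::tibble(
    subject_id = sprintf("S%02d", 1:5),
    features = c("corwl,levwl", "corwl,levwl", "corwl,levwl", "corwl",
                 "corrms"),
    k = c(5L, 7L, 7L, 3L, 9L),
    c_index = rep(0.6, 5))
  sel <- select_final_model(cv)
  expect_equal(sel$features, c("corwl", "levwl"))
  expect_equal(sel$k, 7L)

  # frequency tie between a 1-feature and a 2-feature subset
  cv$features <- c("corwl,levwl", "corwl,levwl", "corwl", "corwl", "corrms")
  expect_equal(select_final_model(cv)$features, "corwl")

  # k frequency tie resolves to the smaller k
  cv$features <- rep("corwl", 5)
  cv$k <- c(3L, 3L, 9L, 9L, 5L)
  expect_equal(select_final_model(cv)$k, 3L)

  cv$k <- rep(11L, 5)
  expect_equal(select_final_model(cv),
               list(features = "corwl", k = 11L))
})

test_that("final LOSO evaluation reports one score per subject", {
  lab <- fabricate_labelled(n_subjects = 6, beta = 0.6, seed = 75)
  fin <- final_loso_evaluation(lab, c("corrms", "corwl"), k = 5)
  expect_equal(nrow(fin), 6)
  expect_equal(attr(fin, "mean_c_index"), mean(fin$c_index))
  expect_true(min(fin$c_index) <= attr(fin, "mean_c_index"))
  expect_true(max(fin$c_index) >= attr(fin, "mean_c_index"))
  expect_false(is.unsorted(fin$c_index))
})

test_that("permutation p-values follow the add-one estimator", {
  expect_equal(semgpain:::perm_pvalue(0.3, rep(0.5, 10)), 1)
  expect_equal(semgpain:::perm_pvalue(0.9, rep(0.5, 19)), 1 / 20)
  expect_equal(semgpain:::perm_pvalue(0.5, c(0.4, 0.5, 0.6)), 3 / 4)

  lab <- fabricate_labelled(n_subjects = 6, beta = 0.8, seed = 76)
  pt <- permutation_test(lab, model_config(k_grid = seq(1L, 9L, 2L),
                                           n_permutations = 19, seed = 7))
  expect_equal(pt$p.value,
               semgpain:::perm_pvalue(pt$observed, pt$null))
  expect_length(pt$null, 19)
  expect_gt(pt$observed, max(pt$null)) # strong signal beats every null
  expect_equal(pt$p.value, 1 / 20)
})

test_that("permutation p-values are approximately uniform under the null", {
  hits <- vapply(1:50, function(i) {
    lab <- fabricate_labelled(n_subjects = 6, tests_per_subject = 2,
                              rows_per_test = 16, beta = 0, seed = 200 + i)
    pt <- permutation_test(lab, model_config(k_grid = c(1L, 5L, 9L),
                                             n_permutations = 39,
                                             seed = 300 + i))
    pt$p.value < 0.05
  }, logical(1))
  expect_lte(mean(hits), 0.14)
})

test_that("held-out labels never leak into model selection", {
  lab <- fabricate_labelled(n_subjects = 6, beta = 0.5, seed = 77)
  cfg <- model_config(candidate_features = c("corrms", "corwl", "levwl"),
                      k_grid = c(1L, 5L, 9L), seed = 1)
  cv <- nested_loso_cv(lab, cfg)
  corrupt <- lab
  rows <- corrupt$subject_id == "S01"
  set.seed(78)
  corrupt$period[rows] <- sample(corrupt$period[rows])
  cv2 <- nested_loso_cv(corrupt, cfg)
  # fold S01's inner selection is a function of the other subjects only
  expect_equal(cv2$features[cv2$subject_id == "S01"],
               cv$features[cv$subject_id == "S01"])
  expect_equal(cv2$k[cv2$subject_id == "S01"],
               cv$k[cv$subject_id == "S01"])
})

test_that("corwl is retained by model selection on the default cohort", {
  runs <- acceptance_runs()
  in_model <- vapply(runs, function(r) "corwl" %in% r$sel$features,
                     logical(1))
  expect_gte(mean(in_model), 0.8)
})
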