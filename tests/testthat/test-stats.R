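# Descriptive statistics: medians, Wilcoxon signed-rank, Spearman, the
# pairwise grid and feature screening.

test_that("subject-period medians pool rows across the subject's tests", {
  lab <- tibble::tibble(
    subject_id = "S01",
    test_id = c(rep("S01_T1", 3), rep("S01_T2", 3)),
    period = factor(c("P1", "P1", "P1", "P2", "P2", "P1"),
                    levels = semgpain:::PERIODS, ordered = TRUE),
    corwl = c(0.1, 0.3, 0.5, 1, 3, 5)
  )
  med <- subject_period_medians(lab)
  expect_equal(med$corwl[med$period == "P1"], median(c(0.1, 0.3, 0.5, 5)))
  expect_equal(med$corwl[med$period == "P2"], 2)

  # order invariance
  med2 <- subject_period_medians(lab[sample(nrow(lab)), ])
  expect_equal(dplyr::arrange(med2, period), dplyr::arrange(med, period))
})

test_that("Wilcoxon signed-rank matches analytic and enumeration references", {
  # all positive unit differences, n = 5: W = 15, exact p = 2/32
  res <- wilcoxon_signed_rank(c(2, 3, 4, 5, 6), c(1, 2, 3, 4, 5))
  expect_equal(res$p.value, 0.0625)
  expect_equal(res$statistic, 15)

  expect_warning(res <- wilcoxon_signed_rank(1:4, 1:4), "all paired")
  expect_equal(res$p.value, 1)

  set.seed(61)
  for (n in 4:10) {
    a <- rnorm(n)
    b <- rnorm(n)
    res <- wilcoxon_signed_rank(a, b)
    expect_equal(res$p.value, wilcoxon_enum_oracle(a, b), tolerance = 1e-12)
    # two-sided symmetry under sign flips
    flip <- wilcoxon_signed_rank(b, a)
    expect_equal(flip$p.value, res$p.value, tolerance = 1e-12)
  }
  # tied absolute differences keep the exact distribution
  for (n in 5:9) {
    a <- sample(1:4, n, replace = TRUE)
    b <- sample(1:4, n, replace = TRUE)
    if (all(a == b)) next
    expect_equal(wilcoxon_signed_rank(a, b)$p.value,
                 wilcoxon_enum_oracle(a, b), tolerance = 1e-12)
  }
  # agreement with wilcox.test's exact path when there are no ties
  a <- rnorm(12); b <- rnorm(12)
  ref <- wilcox.test(a, b, paired = TRUE, exact = TRUE)
  expect_equal(wilcoxon_signed_rank(a, b)$p.value, ref$p.value,
               tolerance = 1e-12)
})

test_that("Spearman's rho equals Pearson on average ranks", {
  expect_equal(spearman_rho(1:3, c(10, 20, 30)), 1)
  expect_equal(spearman_rho(1:3, c(3, 2, 1)), -1)
  expect_equal(spearman_rho(1:4, c(1, 1, 2, 2)), 4 / (2 * sqrt(5)),
               tolerance = 1e-12)
  set.seed(62)
  for (i in 1:10) {
    x <- sample(1:5, 30, replace = TRUE) # heavy ties
    y <- x + rnorm(30)
    expect_equal(spearman_rho(x, y), spearman_rank_oracle(x, y),
                 tolerance = 1e-12)
  }
  expect_warning(r <- spearman_rho(rep(1, 5), 1:5), "zero rank variance")
  expect_true(is.na(r))
})

test_that("the pairwise grid covers 10 features x 6 period pairs", {
  lab <- fabricate_labelled(n_subjects = 8, beta = 0.5,
                            features = semgpain:::FEATURES, seed = 63)
  med <- subject_period_medians(lab)
  grid <- pairwise_period_tests(med)
  expect_equal(nrow(grid), 60)
  expect_setequal(unique(grid$feature), semgpain:::FEATURES)
  expect_setequal(unique(grid$pair),
                  c("P1vP2", "P1vP3", "P1vP4", "P2vP3", "P2vP4", "P3vP4"))
  expect_true(all(grid$n == 8))
  expect_true(all(grid$p.value >= 0 & grid$p.value <= 1))
})

test_that("correlation matrix is symmetric with unit diagonal", {
  lab <- fabricate_labelled(n_subjects = 6, beta = 0.3,
                            features = semgpain:::FEATURES, seed = 64)
  cm <- correlation_table(lab)
  expect_equal(cm, t(cm))
  expect_equal(unname(diag(cm)), rep(1, 11))
  expect_true(all(cm >= -1 & cm <= 1))
  expect_equal(rownames(cm)[1], "period")
})

test_that("feature screening returns the canonical set and prunes redundancy", {
  expect_equal(feature_screening(), c("corrms", "corwl", "levwl", "orbwl"))

  feats <- semgpain:::FEATURES
  cm <- matrix(0.99, 11, 11, dimnames = list(c("period", feats),
                                             c("period", feats)))
  diag(cm) <- 1
  cm["period", feats] <- cm[feats, "period"] <- 0.5
  cm["period", "corwl"] <- cm["corwl", "period"] <- 0.9
  out <- feature_screening(cm, mode = "auto")
  expect_equal(out, "corwl") # all other features are clones of each other

  # relevance-ranked, capped at four, redundant features dropped
  cm2 <- diag(11)
  dimnames(cm2) <- dimnames(cm)
  cm2["period", feats] <- cm2[feats, "period"] <- seq(0.9, 0.1,
                                                      length.out = 10)
  out2 <- feature_screening(cm2, mode = "auto")
  expect_length(out2, 4)
  expect_equal(out2[1], feats[1])
})

test_that("corwl dominates the period correlation on calibrated cohorts", {
  reps <- mc_small_cohorts()
  ranks_first <- vapply(reps, function(r) {
    rho <- abs(r$corr["period", semgpain:::FEATURES])
    names(which.max(rho)) == "corwl"
  }, logical(1))
  expect_gte(mean(ranks_first), 0.8)
})

test_that("corwl separates the periods around the pain threshold", {
  # the threshold contrast is uniformly significant at full study scale, so
  # this check runs on the shared default-cohort replicates
  sig <- vapply(acceptance_runs(), function(r) {
    med <- suppressMessages(subject_period_medians(r$lab))
    grid <- pairwise_period_tests(med)
    p <- grid$p.value[grid$feature == "corwl" & grid$pair == "P2vP3"]
    is.finite(p) && p < 0.05
  }, logical(1))
  expect_gte(mean(sig), 0.9)
})

test_that("null cohorts keep the pairwise false-positive rate near nominal", {
  reps <- null_small_cohorts()
  pvals <- unlist(lapply(reps, function(lab) {
    med <- suppressMessages(subject_period_medians(lab))
    pairwise_period_tests(med)$p.value
  }))
  pvals <- pvals[is.finite(pvals)]
  frac <- mean(pvals < 0.05)
  expect_gte(frac, 0.005)
  expect_lte(frac, 0.10)
})
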