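# Nonparametric statistical evaluation of the standardized sEMG features:
# subject-level period medians, pairwise Wilcoxon signed-rank comparisons,
# Spearman inter-correlations and feature screening.

#' Subject-level per-period feature medians
#'
#' For each subject and pain period P1-P4 (the baseline P0 is excluded from
#' all statistics and modelling), the median of each standardized feature
#' over the pooled rows of all the subject's included tests - heat and
#' electrical analyzed together.
#'
#' @param labelled Standardized labelled feature table from
#'   [label_features()].
#' @return A tibble with `subject_id`, `period` and one median column per
#'   feature. Subject-period combinations with no rows are omitted with a
#'   message.
#' @export
subject_period_medians <- function(labelled) {
  feature_cols <- intersect(FEATURES, names(labelled))
  pain <- labelled[labelled$period != "P0", , drop = FALSE]
  pain$period <- droplevels(pain$period)
  out <- dplyr::summarise(
    dplyr::group_by(pain, .data$subject_id, .data$period),
    dplyr::across(dplyr::all_of(feature_cols), median),
    .groups = "drop")
  n_expected <- length(unique(pain$subject_id)) * nlevels(pain$period)
  if (nrow(out) < n_expected)
    message(n_expected - nrow(out),
            " subject-period combinations had no rows and were omitted")
  out
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Paired test on `a - b`: zero differences are dropped (the original
#' signed-rank procedure) and tied absolute differences receive average
#' ranks. For up to 25 nonzero differences the p-value comes from the exact
#' permutation distribution of the positive-rank sum, computed by dynamic
#' programming over the (possibly tied) ranks - unlike
#' [stats::wilcox.test()], which abandons exactness under ties. Above 25
#' the normal approximation with continuity correction is used.
#'
#' @param a,b Equal-length paired numeric vectors.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return A list with `statistic` (the positive-rank sum V), `p.value` and
#'   `n` (number of nonzero differences). If all differences are zero the
#'   p-value is 1, with a warning.
#' @examples
#' wilcoxon_signed_rank(c(2, 3, 4, 5, 6), c(1, 2, 3, 4, 5)) # exact p 0.0625
#' @export
wilcoxon_signed_rank <- function(a, b, alternative = c("two.sided", "less",
                                                       "greater")) {
  stopifnot(length(a) == length(b))
  alternative <- match.arg(alternative)
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all paired differences are zero; p = 1")
    return(list(statistic = NA_real_, p.value = 1, n = 0L))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 25) {
    p <- signed_rank_exact_p(r, W, alternative)
  } else {
    res <- suppressWarnings(
      wilcox.test(d, mu = 0, alternative = alternative, exact = FALSE,
                  correct = TRUE))
    p <- res$p.value
  }
  list(statistic = W, p.value = p, n = n)
}

# Exact distribution of the positive-rank sum over all 2^n sign
# assignments, on the doubled-rank integer scale so average ranks stay
# exact; O(n * sum(ranks)) by polynomial convolution.
signed_rank_exact_p <- function(r, W, alternative) {
  r2 <- as.integer(round(2 * r))
  f <- c(1, rep(0, sum(r2)))
  for (v in r2) {
    shifted <- c(rep(0, v), f[seq_len(length(f) - v)])
    f <- f + shifted
  }
  total <- sum(f)
  w2 <- as.integer(round(2 * W))
  upper <- sum(f[(w2 + 1):length(f)]) / total # P(W >= w)
  lower <- sum(f[seq_len(w2 + 1)]) / total    # P(W <= w)
  switch(alternative,
         greater = upper,
         less = lower,
         two.sided = min(1, if (w2 > sum(r2) / 2) 2 * upper else 2 * lower))
}

#' Pairwise period comparisons of subject medians
#'
#' The Wilcoxon signed-rank grid: each of the ten features compared across
#' the six period pairs (P1vP2, P1vP3, P1vP4, P2vP3, P2vP4, P3vP4), pairing
#' the subject-level medians of subjects present in both periods.
#'
#' @param median_table Output of [subject_period_medians()].
#' @param min_subjects Minimum number of common subjects required for a cell
#'   (default 6); sparser cells are reported as `NA`.
#' @return A tibble with `feature`, `pair`, `n` and `p.value`.
#' @export
pairwise_period_tests <- function(median_table, min_subjects = 6L) {
  feature_cols <- intersect(FEATURES, names(median_table))
  pain_periods <- c("P1", "P2", "P3", "P4")
  pairs <- utils::combn(pain_periods, 2, simplify = FALSE)
  grid <- lapply(feature_cols, function(f) {
    cells <- lapply(pairs, function(pp) {
      x <- median_table[median_table$period == pp[1], c("subject_id", f)]
      y <- median_table[median_table$period == pp[2], c("subject_id", f)]
      common <- intersect(x$subject_id, y$subject_id)
      if (length(common) < min_subjects)
        return(tibble::tibble(feature = f,
                              pair = paste0(pp[1], "v", pp[2]),
                              n = length(common), p.value = NA_real_))
      xa <- x[[f]][match(common, x$subject_id)]
      yb <- y[[f]][match(common, y$subject_id)]
      res <- wilcoxon_signed_rank(xa, yb)
      tibble::tibble(feature = f, pair = paste0(pp[1], "v", pp[2]),
                     n = res$n, p.value = res$p.value)
    })
    dplyr::bind_rows(cells)
  })
  dplyr::bind_rows(grid)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks; ties receive average ranks. Returns
#' `NA` with a warning when either argument has zero rank variance.
#'
#' @param x,y Equal-length numeric vectors of at least 3 values.
#' @return Spearman's rho in `[-1, 1]`, or `NA`.
#' @examples
#' spearman_rho(1:4, c(1, 1, 2, 2)) # 0.8944
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    warning("zero rank variance; Spearman's rho undefined")
    return(NA_real_)
  }
  cor(x, y, method = "spearman")
}

#' Feature / period-index correlation matrix
#'
#' Spearman's rho between every pair of the ten standardized features and
#' between each feature and the ordinal period index (P1 = 1 ... P4 = 4),
#' computed over all P1-P4 rows.
#'
#' @param labelled Standardized labelled feature table.
#' @return A symmetric correlation matrix with `period` as its first
#'   row/column.
#' @export
correlation_table <- function(labelled) {
  feature_cols <- intersect(FEATURES, names(labelled))
  pain <- labelled[labelled$period != "P0", , drop = FALSE]
  dat <- cbind(period = as.integer(droplevels(pain$period)),
               as.matrix(pain[, feature_cols]))
  cor(dat, method = "spearman")
}

#' Screen candidate features for the prediction model
#'
#' In `"fixed"` mode (default) returns the canonical candidate set
#' `corrms, corwl, levwl, orbwl` - the corrugator pair plus the two
#' waveform-length features of the muscles most associated with the pain
#' threshold. In `"auto"` mode, features are ranked by `|rho|` against the
#' period index and greedily accepted unless their pairwise `|rho|` with an
#' already-kept feature exceeds `redundancy_threshold`, returning at most
#' `max_features` features (falling back to the top-ranked feature if the
#' redundancy rule empties the set).
#'
#' @param correlation_matrix Output of [correlation_table()].
#' @param mode `"fixed"` or `"auto"`.
#' @param redundancy_threshold Pairwise `|rho|` above which a feature is
#'   considered redundant (default 0.80).
#' @param max_features Maximum size of the candidate set (default 4).
#' @return Character vector of feature names.
#' @export
feature_screening <- function(correlation_matrix = NULL,
                              mode = c("fixed", "auto"),
                              redundancy_threshold = 0.80,
                              max_features = 4L) {
  mode <- match.arg(mode)
  if (mode == "fixed") return(c("corrms", "corwl", "levwl", "orbwl"))
  stopifnot(!is.null(correlation_matrix),
            "period" %in% rownames(correlation_matrix))
  feats <- setdiff(rownames(correlation_matrix), "period")
  relevance <- abs(correlation_matrix["period", feats])
  ranked <- feats[order(-relevance, feats)]
  keep <- character(0)
  for (f in ranked) {
    if (length(keep) >= max_features) break
    if (all(abs(correlation_matrix[f, keep]) <= redundancy_threshold))
      keep <- c(keep, f)
  }
  if (length(keep) == 0) keep <- ranked[1]
  keep
}
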