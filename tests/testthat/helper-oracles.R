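# Independent reference implementations used as oracles. These deliberately
# avoid the package's computational paths: pairwise enumeration, explicit
# loops, and rank statistics.

# c-index by explicit enumeration of all comparable pairs.
ci_pair_oracle <- function(truth, pred) {
  truth <- as.numeric(truth)
  pred <- as.numeric(pred)
  credit <- 0
  comparable <- 0
  n <- length(truth)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (truth[i] == truth[j]) next
      comparable <- comparable + 1
      lo <- if (truth[i] < truth[j]) i else j
      hi <- if (truth[i] < truth[j]) j else i
      if (pred[lo] < pred[hi]) credit <- credit + 1
      else if (pred[lo] == pred[hi]) credit <- credit + 0.5
    }
  }
  credit / comparable
}

# AUC of binary labels via the rank-sum statistic (average ranks handle
# tied scores as half credit).
auc_rank_oracle <- function(binary_truth, score) {
  r <- rank(score)
  n1 <- sum(binary_truth == max(binary_truth))
  n0 <- length(binary_truth) - n1
  (sum(r[binary_truth == max(binary_truth)]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

# Exact two-sided signed-rank p-value by enumerating all 2^n sign vectors,
# mirroring the standard two-sided rule on the positive-rank sum.
wilcoxon_enum_oracle <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n >= 1, n <= 12)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  dist <- as.vector(signs %*% r)
  mu <- n * (n + 1) / 4
  p <- if (W > mu) 2 * mean(dist >= W) else 2 * mean(dist <= W)
  min(1, p)
}

# Pearson correlation of average ranks.
spearman_rank_oracle <- function(x, y) {
  cor(rank(x), rank(y))
}

# Hampel by direct sliding-window medians (truncated windows at the edges).
hampel_oracle <- function(x, k = 3, t = 3) {
  n <- length(x)
  if (n < 2 * k + 1) return(x)
  out <- x
  for (i in seq_len(n)) {
    win <- x[max(1, i - k):min(n, i + k)]
    m <- sort(win)[ceiling(length(win) / 2)]
    if (length(win) %% 2 == 0) {
      s <- sort(win)
      m <- (s[length(win) / 2] + s[length(win) / 2 + 1]) / 2
    }
    dev <- abs(win - m)
    sdev <- sort(dev)
    mad_ <- if (length(dev) %% 2 == 0)
      (sdev[length(dev) / 2] + sdev[length(dev) / 2 + 1]) / 2
    else sdev[ceiling(length(dev) / 2)]
    if (abs(x[i] - m) > t * 1.4826 * mad_) out[i] <- m
  }
  out
}

# Brute-force kNN with the package's stated tie rules, written as explicit
# per-row loops with incremental neighbour selection (no order()/matrix ops).
knn_bruteforce_oracle <- function(train_x, train_y, test_x, k) {
  train_x <- as.matrix(train_x)
  test_x <- as.matrix(test_x)
  lev <- levels(factor(train_y))
  y <- as.integer(factor(train_y, levels = lev))
  out <- integer(nrow(test_x))
  for (i in seq_len(nrow(test_x))) {
    d <- numeric(nrow(train_x))
    for (j in seq_len(nrow(train_x)))
      d[j] <- sum((train_x[j, ] - test_x[i, ])^2)
    chosen <- integer(0)
    avail <- rep(TRUE, length(d))
    for (step in seq_len(k)) {
      best <- 0
      for (j in seq_len(length(d))) {
        if (!avail[j]) next
        if (best == 0 || d[j] < d[best]) best <- j
      }
      avail[best] <- FALSE
      chosen <- c(chosen, best)
    }
    counts <- integer(length(lev))
    for (j in chosen) counts[y[j]] <- counts[y[j]] + 1
    out[i] <- which(counts == max(counts))[1]
  }
  factor(lev[out], levels = lev, ordered = TRUE)
}

# Plain-R nested leave-subject-out CV built from the exported primitives
# knn_predict() and c_index(), with the same tie-break conventions as the
# compiled engine (subsets by size then lexicographic order, k ascending).
r_nested_cv_oracle <- function(labelled, config) {
  pain <- labelled[labelled$period != "P0", , drop = FALSE]
  pain$period <- droplevels(pain$period)
  subs <- sort(unique(pain$subject_id))
  subsets <- semgpain:::feature_subsets(config$candidate_features)
  kg <- config$k_grid
  res <- lapply(subs, function(A) {
    score <- matrix(0, length(subsets), length(kg))
    n_inner <- 0
    for (B in setdiff(subs, A)) {
      tr <- pain[!(pain$subject_id %in% c(A, B)), , drop = FALSE]
      te <- pain[pain$subject_id == B, , drop = FALSE]
      if (length(unique(te$period)) < 2) next
      n_inner <- n_inner + 1
      for (si in seq_along(subsets)) {
        for (m in seq_along(kg)) {
          pr <- knn_predict(tr[, subsets[[si]], drop = FALSE], tr$period,
                            te[, subsets[[si]], drop = FALSE],
                            min(kg[m], nrow(tr)))
          score[si, m] <- score[si, m] + c_index(te$period, pr)
        }
      }
    }
    best_si <- 1; best_m <- 1; best <- -Inf
    for (si in seq_along(subsets)) {
      for (m in seq_along(kg)) {
        if (score[si, m] > best) {
          best <- score[si, m]; best_si <- si; best_m <- m
        }
      }
    }
    tr <- pain[pain$subject_id != A, , drop = FALSE]
    te <- pain[pain$subject_id == A, , drop = FALSE]
    ci <- NA_real_
    if (length(unique(te$period)) >= 2) {
      pr <- knn_predict(tr[, subsets[[best_si]], drop = FALSE], tr$period,
                        te[, subsets[[best_si]], drop = FALSE],
                        min(kg[best_m], nrow(tr)))
      ci <- c_index(te$period, pr)
    }
    list(subset = best_si, k = kg[best_m], ci = ci)
  })
  fold_ci <- vapply(res, function(r) r$ci, numeric(1))
  list(sel_subset = vapply(res, function(r) as.integer(r$subset), integer(1)),
       sel_k = vapply(res, function(r) as.integer(r$k), integer(1)),
       fold_cindex = fold_ci,
       meta = mean(fold_ci, na.rm = TRUE))
}
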