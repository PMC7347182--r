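# Ordinal kNN pain-intensity model: concordance index, leave-subject-out
# folds, nested cross-validated meta-learning, final evaluation and the
# permutation significance test. The combinatorial inner search runs in
# compiled code (src/knn_engine.cpp) on precomputed nearest-neighbour tables.

#' Model configuration
#'
#' @param candidate_features Candidate feature names searched by the inner
#'   loop (default the screened set `corrms, corwl, levwl, orbwl`; every
#'   non-empty subset is evaluated).
#' @param k_grid Neighbour counts to search; odd values 1-31 by default.
#' @param distance Distance metric (only `"euclidean"` is implemented).
#' @param n_permutations Number of label permutations for
#'   [permutation_test()] (1000 in full runs; 200 is a practical desk-scale
#'   default).
#' @param seed Integer seed for permutation randomness.
#' @return A list of class `model_config`.
#' @export
model_config <- function(candidate_features = feature_screening(),
                         k_grid = seq(1L, 31L, 2L),
                         distance = "euclidean",
                         n_permutations = 1000L,
                         seed = 1L) {
  stopifnot(length(candidate_features) >= 1, all(k_grid >= 1),
            identical(distance, "euclidean"), n_permutations >= 19)
  structure(list(candidate_features = candidate_features,
                 k_grid = sort(as.integer(unique(k_grid))),
                 distance = distance,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Concordance index for ordinal predictions
#'
#' Over all pairs `(i, j)` whose true labels differ (`true_i < true_j`), the
#' pair scores 1 if the predictions are ordered the same way, 0.5 if they are
#' tied and 0 otherwise; the c-index is the mean score. It generalizes the
#' area under the ROC curve to ordinal outcomes: 1 is perfect concordance,
#' 0.5 is random, values below 0.5 are discordant. Computed from the
#' label-by-prediction contingency table, so it scales to large inputs.
#'
#' @param truth True ordinal labels (ordered factor, or anything coercible
#'   to one by sorted unique values).
#' @param pred Predicted ordinal labels on the same scale.
#' @return The c-index in `[0, 1]`, or `NA` (with a warning) when no pair of
#'   true labels differs.
#' @examples
#' c_index(c(1, 1, 2, 3), c(1, 2, 2, 3)) # 0.9
#' @export
c_index <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  lev <- if (is.factor(truth)) levels(truth) else sort(unique(c(truth, pred)))
  ti <- as.integer(factor(truth, levels = lev, ordered = TRUE))
  pi_ <- as.integer(factor(pred, levels = lev, ordered = TRUE))
  stopifnot(!anyNA(ti), !anyNA(pi_))
  tab <- table(factor(ti, levels = seq_along(lev)),
               factor(pi_, levels = seq_along(lev)))
  tab <- matrix(as.numeric(tab), nrow(tab))
  L <- nrow(tab)
  n_true <- rowSums(tab)
  comparable <- 0
  credit <- 0
  for (a in seq_len(L - 1)) {
    for (b in (a + 1):L) {
      comparable <- comparable + n_true[a] * n_true[b]
      # predictions: concordant p < q, tied p == q
      cum_b <- cumsum(tab[b, ])
      if (L > 1) {
        credit <- credit +
          sum(tab[a, seq_len(L - 1)] * (cum_b[L] - cum_b[seq_len(L - 1)])) +
          0.5 * sum(tab[a, ] * tab[b, ])
      }
    }
  }
  if (comparable == 0) {
    warning("no pairs with differing true labels; c-index undefined")
    return(NA_real_)
  }
  credit / comparable
}

#' k-nearest-neighbour ordinal prediction
#'
#' Euclidean-distance majority vote: each test row takes the most frequent
#' label among its `k` nearest training rows. Voting ties are broken by the
#' lower ordinal label (then by the smaller mean neighbour distance, which
#' the first rule already decides); equidistant neighbours at the window edge
#' are taken in training-row order.
#'
#' @param train_x Numeric training matrix (rows standardized features).
#' @param train_y Training labels (ordered factor).
#' @param test_x Numeric matrix of rows to predict.
#' @param k Number of neighbours (`k <= nrow(train_x)`).
#' @return Predicted labels as an ordered factor with the training levels.
#' @export
knn_predict <- function(train_x, train_y, test_x, k) {
  train_x <- as.matrix(train_x)
  test_x <- as.matrix(test_x)
  if (nrow(train_x) == 0) stop("empty training set")
  stopifnot(k >= 1, k <= nrow(train_x), ncol(train_x) == ncol(test_x))
  lev <- levels(factor(train_y))
  y <- as.integer(factor(train_y, levels = lev))
  preds <- integer(nrow(test_x))
  for (i in seq_len(nrow(test_x))) {
    d2 <- colSums((t(train_x) - test_x[i, ])^2)
    nb <- order(d2, seq_along(d2))[seq_len(k)]
    cnt <- tabulate(y[nb], nbins = length(lev))
    preds[i] <- which.max(cnt) # first max = lowest ordinal label
  }
  factor(lev[preds], levels = lev, ordered = TRUE)
}

#' Leave-subject-out folds
#'
#' One fold per subject, in sorted subject-id order; each fold holds out all
#' rows of that subject, so no subject contributes to both sides.
#'
#' @param subject_ids Vector of per-row subject identifiers (or a data frame
#'   with a `subject_id` column).
#' @return A list of folds, each a list with `train` and `test` subject ids.
#' @export
loso_folds <- function(subject_ids) {
  if (is.data.frame(subject_ids)) subject_ids <- subject_ids$subject_id
  subjects <- sort(unique(as.character(subject_ids)))
  if (length(subjects) < 2) stop("leave-subject-out needs at least 2 subjects")
  lapply(subjects, function(s)
    list(train = setdiff(subjects, s), test = s))
}

# Enumerate non-empty subsets of the candidate features, ordered by size
# then lexicographically - the deterministic tie-break order of the search.
feature_subsets <- function(candidates) {
  idx <- seq_along(candidates)
  subsets <- unlist(lapply(idx, function(m)
    utils::combn(idx, m, simplify = FALSE)), recursive = FALSE)
  lapply(subsets, function(s) candidates[s])
}

# Shared engine state: per-subset neighbour tables plus integer encodings.
build_knn_engine <- function(labelled, config, n_keep = 256L,
                             subsets = NULL) {
  pain <- labelled[labelled$period != "P0", , drop = FALSE]
  missing <- setdiff(config$candidate_features, names(pain))
  if (length(missing) > 0)
    stop("candidate features absent from the table: ",
         paste(missing, collapse = ", "))
  subjects <- sort(unique(pain$subject_id))
  subj0 <- match(pain$subject_id, subjects) - 1L
  labels <- as.integer(droplevels(pain$period))
  if (is.null(subsets)) subsets <- feature_subsets(config$candidate_features)
  Xs <- lapply(subsets, function(s) as.matrix(pain[, s, drop = FALSE]))
  n_keep <- min(n_keep, nrow(pain) - 1L)
  neigh <- lapply(Xs, function(X) knn_neighbor_table(X, subj0, n_keep))
  list(pain = pain, subjects = subjects, subj0 = subj0, labels = labels,
       n_labels = max(labels), subsets = subsets, Xs = Xs, neigh = neigh,
       k_grid = config$k_grid)
}

#' Nested leave-subject-out cross-validation
#'
#' The meta-learning estimate: for each outer fold (held-out subject), an
#' inner leave-subject-out CV over the remaining subjects scores every
#' non-empty subset of the candidate features crossed with every `k`; the
#' best inner mean c-index (ties resolved toward the smaller subset, then
#' the smaller `k`) is refit on all inner data and scored on the held-out
#' subject. The aggregate statistic is the unweighted mean of the
#' per-subject fold c-indices.
#'
#' @param labelled Standardized labelled feature table (P0 rows are ignored).
#' @param config A [model_config()].
#' @return A tibble of class `semg_cv` with one row per outer fold:
#'   `subject_id`, `features` (comma-joined selected subset), `k` and
#'   `c_index` (`NA` for skipped folds, e.g. a held-out subject with fewer
#'   than two distinct labels). The aggregate mean is attached as attribute
#'   `"meta_c_index"`.
#' @export
nested_loso_cv <- function(labelled, config = model_config()) {
  eng <- build_knn_engine(labelled, config)
  if (length(eng$subjects) < 2) stop("need at least 2 subjects")
  res <- knn_nested_cv(eng$neigh, eng$Xs, eng$subj0, eng$labels,
                       eng$k_grid, eng$n_labels)
  if (anyNA(res$fold_cindex))
    warning(sum(is.na(res$fold_cindex)),
            " fold(s) skipped (held-out subject with < 2 distinct labels)")
  out <- tibble::tibble(
    subject_id = eng$subjects,
    features = vapply(eng$subsets[res$sel_subset],
                      paste, collapse = ",", FUN.VALUE = character(1)),
    k = res$sel_k,
    c_index = res$fold_cindex
  )
  attr(out, "meta_c_index") <- mean(res$fold_cindex, na.rm = TRUE)
  attr(out, "subsets") <- eng$subsets
  class(out) <- c("semg_cv", class(out))
  out
}

#' @export
print.semg_cv <- function(x, ...) {
  cat(sprintf("<nested LOSO CV: %d folds, meta c-index %.3f>\n",
              nrow(x), attr(x, "meta_c_index")))
  NextMethod()
}

#' Select the final model from nested-CV results
#'
#' The modal (most frequently selected) feature subset across outer folds,
#' then the modal `k` among the folds that chose it; frequency ties resolve
#' toward the smaller subset (then lexicographic order), and `k` ties toward
#' the smaller `k`.
#'
#' @param cv_result Output of [nested_loso_cv()].
#' @return A list with `features` (character vector) and `k`.
#' @export
select_final_model <- function(cv_result) {
  stopifnot(nrow(cv_result) > 0)
  feats <- cv_result$features
  counts <- table(feats)
  cand <- names(counts)[counts == max(counts)]
  sizes <- lengths(strsplit(cand, ","))
  cand <- cand[order(sizes, cand)]
  chosen <- cand[1]
  ks <- cv_result$k[feats == chosen]
  kt <- table(ks)
  k_modal <- min(as.integer(names(kt)[kt == max(kt)]))
  list(features = strsplit(chosen, ",")[[1]], k = k_modal)
}

#' Final plain leave-subject-out evaluation
#'
#' With the feature subset and `k` fixed a priori (from
#' [select_final_model()]), trains on all other subjects for each subject in
#' turn and reports that subject's c-index - the per-subject concordance
#' profile and its unweighted mean, the headline performance estimate.
#'
#' @param labelled Standardized labelled feature table.
#' @param features Character vector of feature names.
#' @param k Neighbour count.
#' @return A tibble (`subject_id`, `c_index`) ordered by score, with the
#'   mean attached as attribute `"mean_c_index"`.
#' @export
final_loso_evaluation <- function(labelled, features, k) {
  cfg <- model_config(candidate_features = features, k_grid = k,
                      n_permutations = 19L)
  # single subset: the engine reduces to the plain LOSO path
  eng <- build_knn_engine(labelled, cfg, subsets = list(features))
  ci <- knn_final_loso(eng$neigh[[1]], eng$Xs[[1]],
                       eng$subj0, eng$labels, as.integer(k), eng$n_labels)
  out <- tibble::tibble(subject_id = eng$subjects, c_index = ci)
  out <- out[order(out$c_index), ]
  attr(out, "mean_c_index") <- mean(ci, na.rm = TRUE)
  out
}

# Add-one permutation p-value.
perm_pvalue <- function(observed, null) {
  (1 + sum(null >= observed)) / (1 + length(null))
}

#' Permutation significance test of the nested-CV classifier
#'
#' Tests the null hypothesis that the classifier's performance arises by
#' chance: period labels are randomly permuted within each test (features
#' and the subject/test structure untouched), the full nested
#' leave-subject-out CV statistic is recomputed for each permutation, and
#' the add-one p-value `(1 + #\{null >= observed\}) / (1 + B)` is reported.
#'
#' @param labelled Standardized labelled feature table.
#' @param config A [model_config()]; `n_permutations` and `seed` control the
#'   null distribution.
#' @return A list of class `semg_permtest` with `observed` (nested-CV meta
#'   c-index), `null` (vector of permuted statistics) and `p.value`.
#' @export
permutation_test <- function(labelled, config = model_config()) {
  eng <- build_knn_engine(labelled, config)
  obs_res <- knn_nested_cv(eng$neigh, eng$Xs, eng$subj0, eng$labels,
                           eng$k_grid, eng$n_labels)
  observed <- mean(obs_res$fold_cindex, na.rm = TRUE)
  B <- config$n_permutations
  set.seed(config$seed)
  test_idx <- split(seq_along(eng$labels), eng$pain$test_id)
  labmat <- matrix(0L, length(eng$labels), B)
  for (b in seq_len(B)) {
    col <- eng$labels
    for (idx in test_idx) col[idx] <- col[idx][sample.int(length(idx))]
    labmat[, b] <- col
  }
  null <- knn_perm_null(eng$neigh, eng$Xs, eng$subj0, labmat,
                        eng$k_grid, eng$n_labels)
  structure(list(observed = observed, null = null,
                 p.value = perm_pvalue(observed, null),
                 n_permutations = B),
            class = "semg_permtest")
}

#' @export
print.semg_permtest <- function(x, ...) {
  cat(sprintf("<permutation test: observed %.3f, null mean %.3f (B = %d), p = %.4g>\n",
              x$observed, mean(x$null), x$n_permutations, x$p.value))
  invisible(x)
}
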