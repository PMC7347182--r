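// Compiled hot path for the ordinal kNN meta-learning model.
//
// The nested leave-subject-out search evaluates every candidate feature
// subset crossed with every k, for every (outer, inner) subject pair, and
// the permutation test repeats that search hundreds of times with permuted
// labels. Distances never change across folds or permutations, so each
// subset's nearest neighbours (excluding same-subject rows) are precomputed
// once; fold-specific exclusions are applied by skipping rows while walking
// the stored list, with an exact full-scan fallback when a fold's exclusions
// exhaust it. The c-index of 4-level ordinal predictions is computed from
// the label-by-prediction contingency table in constant time.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

static const int MAX_LABELS = 16;

static inline double dist2_row(const NumericMatrix& X, int i, int j) {
  double s = 0.0;
  for (int c = 0; c < X.ncol(); ++c) {
    const double d = X(i, c) - X(j, c);
    s += d * d;
  }
  return s;
}

// Per-subset nearest neighbours of every row among other-subject rows,
// sorted by (squared distance, row index); -1 pads short lists. Distances
// are accumulated by contiguous column sweeps (vectorizable), then the top
// n_keep are selected with nth_element + sort.
// [[Rcpp::export]]
IntegerMatrix knn_neighbor_table(NumericMatrix X, IntegerVector subject,
                                 int n_keep) {
  const int n = X.nrow(), d = X.ncol();
  IntegerMatrix out(n, n_keep);
  std::vector<const double*> col(d);
  for (int c = 0; c < d; ++c) col[c] = &X(0, c);
  std::vector<double> d2(n);
  std::vector<int> idx;
  idx.reserve(n);
  for (int i = 0; i < n; ++i) {
    std::fill(d2.begin(), d2.end(), 0.0);
    for (int c = 0; c < d; ++c) {
      const double* xc = col[c];
      const double xi = xc[i];
      double* dp = d2.data();
      for (int j = 0; j < n; ++j) {
        const double diff = xc[j] - xi;
        dp[j] += diff * diff;
      }
    }
    idx.clear();
    const int si = subject[i];
    for (int j = 0; j < n; ++j)
      if (subject[j] != si) idx.push_back(j);
    const int keep = std::min((int)idx.size(), n_keep);
    const double* dp = d2.data();
    struct Cmp {
      const double* dp;
      bool operator()(int a, int b) const {
        return dp[a] < dp[b] || (dp[a] == dp[b] && a < b);
      }
    } cmp = {dp};
    std::nth_element(idx.begin(), idx.begin() + keep, idx.end(), cmp);
    std::sort(idx.begin(), idx.begin() + keep, cmp);
    for (int t = 0; t < n_keep; ++t)
      out(i, t) = (t < keep) ? idx[t] : -1;
  }
  return out;
}

struct SubsetData {
  std::vector<int> nb; // row-major n x n_keep neighbour lists
  NumericMatrix X;     // features, for the exact fallback
  int n_keep;
};

struct EngineData {
  std::vector<SubsetData> subsets;
  std::vector<int> subj;
  std::vector<std::vector<int> > rows_by_subject;
  std::vector<int> kgrid;
  int n, S, L, kmax;
};

static EngineData make_engine(List neigh, List Xs, IntegerVector subject,
                              IntegerVector kgrid, int n_labels) {
  EngineData E;
  E.n = subject.size();
  E.subj.assign(subject.begin(), subject.end());
  E.S = 0;
  for (int i = 0; i < E.n; ++i) E.S = std::max(E.S, E.subj[i] + 1);
  E.rows_by_subject.assign(E.S, std::vector<int>());
  for (int i = 0; i < E.n; ++i) E.rows_by_subject[E.subj[i]].push_back(i);
  E.kgrid.assign(kgrid.begin(), kgrid.end());
  E.kmax = E.kgrid.back();
  E.L = n_labels;
  if (E.L > MAX_LABELS) stop("too many ordinal levels");
  for (int s = 0; s < neigh.size(); ++s) {
    SubsetData sd;
    IntegerMatrix nm = neigh[s];
    sd.n_keep = nm.ncol();
    sd.nb.resize((size_t)E.n * sd.n_keep);
    for (int i = 0; i < E.n; ++i)
      for (int t = 0; t < sd.n_keep; ++t)
        sd.nb[(size_t)i * sd.n_keep + t] = nm(i, t);
    sd.X = as<NumericMatrix>(Xs[s]);
    E.subsets.push_back(sd);
  }
  return E;
}

// Majority vote (ties -> lower ordinal label) over the first k valid
// neighbours, for every k in the grid at once. Returns predictions 1..L in
// out[0..nk-1]. e1/e2 are fold-excluded subjects (-1 for none).
static void predict_row(const EngineData& E, const SubsetData& sd,
                        const int* lab, int r, int e1, int e2, int* out) {
  const int nk = (int)E.kgrid.size();
  int cnt[MAX_LABELS];
  std::fill(cnt, cnt + E.L, 0);
  int got = 0, ki = 0, best = 0;
  const int* nb = &sd.nb[(size_t)r * sd.n_keep];
  for (int t = 0; t < sd.n_keep && ki < nk; ++t) {
    const int j = nb[t];
    if (j < 0) break;
    const int s = E.subj[j];
    if (s == e1 || s == e2) continue;
    const int l = lab[j] - 1;
    ++cnt[l];
    ++got;
    if (got == 1 || cnt[l] > cnt[best] || (cnt[l] == cnt[best] && l < best))
      best = l;
    if (got == E.kgrid[ki]) out[ki++] = best + 1;
  }
  if (ki == nk) return;
  // Stored list exhausted before kmax: exact full scan over all eligible
  // training rows (also covers folds where fewer than kmax rows exist).
  std::vector<std::pair<double, int> > cand;
  for (int j = 0; j < E.n; ++j) {
    const int s = E.subj[j];
    if (s == E.subj[r] || s == e1 || s == e2) continue;
    cand.push_back(std::make_pair(dist2_row(sd.X, r, j), j));
  }
  std::sort(cand.begin(), cand.end());
  std::fill(cnt, cnt + E.L, 0);
  got = 0; ki = 0; best = 0;
  for (size_t t = 0; t < cand.size() && ki < nk; ++t) {
    const int l = lab[cand[t].second] - 1;
    ++cnt[l];
    ++got;
    if (got == 1 || cnt[l] > cnt[best] || (cnt[l] == cnt[best] && l < best))
      best = l;
    if (got == E.kgrid[ki]) out[ki++] = best + 1;
  }
  for (; ki < nk; ++ki) out[ki] = best + 1; // k capped at the fold size
}

// Concordance index from an L x L truth-by-prediction table.
static double cindex_table(const double* T, int L) {
  double comparable = 0.0, credit = 0.0;
  for (int a = 0; a < L - 1; ++a) {
    double na = 0.0;
    for (int p = 0; p < L; ++p) na += T[a * L + p];
    for (int b = a + 1; b < L; ++b) {
      double nb = 0.0;
      for (int p = 0; p < L; ++p) nb += T[b * L + p];
      comparable += na * nb;
      for (int p = 0; p < L; ++p) {
        if (T[a * L + p] == 0.0) continue;
        double conc = 0.0;
        for (int q = p + 1; q < L; ++q) conc += T[b * L + q];
        credit += T[a * L + p] * (conc + 0.5 * T[b * L + p]);
      }
    }
  }
  if (comparable == 0.0) return NA_REAL;
  return credit / comparable;
}

static bool has_two_labels(const std::vector<int>& rows, const int* lab) {
  for (size_t i = 1; i < rows.size(); ++i)
    if (lab[rows[i]] != lab[rows[0]]) return true;
  return false;
}

// One full nested leave-subject-out run; fills the per-fold selections and
// c-indices, returns the aggregate mean over valid folds.
static double nested_run(const EngineData& E, const int* lab,
                         std::vector<int>* sel_subset,
                         std::vector<int>* sel_k,
                         std::vector<double>* fold_ci) {
  const int ns = (int)E.subsets.size();
  const int nk = (int)E.kgrid.size();
  std::vector<double> score(ns * nk);
  std::vector<int> preds(nk);
  std::vector<double> tab(E.L * E.L);
  std::vector<std::vector<int> > pred_buf(ns * nk);
  double agg = 0.0;
  int n_valid_folds = 0;

  for (int A = 0; A < E.S; ++A) {
    std::fill(score.begin(), score.end(), 0.0);
    int n_inner = 0;
    for (int B = 0; B < E.S; ++B) {
      if (B == A) continue;
      const std::vector<int>& rows = E.rows_by_subject[B];
      if (rows.empty() || !has_two_labels(rows, lab)) continue;
      ++n_inner;
      for (int si = 0; si < ns; ++si) {
        for (int m = 0; m < nk; ++m) {
          pred_buf[si * nk + m].resize(rows.size());
        }
        for (size_t ri = 0; ri < rows.size(); ++ri) {
          predict_row(E, E.subsets[si], lab, rows[ri], A, -1, preds.data());
          for (int m = 0; m < nk; ++m)
            pred_buf[si * nk + m][ri] = preds[m];
        }
        for (int m = 0; m < nk; ++m) {
          std::fill(tab.begin(), tab.end(), 0.0);
          const std::vector<int>& pv = pred_buf[si * nk + m];
          for (size_t ri = 0; ri < rows.size(); ++ri)
            tab[(lab[rows[ri]] - 1) * E.L + (pv[ri] - 1)] += 1.0;
          const double ci = cindex_table(tab.data(), E.L);
          score[si * nk + m] += ci;
        }
      }
    }
    // Argmax of the mean inner c-index; iteration order (subsets sorted by
    // size then lexicographically, k ascending) realizes the tie-breaks.
    int best_si = 0, best_m = 0;
    double best_score = -1.0;
    if (n_inner > 0) {
      for (int si = 0; si < ns; ++si)
        for (int m = 0; m < nk; ++m)
          if (score[si * nk + m] > best_score) {
            best_score = score[si * nk + m];
            best_si = si; best_m = m;
          }
    }
    if (sel_subset) (*sel_subset)[A] = best_si + 1;
    if (sel_k) (*sel_k)[A] = E.kgrid[best_m];

    const std::vector<int>& rows = E.rows_by_subject[A];
    double ci = NA_REAL;
    if (!rows.empty() && has_two_labels(rows, lab)) {
      std::fill(tab.begin(), tab.end(), 0.0);
      // refit on all inner data = every subject but A; the stored lists
      // already exclude A's own rows, so no extra exclusion applies.
      std::vector<int> pk(nk);
      for (size_t ri = 0; ri < rows.size(); ++ri) {
        predict_row(E, E.subsets[best_si], lab, rows[ri], -1, -1, pk.data());
        tab[(lab[rows[ri]] - 1) * E.L + (pk[best_m] - 1)] += 1.0;
      }
      ci = cindex_table(tab.data(), E.L);
    }
    if (fold_ci) (*fold_ci)[A] = ci;
    if (!ISNA(ci)) { agg += ci; ++n_valid_folds; }
  }
  return n_valid_folds > 0 ? agg / n_valid_folds : NA_REAL;
}

// [[Rcpp::export]]
List knn_nested_cv(List neigh, List Xs, IntegerVector subject,
                   IntegerVector labels, IntegerVector kgrid, int n_labels) {
  EngineData E = make_engine(neigh, Xs, subject, kgrid, n_labels);
  std::vector<int> lab(labels.begin(), labels.end());
  std::vector<int> sel_subset(E.S), sel_k(E.S);
  std::vector<double> fold_ci(E.S);
  const double agg = nested_run(E, lab.data(), &sel_subset, &sel_k, &fold_ci);
  return List::create(_["sel_subset"] = wrap(sel_subset),
                      _["sel_k"] = wrap(sel_k),
                      _["fold_cindex"] = wrap(fold_ci),
                      _["meta_c_index"] = agg);
}

// [[Rcpp::export]]
NumericVector knn_perm_null(List neigh, List Xs, IntegerVector subject,
                            IntegerMatrix label_matrix, IntegerVector kgrid,
                            int n_labels) {
  EngineData E = make_engine(neigh, Xs, subject, kgrid, n_labels);
  const int B = label_matrix.ncol();
  NumericVector out(B);
  std::vector<int> lab(E.n);
  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < E.n; ++i) lab[i] = label_matrix(i, b);
    out[b] = nested_run(E, lab.data(), NULL, NULL, NULL);
    if (b % 10 == 9) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Plain leave-subject-out evaluation of one fixed (subset, k) model.
// [[Rcpp::export]]
NumericVector knn_final_loso(IntegerMatrix neigh, NumericMatrix X,
                             IntegerVector subject, IntegerVector labels,
                             int k, int n_labels) {
  List nl = List::create(neigh);
  List xl = List::create(X);
  EngineData E = make_engine(nl, xl, subject, IntegerVector::create(k),
                             n_labels);
  std::vector<int> lab(labels.begin(), labels.end());
  NumericVector out(E.S);
  std::vector<double> tab(E.L * E.L);
  int pk;
  for (int A = 0; A < E.S; ++A) {
    const std::vector<int>& rows = E.rows_by_subject[A];
    if (rows.empty() || !has_two_labels(rows, lab.data())) {
      out[A] = NA_REAL;
      continue;
    }
    std::fill(tab.begin(), tab.end(), 0.0);
    for (size_t ri = 0; ri < rows.size(); ++ri) {
      predict_row(E, E.subsets[0], lab.data(), rows[ri], -1, -1, &pk);
      tab[(lab[rows[ri]] - 1) * E.L + (pk - 1)] += 1.0;
    }
    out[A] = cindex_table(tab.data(), E.L);
  }
  return out;
}
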