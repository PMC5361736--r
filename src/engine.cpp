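#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// K nearest training neighbours for every individual under a
// cross-validation plan: neighbours of i are drawn from folds != fold[i].
// Distance ties break towards the smaller individual index; columns of the
// result are ordered by increasing (distance, index), so column 1 is the
// single nearest neighbour.  Indices are 1-based.
// [[Rcpp::export]]
IntegerMatrix cv_knn_neighbors(NumericMatrix d2, IntegerVector fold, int K) {
  int n = d2.nrow();
  if (fold.size() != n) stop("fold length must match distance matrix");
  IntegerMatrix nb(n, K);
  // bounded max-heap of (distance, index) pairs per individual: O(n log K)
  // without per-row allocation
  std::vector<std::pair<double, int> > heap;
  heap.reserve(K + 1);
  for (int i = 0; i < n; ++i) {
    heap.clear();
    const double *col = &d2(0, i);
    int fi = fold[i], seen = 0;
    for (int j = 0; j < n; ++j) {
      if (fold[j] == fi) continue;
      std::pair<double, int> cand(col[j], j);
      ++seen;
      if ((int)heap.size() < K) {
        heap.push_back(cand);
        std::push_heap(heap.begin(), heap.end());
      } else if (cand < heap.front()) {
        std::pop_heap(heap.begin(), heap.end());
        heap.back() = cand;
        std::push_heap(heap.begin(), heap.end());
      }
    }
    if (seen < K) stop("K exceeds training-set size");
    std::sort_heap(heap.begin(), heap.end());
    for (int k = 0; k < K; ++k) nb(i, k) = heap[k].second + 1;
  }
  return nb;
}

// Train/test variant: neighbours of each test individual among an explicit
// training index set (1-based in and out).
// [[Rcpp::export]]
IntegerMatrix tt_knn_neighbors(NumericMatrix d2, IntegerVector train,
                               IntegerVector test, int K) {
  int nte = test.size(), ntr = train.size();
  if (K > ntr) stop("K exceeds training-set size");
  IntegerMatrix nb(nte, K);
  std::vector<std::pair<double, int> > cand(ntr);
  for (int t = 0; t < nte; ++t) {
    int i = test[t] - 1;
    for (int j = 0; j < ntr; ++j) {
      cand[j] = std::make_pair(d2(train[j] - 1, i), train[j] - 1);
    }
    std::partial_sort(cand.begin(), cand.begin() + K, cand.end());
    for (int k = 0; k < K; ++k) nb(t, k) = cand[k].second + 1;
  }
  return nb;
}

static inline double fold_mean_ba(const std::vector<int> &tp,
                                  const std::vector<int> &fn,
                                  const std::vector<int> &tn,
                                  const std::vector<int> &fp, int nfold) {
  double s = 0.0;
  for (int f = 0; f < nfold; ++f) {
    double sens = (tp[f] + fn[f] > 0) ? (double)tp[f] / (tp[f] + fn[f]) : 0.5;
    double spec = (tn[f] + fp[f] > 0) ? (double)tn[f] / (tn[f] + fp[f]) : 0.5;
    s += 0.5 * (sens + spec);
  }
  return s / nfold;
}

// Cross-validated balanced accuracy of the KNN vote for each phenotype
// column of y (n x P, entries 0/1).  nb is the neighbour matrix from
// cv_knn_neighbors.  tie_rule: 0 = nearest neighbour breaks, 1 = case
// wins, 2 = control wins.  Degenerate folds (one class absent among test
// individuals) use rate 0.5 for the missing class.
// [[Rcpp::export]]
NumericVector cv_knn_ba(IntegerMatrix nb, IntegerMatrix y, IntegerVector fold,
                        int nfold, int tie_rule) {
  int n = nb.nrow(), K = nb.ncol(), P = y.ncol();
  if (y.nrow() != n || fold.size() != n) stop("dimension mismatch");
  NumericVector out(P);
  std::vector<int> tp(nfold), fn(nfold), tn(nfold), fp(nfold);
  // transpose the (0-based) neighbour lists for contiguous access
  std::vector<int> tnb((size_t)n * K);
  for (int k = 0; k < K; ++k) {
    for (int i = 0; i < n; ++i) tnb[(size_t)i * K + k] = nb(i, k) - 1;
  }
  for (int p = 0; p < P; ++p) {
    std::fill(tp.begin(), tp.end(), 0);
    std::fill(fn.begin(), fn.end(), 0);
    std::fill(tn.begin(), tn.end(), 0);
    std::fill(fp.begin(), fp.end(), 0);
    const int *yp = &y(0, p);
    for (int i = 0; i < n; ++i) {
      const int *nbr = &tnb[(size_t)i * K];
      int votes = 0;
      for (int k = 0; k < K; ++k) votes += yp[nbr[k]];
      int pred;
      if (2 * votes > K) pred = 1;
      else if (2 * votes < K) pred = 0;
      else if (tie_rule == 1) pred = 1;
      else if (tie_rule == 2) pred = 0;
      else pred = yp[nbr[0]];
      int f = fold[i] - 1;
      if (yp[i] == 1) { if (pred == 1) ++tp[f]; else ++fn[f]; }
      else            { if (pred == 0) ++tn[f]; else ++fp[f]; }
    }
    out[p] = fold_mean_ba(tp, fn, tn, fp, nfold);
  }
  return out;
}

// Cross-validated balanced accuracy of the classic MDR cell classifier for
// each phenotype column of y.  cell: 0-based multi-locus genotype cell per
// individual (< ncell).  A cell is labelled high-risk when its training
// case:control ratio strictly exceeds the overall training ratio
// (cross-multiplied to avoid division); equality labels low-risk.  Test
// individuals whose cell is unseen in training are unclassifiable and are
// excluded from the confusion counts.
// [[Rcpp::export]]
NumericVector cv_mdr_ba(IntegerVector cell, int ncell, IntegerMatrix y,
                        IntegerVector fold, int nfold) {
  int n = cell.size(), P = y.ncol();
  if (y.nrow() != n || fold.size() != n) stop("dimension mismatch");
  NumericVector out(P);
  std::vector<int> tot_cnt(ncell, 0);
  std::vector<int> f_cnt(nfold * ncell, 0);
  std::vector<int> n_f(nfold, 0);
  for (int i = 0; i < n; ++i) {
    int f = fold[i] - 1, c = cell[i];
    if (c < 0 || c >= ncell) stop("cell index out of range");
    ++tot_cnt[c];
    ++f_cnt[f * ncell + c];
    ++n_f[f];
  }
  std::vector<int> tot_case(ncell), f_case(nfold * ncell), case_f(nfold);
  std::vector<int> tp(nfold), fn(nfold), tn(nfold), fp(nfold);
  for (int p = 0; p < P; ++p) {
    std::fill(tot_case.begin(), tot_case.end(), 0);
    std::fill(f_case.begin(), f_case.end(), 0);
    std::fill(case_f.begin(), case_f.end(), 0);
    int C = 0;
    for (int i = 0; i < n; ++i) {
      if (y(i, p) == 1) {
        int f = fold[i] - 1, c = cell[i];
        ++tot_case[c];
        ++f_case[f * ncell + c];
        ++case_f[f];
        ++C;
      }
    }
    std::fill(tp.begin(), tp.end(), 0);
    std::fill(fn.begin(), fn.end(), 0);
    std::fill(tn.begin(), tn.end(), 0);
    std::fill(fp.begin(), fp.end(), 0);
    for (int i = 0; i < n; ++i) {
      int f = fold[i] - 1, c = cell[i];
      int tr_cnt = tot_cnt[c] - f_cnt[f * ncell + c];
      if (tr_cnt == 0) continue;  // unclassifiable
      int tr_case = tot_case[c] - f_case[f * ncell + c];
      int tr_ctrl = tr_cnt - tr_case;
      long long all_case = C - case_f[f];
      long long all_ctrl = (long long)(n - n_f[f]) - all_case;
      bool high = (long long)tr_case * all_ctrl > (long long)tr_ctrl * all_case;
      int pred = high ? 1 : 0;
      if (y(i, p) == 1) { if (pred == 1) ++tp[f]; else ++fn[f]; }
      else              { if (pred == 0) ++tn[f]; else ++fp[f]; }
    }
    out[p] = fold_mean_ba(tp, fn, tn, fp, nfold);
  }
  return out;
}
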