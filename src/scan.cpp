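#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// State index (0-based) of one sample: first marker is the most significant
// bit, matching the 1-based state numbering used throughout the package.

// Exhaustive scan over the Cartesian product of per-marker threshold grids
// for one fixed marker combination.
//
// bits[m]: N x T_m integer matrix, entry (i, t) = 1 iff sample i exceeds
// grid threshold t of marker m. is_case: 1 = case, 0 = control.
//
// For every threshold combination, samples are assigned states, each state
// takes the majority class of its occupants (ties -> control; unoccupied
// states hold no training samples so they cannot affect the training
// confusion counts), and the confusion counts are accumulated. Combinations
// meeting both cutoffs are retained; the best combination by (correct calls,
// then true negatives, then earliest in lexicographic grid order) is always
// tracked, independently of the cutoffs.
//
// Returns 1-based grid indices so the R side can map back to thresholds.
// [[Rcpp::export]]
List cpp_scan_combo(List bits, IntegerVector is_case,
                    double min_sens, double min_spec) {
  const int n = bits.size();
  const int N = is_case.size();
  std::vector<IntegerMatrix> B;
  std::vector<int> T(n);
  for (int m = 0; m < n; ++m) {
    B.push_back(as<IntegerMatrix>(bits[m]));
    if (B[m].nrow() != N) stop("bit matrix rows must match sample count");
    T[m] = B[m].ncol();
  }
  const int nStates = 1 << n;
  int nCase = 0;
  for (int i = 0; i < N; ++i) nCase += is_case[i];
  const int nCtrl = N - nCase;

  std::vector<int> idx(n, 0);
  std::vector<int> partial(N, 0);  // state over first n-1 markers, shifted
  std::vector<int> caseCnt(nStates), ctrlCnt(nStates);
  std::vector<int> keepIdx;
  std::vector<int> keepCounts;  // tp, fp, tn, fn per retained combo
  int bestCorrect = -1, bestTN = -1;
  std::vector<int> bestIdx(n, 0);
  int bestTP = 0, bestFP = 0, bestTNc = 0, bestFN = 0;

  bool done = false, partialDirty = true;
  while (!done) {
    if (partialDirty) {
      for (int i = 0; i < N; ++i) {
        int s = 0;
        for (int m = 0; m < n - 1; ++m) s = (s << 1) | B[m](i, idx[m]);
        partial[i] = s << 1;
      }
      partialDirty = false;
    }
    std::fill(caseCnt.begin(), caseCnt.end(), 0);
    std::fill(ctrlCnt.begin(), ctrlCnt.end(), 0);
    const IntegerMatrix& Bl = B[n - 1];
    const int tl = idx[n - 1];
    for (int i = 0; i < N; ++i) {
      const int s = partial[i] | Bl(i, tl);
      if (is_case[i]) ++caseCnt[s]; else ++ctrlCnt[s];
    }
    int tp = 0, tn = 0;
    for (int s = 0; s < nStates; ++s) {
      if (caseCnt[s] > ctrlCnt[s]) tp += caseCnt[s];
      else tn += ctrlCnt[s];
    }
    const int fn = nCase - tp, fp = nCtrl - tn;
    const double sens = nCase > 0 ? (double)tp / nCase : 0.0;
    const double spec = nCtrl > 0 ? (double)tn / nCtrl : 0.0;
    if (sens >= min_sens && spec >= min_spec) {
      for (int m = 0; m < n; ++m) keepIdx.push_back(idx[m] + 1);
      keepCounts.push_back(tp);
      keepCounts.push_back(fp);
      keepCounts.push_back(tn);
      keepCounts.push_back(fn);
    }
    const int correct = tp + tn;
    if (correct > bestCorrect || (correct == bestCorrect && tn > bestTN)) {
      bestCorrect = correct;
      bestTN = tn;
      for (int m = 0; m < n; ++m) bestIdx[m] = idx[m] + 1;
      bestTP = tp; bestFP = fp; bestTNc = tn; bestFN = fn;
    }
    // odometer over grid indices, last marker fastest (lexicographic order)
    int m = n - 1;
    while (m >= 0) {
      if (++idx[m] < T[m]) break;
      idx[m] = 0;
      --m;
    }
    if (m < 0) done = true;
    else if (m < n - 1) partialDirty = true;
  }

  const int nKeep = keepIdx.size() / n;
  IntegerMatrix retained(nKeep, n), counts(nKeep, 4);
  for (int r = 0; r < nKeep; ++r) {
    for (int m = 0; m < n; ++m) retained(r, m) = keepIdx[r * n + m];
    for (int c = 0; c < 4; ++c) counts(r, c) = keepCounts[r * 4 + c];
  }
  return List::create(
    _["retained"] = retained,
    _["counts"] = counts,
    _["best_idx"] = wrap(bestIdx),
    _["best_counts"] = IntegerVector::create(bestTP, bestFP, bestTNc, bestFN));
}

static int popcount_int(int x) {
  int c = 0;
  while (x) { c += x & 1; x >>= 1; }
  return c;
}

// Complete a per-state class assignment from training occupancy counts.
// Occupied states: majority class, ties -> control. Unoccupied states: the
// majority class among occupied states at minimum Hamming distance, ties
// -> control. cls[s] = 1 case, 0 control.
static void complete_rules(const std::vector<int>& caseCnt,
                           const std::vector<int>& ctrlCnt,
                           std::vector<int>& cls) {
  const int nStates = caseCnt.size();
  std::vector<int> occupied;
  for (int s = 0; s < nStates; ++s) {
    if (caseCnt[s] + ctrlCnt[s] > 0) {
      cls[s] = caseCnt[s] > ctrlCnt[s] ? 1 : 0;
      occupied.push_back(s);
    } else {
      cls[s] = -1;
    }
  }
  for (int s = 0; s < nStates; ++s) {
    if (cls[s] != -1) continue;
    if (occupied.empty()) { cls[s] = 0; continue; }
    int dmin = nStates;
    for (size_t j = 0; j < occupied.size(); ++j) {
      const int d = popcount_int(s ^ occupied[j]);
      if (d < dmin) dmin = d;
    }
    int nc = 0, nk = 0;
    for (size_t j = 0; j < occupied.size(); ++j) {
      if (popcount_int(s ^ occupied[j]) == dmin) {
        if (cls[occupied[j]] == 1) ++nc; else ++nk;
      }
    }
    cls[s] = nc > nk ? 1 : 0;
  }
}

// Cross-validate one fixed panel. state: 0-based per-sample state over ALL
// samples (states do not depend on the split). split: 1..k test-split id per
// sample. For each split, rules are learned on the training 9/10; if the
// training sensitivity and specificity meet the cutoffs the completed rules
// are applied to the held-out split and its accuracy returned, else NA.
// [[Rcpp::export]]
NumericVector cpp_panel_cv(IntegerVector state, IntegerVector is_case,
                           IntegerVector split, int k, int n,
                           double min_sens, double min_spec) {
  const int N = state.size();
  const int nStates = 1 << n;
  // total counts, then subtract each split's counts to get training counts
  std::vector<int> caseTot(nStates, 0), ctrlTot(nStates, 0);
  for (int i = 0; i < N; ++i) {
    if (is_case[i]) ++caseTot[state[i]]; else ++ctrlTot[state[i]];
  }
  NumericVector out(k, NA_REAL);
  std::vector<int> caseCnt(nStates), ctrlCnt(nStates), cls(nStates);
  for (int f = 1; f <= k; ++f) {
    std::fill(caseCnt.begin(), caseCnt.end(), 0);
    std::fill(ctrlCnt.begin(), ctrlCnt.end(), 0);
    int nTest = 0;
    for (int i = 0; i < N; ++i) {
      if (split[i] == f) {
        ++nTest;
        continue;
      }
      if (is_case[i]) ++caseCnt[state[i]]; else ++ctrlCnt[state[i]];
    }
    int trCase = 0, trCtrl = 0;
    for (int s = 0; s < nStates; ++s) { trCase += caseCnt[s]; trCtrl += ctrlCnt[s]; }
    if (trCase == 0 || trCtrl == 0 || nTest == 0) continue;  // degenerate
    int tp = 0, tn = 0;
    for (int s = 0; s < nStates; ++s) {
      if (caseCnt[s] > ctrlCnt[s]) tp += caseCnt[s];
      else tn += ctrlCnt[s];
    }
    const double sens = (double)tp / trCase, spec = (double)tn / trCtrl;
    if (sens < min_sens || spec < min_spec) continue;  // NA for this split
    complete_rules(caseCnt, ctrlCnt, cls);
    int correct = 0;
    for (int i = 0; i < N; ++i) {
      if (split[i] != f) continue;
      const int pred = cls[state[i]];
      if (pred == is_case[i]) ++correct;
    }
    out[f - 1] = (double)correct / nTest;
  }
  return out;
}
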