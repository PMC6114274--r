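#include <Rcpp.h>
using namespace Rcpp;

// Sum of shifted log-odds columns: read position p (0-based) with residue
// index a (1-based into the 20-letter alphabet; NA = ambiguity, scores 0)
// contributes lo_rev(., a) to result slots p .. p+C-1. Result slot i holds
// the ungapped placement score at offset d = i - (C - 1) (0-based).
// [[Rcpp::export(name = ".placement_scores_cpp")]]
NumericVector placement_scores_cpp(const NumericMatrix& lo_rev,
                                   const IntegerVector& idx) {
  const int C = lo_rev.nrow();
  const int R = idx.size();
  NumericVector res(R + C - 1);
  double* out = REAL(res);
  for (int p = 0; p < R; ++p) {
    const int a = idx[p];
    if (a == NA_INTEGER) continue;
    const double* col = &lo_rev(0, a - 1);
    double* r = out + p;
    for (int j = 0; j < C; ++j) r[j] += col[j];
  }
  return res;
}

// Maximal-sum contiguous subarray (Kadane); leftmost, then shortest, on
// ties. Returns (sum, start, end) with 1-based inclusive coordinates.
// [[Rcpp::export(name = ".max_subarray_cpp")]]
List max_subarray_cpp(const NumericVector& x) {
  const int n = x.size();
  double best_sum = R_NegInf, cur_sum = 0.0;
  int best_start = 1, best_end = 1, cur_start = 1;
  for (int i = 0; i < n; ++i) {
    if (cur_sum <= 0) {
      cur_sum = x[i];
      cur_start = i + 1;
    } else {
      cur_sum += x[i];
    }
    if (cur_sum > best_sum) {
      best_sum = cur_sum;
      best_start = cur_start;
      best_end = i + 1;
    }
  }
  return List::create(_["sum"] = best_sum, _["start"] = best_start,
                      _["end"] = best_end);
}

// Stationary order-3 chain sampler: first three residues from the marginal
// 3-prefix distribution (cumulative vector of length 8000), then next
// residues from the conditional rows (8000 x 20). Residues are 1-based
// indices into the 20-letter alphabet. Uses R's RNG.
// [[Rcpp::export(name = ".sample_markov_cpp")]]
List sample_markov_cpp(const NumericVector& prefix_cum,
                       const NumericMatrix& cond,
                       const IntegerVector& lengths) {
  const int n = lengths.size();
  List out(n);
  for (int s = 0; s < n; ++s) {
    const int L = lengths[s];
    if (L < 1) {
      out[s] = IntegerVector(0);
      continue;
    }
    IntegerVector res(std::max(L, 3));
    // prefix draw: binary search on the cumulative marginal
    double u = unif_rand();
    int lo = 0, hi = prefix_cum.size() - 1;
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (prefix_cum[mid] < u) lo = mid + 1; else hi = mid;
    }
    int pref = lo;  // 0-based prefix index = (i1-1) + 20(i2-1) + 400(i3-1)
    res[0] = pref % 20 + 1;
    res[1] = (pref / 20) % 20 + 1;
    res[2] = pref / 400 + 1;
    for (int t = 3; t < L; ++t) {
      const int p = (res[t - 3] - 1) + 20 * (res[t - 2] - 1) +
                    400 * (res[t - 1] - 1);
      double v = unif_rand(), acc = 0.0;
      int k = 0;
      for (; k < 19; ++k) {
        acc += cond(p, k);
        if (acc >= v) break;
      }
      res[t] = k + 1;
    }
    out[s] = (L >= 3) ? res : IntegerVector(res.begin(), res.begin() + L);
  }
  return out;
}
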