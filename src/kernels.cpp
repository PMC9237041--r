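#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// k-nearest-neighbour indices under Euclidean distance, ties broken by
// ascending row index. Returns an n x k matrix of 1-based indices.
// [[Rcpp::export]]
IntegerMatrix cpp_knn(NumericMatrix x, int k, bool include_self) {
  const int n = x.nrow(), d = x.ncol();
  if (k < 1) stop("k must be >= 1");
  if ((include_self && k > n) || (!include_self && k > n - 1))
    stop("k exceeds the number of available neighbours");
  IntegerMatrix out(n, k);
  std::vector<std::pair<double, int> > cand(n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        const double diff = x(i, c) - x(j, c);
        s += diff * diff;
      }
      cand[j] = std::make_pair(s, j);
    }
    if (!include_self) cand[i].first = R_PosInf;
    std::partial_sort(cand.begin(), cand.begin() + k, cand.end());
    for (int m = 0; m < k; ++m) out(i, m) = cand[m].second + 1;
  }
  return out;
}

// neighbourhood mean and n-1 SD of `v` for each row of a neighbour-index
// matrix (1-based indices, as from cpp_knn)
// [[Rcpp::export]]
List cpp_running_stats(IntegerMatrix nidx, NumericVector v) {
  const int n = nidx.nrow(), k = nidx.ncol();
  NumericVector mean_out(n), sd_out(n);
  // two-pass with extended precision, matching R's mean()/sd() arithmetic
  for (int i = 0; i < n; ++i) {
    long double s = 0.0;
    for (int m = 0; m < k; ++m) s += v[nidx(i, m) - 1];
    long double mu0 = s / k, corr = 0.0;
    for (int m = 0; m < k; ++m) corr += v[nidx(i, m) - 1] - mu0;
    const double mu = (double)(mu0 + corr / k);
    mean_out[i] = mu;
    if (k >= 2) {
      long double ss = 0.0;
      for (int m = 0; m < k; ++m) {
        const double dev = v[nidx(i, m) - 1] - mu;
        ss += (long double)dev * dev;
      }
      sd_out[i] = std::sqrt((double)(ss / (k - 1)));
    } else {
      sd_out[i] = NA_REAL;
    }
  }
  return List::create(_["mean"] = mean_out, _["sd"] = sd_out);
}

// running SD for many value vectors (columns of V) over fixed neighbourhoods;
// used by the permutation null of the variance-gradient test
// [[Rcpp::export]]
NumericMatrix cpp_running_sd_batch(IntegerMatrix nidx, NumericMatrix V) {
  const int n = nidx.nrow(), k = nidx.ncol(), B = V.ncol();
  if (V.nrow() != n) stop("value matrix must have one row per observation");
  if (k < 2) stop("neighbourhood size must be >= 2 for an SD");
  NumericMatrix out(n, B);
  for (int b = 0; b < B; ++b) {
    const double* vb = &V(0, b);
    for (int i = 0; i < n; ++i) {
      double s = 0.0, ss = 0.0;
      for (int m = 0; m < k; ++m) {
        const double val = vb[nidx(i, m) - 1];
        s += val;
        ss += val * val;
      }
      const double mu = s / k;
      double var = (ss - k * mu * mu) / (k - 1);
      if (var < 0) var = 0;
      out(i, b) = std::sqrt(var);
    }
  }
  return out;
}

// weighted pooled-adjacent-violators: non-decreasing weighted least-squares
// fit of y with positive weights w
// [[Rcpp::export]]
NumericVector cpp_pava(NumericVector y, NumericVector w) {
  const int n = y.size();
  if (w.size() != n) stop("y and w must have equal length");
  std::vector<double> val(n), wt(n);
  std::vector<int> len(n);
  int b = -1;
  for (int i = 0; i < n; ++i) {
    ++b;
    val[b] = y[i]; wt[b] = w[i]; len[b] = 1;
    while (b > 0 && val[b - 1] > val[b]) {
      const double tw = wt[b - 1] + wt[b];
      val[b - 1] = (wt[b - 1] * val[b - 1] + wt[b] * val[b]) / tw;
      wt[b - 1] = tw;
      len[b - 1] += len[b];
      --b;
    }
  }
  NumericVector out(n);
  int pos = 0;
  for (int i = 0; i <= b; ++i)
    for (int m = 0; m < len[i]; ++m) out[pos++] = val[i];
  return out;
}
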