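#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Counts inversions in y by iterative bottom-up stable merge sort.
// Equal elements never count as inversions.
static long long merge_count(std::vector<double>& y, std::vector<double>& buf) {
  const size_t n = y.size();
  long long cnt = 0;
  for (size_t width = 1; width < n; width *= 2) {
    for (size_t lo = 0; lo + width < n; lo += 2 * width) {
      size_t mid = lo + width;
      size_t hi = std::min(lo + 2 * width, n);
      size_t i = lo, j = mid, k = lo;
      while (i < mid && j < hi) {
        if (y[j] < y[i]) {
          buf[k++] = y[j++];
          cnt += (long long)(mid - i);
        } else {
          buf[k++] = y[i++];
        }
      }
      while (i < mid) buf[k++] = y[i++];
      while (j < hi) buf[k++] = y[j++];
      std::copy(buf.begin() + lo, buf.begin() + hi, y.begin() + lo);
    }
  }
  return cnt;
}

// Knight's O(n log n) Kendall statistics. Returns (S, n0, n1, n2, n3):
// S = concordant - discordant, n0 = n(n-1)/2, n1/n2 = tied pairs in x/y,
// n3 = pairs tied in both. tau_a = S/n0, tau_b = S/sqrt((n0-n1)(n0-n2)).
// [[Rcpp::export]]
NumericVector kendall_stats_cpp(NumericVector x, NumericVector y) {
  const int n = x.size();
  if (n != y.size()) stop("x and y must have equal length");
  std::vector<std::pair<double, double> > v(n);
  for (int i = 0; i < n; ++i) v[i] = std::make_pair(x[i], y[i]);
  std::sort(v.begin(), v.end());

  long long n1 = 0, n3 = 0;
  {
    long long run_x = 1, run_xy = 1;
    for (int i = 1; i < n; ++i) {
      if (v[i].first == v[i - 1].first) {
        ++run_x;
        if (v[i].second == v[i - 1].second) {
          ++run_xy;
        } else {
          n3 += run_xy * (run_xy - 1) / 2;
          run_xy = 1;
        }
      } else {
        n1 += run_x * (run_x - 1) / 2;
        n3 += run_xy * (run_xy - 1) / 2;
        run_x = 1;
        run_xy = 1;
      }
    }
    n1 += run_x * (run_x - 1) / 2;
    n3 += run_xy * (run_xy - 1) / 2;
  }

  std::vector<double> ys(n), buf(n);
  for (int i = 0; i < n; ++i) ys[i] = v[i].second;
  long long swaps = merge_count(ys, buf);

  long long n2 = 0;
  {
    // ys is now sorted
    long long run_y = 1;
    for (int i = 1; i < n; ++i) {
      if (ys[i] == ys[i - 1]) {
        ++run_y;
      } else {
        n2 += run_y * (run_y - 1) / 2;
        run_y = 1;
      }
    }
    n2 += run_y * (run_y - 1) / 2;
  }

  long long n0 = (long long)n * (n - 1) / 2;
  long long S = n0 - n1 - n2 + n3 - 2 * swaps;
  return NumericVector::create((double)S, (double)n0, (double)n1,
                               (double)n2, (double)n3);
}

// Builds one trials-by-voxels pattern matrix: a*zt[t]*u[v] + d*zd[t]*w[v]
// + N(0, noise_sd), with u, w drawn unit-norm from R's RNG. Draw order
// (u, then w, then noise in column-major order) is part of the
// reproducibility contract.
// [[Rcpp::export]]
NumericMatrix gen_pattern_cpp(NumericVector zt, NumericVector zd, double a,
                              double d, double noise_sd, int n_voxels) {
  const int n = zt.size();
  if (n != zd.size()) stop("zt and zd must have equal length");
  NumericVector u = rnorm(n_voxels), w = rnorm(n_voxels);
  double su = 0, sw = 0;
  for (int v = 0; v < n_voxels; ++v) { su += u[v] * u[v]; sw += w[v] * w[v]; }
  su = std::sqrt(su); sw = std::sqrt(sw);
  NumericMatrix out(n, n_voxels);
  for (int v = 0; v < n_voxels; ++v) {
    const double uv = a * u[v] / su, wv = d * w[v] / sw;
    for (int t = 0; t < n; ++t) {
      out(t, v) = zt[t] * uv + zd[t] * wv + R::rnorm(0.0, noise_sd);
    }
  }
  return out;
}

// Kendall statistics of continuous x against two *categorical* y vectors
// (integer category codes in 0..k-1, category order = value order; e.g.
// rating-derived RDM entries with few distinct values). Sorts (x, c1, c2)
// records once and replaces inversion counting with an O(n*k) category
// walk; exact for any input, efficient when k is small. Returns a 2x5
// matrix of (S, n0, n1, n2, n3).
// [[Rcpp::export]]
NumericMatrix kendall_stats_categorical_cpp(NumericVector x,
                                            IntegerVector cat1, int k1,
                                            IntegerVector cat2, int k2) {
  const int n = x.size();
  if (n != cat1.size() || n != cat2.size()) {
    stop("inputs must have equal length");
  }
  struct El { double x; int c1, c2; };
  std::vector<El> v(n);
  for (int i = 0; i < n; ++i) {
    if (cat1[i] < 0 || cat1[i] >= k1 || cat2[i] < 0 || cat2[i] >= k2) {
      stop("category code out of range");
    }
    v[i].x = x[i]; v[i].c1 = cat1[i]; v[i].c2 = cat2[i];
  }
  std::sort(v.begin(), v.end(),
            [](const El& a, const El& b) { return a.x < b.x; });

  const long long n0 = (long long)n * (n - 1) / 2;
  std::vector<long long> cnt1(k1, 0), below1(k1, 0), loc1(k1, 0);
  std::vector<long long> cnt2(k2, 0), below2(k2, 0), loc2(k2, 0);
  long long C1 = 0, D1 = 0, n3_1 = 0, C2 = 0, D2 = 0, n3_2 = 0;
  long long n1 = 0, seen = 0;

  int a = 0;
  while (a < n) {
    int b = a + 1;
    while (b < n && v[b].x == v[a].x) ++b;   // run of tied x: [a, b)
    const long long len = b - a;
    n1 += len * (len - 1) / 2;
    for (int i = a; i < b; ++i) {
      const int c1 = v[i].c1, c2 = v[i].c2;
      C1 += below1[c1]; D1 += seen - below1[c1] - cnt1[c1];
      C2 += below2[c2]; D2 += seen - below2[c2] - cnt2[c2];
      ++loc1[c1]; ++loc2[c2];
    }
    // fold the run into the running totals; count within-run joint ties
    for (int i = a; i < b; ++i) {
      const int c1 = v[i].c1, c2 = v[i].c2;
      if (loc1[c1]) {
        n3_1 += loc1[c1] * (loc1[c1] - 1) / 2;
        cnt1[c1] += loc1[c1];
        for (int cc = c1 + 1; cc < k1; ++cc) below1[cc] += loc1[c1];
        loc1[c1] = 0;
      }
      if (loc2[c2]) {
        n3_2 += loc2[c2] * (loc2[c2] - 1) / 2;
        cnt2[c2] += loc2[c2];
        for (int cc = c2 + 1; cc < k2; ++cc) below2[cc] += loc2[c2];
        loc2[c2] = 0;
      }
    }
    seen += len;
    a = b;
  }
  long long n2_1 = 0, n2_2 = 0;
  for (int c = 0; c < k1; ++c) n2_1 += cnt1[c] * (cnt1[c] - 1) / 2;
  for (int c = 0; c < k2; ++c) n2_2 += cnt2[c] * (cnt2[c] - 1) / 2;

  NumericMatrix out(2, 5);
  out(0, 0) = (double)(C1 - D1); out(0, 1) = (double)n0;
  out(0, 2) = (double)n1; out(0, 3) = (double)n2_1; out(0, 4) = (double)n3_1;
  out(1, 0) = (double)(C2 - D2); out(1, 1) = (double)n0;
  out(1, 2) = (double)n1; out(1, 3) = (double)n2_2; out(1, 4) = (double)n3_2;
  return out;
}

// Correlation-distance RDM: 1 - Pearson r between all row pairs, clamped
// to [0, 2], zero diagonal. Rows with zero variance are reported (1-based)
// instead of a result so the caller can name the degenerate trials.
// [[Rcpp::export]]
Rcpp::List one_minus_r_cpp(NumericMatrix m) {
  const int n = m.nrow(), p = m.ncol();
  std::vector<double> rows((size_t)n * p);
  std::vector<int> bad;
  for (int i = 0; i < n; ++i) {
    double mean = 0;
    for (int j = 0; j < p; ++j) mean += m(i, j);
    mean /= p;
    double ss = 0;
    double* ri = &rows[(size_t)i * p];
    for (int j = 0; j < p; ++j) {
      ri[j] = m(i, j) - mean;
      ss += ri[j] * ri[j];
    }
    if (ss == 0) { bad.push_back(i + 1); continue; }
    const double inv = 1.0 / std::sqrt(ss);
    for (int j = 0; j < p; ++j) ri[j] *= inv;
  }
  if (!bad.empty()) {
    return Rcpp::List::create(Rcpp::Named("rdm") = R_NilValue,
                              Rcpp::Named("bad") = Rcpp::wrap(bad));
  }
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    const double* ri = &rows[(size_t)i * p];
    for (int j = i + 1; j < n; ++j) {
      const double* rj = &rows[(size_t)j * p];
      double r = 0;
      for (int t = 0; t < p; ++t) r += ri[t] * rj[t];
      double d = 1.0 - r;
      if (d < 0) d = 0; else if (d > 2) d = 2;
      out(i, j) = d; out(j, i) = d;
    }
  }
  return Rcpp::List::create(Rcpp::Named("rdm") = out,
                            Rcpp::Named("bad") = IntegerVector());
}
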