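#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Knight's O(m log m) Kendall tau-a.
//
// tau_A = (C - D) / (m(m-1)/2): ALL pairs in the denominator, so pairs tied
// in either variable count as neither concordant nor discordant. With
//   n0  = m(m-1)/2
//   t_x = pairs tied in x, t_y = pairs tied in y, t_xy = tied in both
//   S   = discordant pairs (exchanges while merge-sorting y after a stable
//         sort by (x, y); ties in x are y-sorted so contribute no exchange)
// we have C - D = n0 - t_x - t_y + t_xy - 2 S.

static long long merge_count(std::vector<double>& y, std::vector<double>& buf) {
  const size_t n = y.size();
  long long swaps = 0;
  for (size_t width = 1; width < n; width *= 2) {
    for (size_t lo = 0; lo < n; lo += 2 * width) {
      size_t mid = std::min(lo + width, n);
      size_t hi = std::min(lo + 2 * width, n);
      size_t i = lo, j = mid, k = lo;
      while (i < mid && j < hi) {
        if (y[j] < y[i]) {           // strict: equal values are not exchanges
          swaps += (long long)(mid - i);
          buf[k++] = y[j++];
        } else {
          buf[k++] = y[i++];
        }
      }
      while (i < mid) buf[k++] = y[i++];
      while (j < hi) buf[k++] = y[j++];
    }
    std::copy(buf.begin(), buf.end(), y.begin());
  }
  return swaps;
}

static long long tie_pairs(const std::vector<double>& v) {
  long long t = 0, run = 1;
  for (size_t i = 1; i < v.size(); ++i) {
    if (v[i] == v[i - 1]) {
      ++run;
    } else {
      t += run * (run - 1) / 2;
      run = 1;
    }
  }
  t += run * (run - 1) / 2;
  return t;
}

// [[Rcpp::export(name = ".tau_a_cpp")]]
double tau_a_cpp(NumericVector x, NumericVector y) {
  const R_xlen_t m = x.size();
  if (y.size() != m) stop("x and y must have equal length");
  if (m < 2) stop("need at least 2 jointly valid entries");

  std::vector<size_t> idx(m);
  for (R_xlen_t i = 0; i < m; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(), [&](size_t a, size_t b) {
    if (x[a] != x[b]) return x[a] < x[b];
    return y[a] < y[b];
  });

  std::vector<double> xs(m), ys(m);
  for (R_xlen_t i = 0; i < m; ++i) {
    xs[i] = x[idx[i]];
    ys[i] = y[idx[i]];
  }

  long long t_x = tie_pairs(xs);

  long long t_xy = 0, run = 1;
  for (R_xlen_t i = 1; i < m; ++i) {
    if (xs[i] == xs[i - 1] && ys[i] == ys[i - 1]) {
      ++run;
    } else {
      t_xy += run * (run - 1) / 2;
      run = 1;
    }
  }
  t_xy += run * (run - 1) / 2;

  std::vector<double> buf(m);
  long long S = merge_count(ys, buf);  // ys now sorted
  long long t_y = tie_pairs(ys);

  const double n0 = (double)m * (m - 1) / 2.0;
  const double num = n0 - (double)t_x - (double)t_y + (double)t_xy - 2.0 * (double)S;
  return num / n0;
}
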