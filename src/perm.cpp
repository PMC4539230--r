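#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Midranks of v restricted to indices [lo, hi) of idx, written into r.
// Scratch `ord` holds a sort permutation of the slice.
static void midranks(const std::vector<double>& v, double* r, int n) {
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return v[a] < v[b]; });
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && v[ord[j + 1]] == v[ord[i]]) ++j;
    double avg = (i + j) / 2.0 + 1.0;  // mean of ranks i+1 .. j+1
    for (int k = i; k <= j; ++k) r[ord[k]] = avg;
    i = j + 1;
  }
}

// Spearman rho of (x, y); returns NA_REAL when either vector has zero
// rank variance.
static double spearman_rho(const std::vector<double>& x,
                           const std::vector<double>& y) {
  int n = (int)x.size();
  std::vector<double> rx(n), ry(n);
  midranks(x, rx.data(), n);
  midranks(y, ry.data(), n);
  double mx = 0, my = 0;
  for (int i = 0; i < n; ++i) { mx += rx[i]; my += ry[i]; }
  mx /= n; my /= n;
  double sxy = 0, sxx = 0, syy = 0;
  for (int i = 0; i < n; ++i) {
    double dx = rx[i] - mx, dy = ry[i] - my;
    sxy += dx * dy; sxx += dx * dx; syy += dy * dy;
  }
  if (sxx <= 0 || syy <= 0) return NA_REAL;
  return sxy / std::sqrt(sxx * syy);
}

// Monte-Carlo null of the Spearman correlation difference under random
// reassignment of group labels. Pairs (x_i, y_i) stay intact; the first
// n_a positions of a shuffled index vector form group A. Uses R's RNG so
// results are reproducible from set.seed(). A resample in which either
// relabeled group has zero rank variance contributes diff = 0 and is
// tallied in `degenerate`.
// [[Rcpp::export]]
List perm_corr_diff_engine(NumericVector x, NumericVector y,
                           int n_a, int n_resamples) {
  int n = x.size();
  int n_b = n - n_a;
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  NumericVector null_diffs(n_resamples);
  int degenerate = 0;
  std::vector<double> xa(n_a), ya(n_a), xb(n_b), yb(n_b);
  for (int b = 0; b < n_resamples; ++b) {
    // Fisher-Yates shuffle driven by R's RNG stream
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;  // guard against unif_rand() == 1.0
      std::swap(idx[i], idx[j]);
    }
    for (int i = 0; i < n_a; ++i) { xa[i] = x[idx[i]]; ya[i] = y[idx[i]]; }
    for (int i = 0; i < n_b; ++i) {
      xb[i] = x[idx[n_a + i]]; yb[i] = y[idx[n_a + i]];
    }
    double ra = spearman_rho(xa, ya), rb = spearman_rho(xb, yb);
    if (ISNA(ra) || ISNA(rb)) { null_diffs[b] = 0.0; ++degenerate; }
    else null_diffs[b] = ra - rb;
  }
  return List::create(_["null_diffs"] = null_diffs,
                      _["n_degenerate"] = degenerate);
}

// [[Rcpp::export]]
double spearman_rho_cpp(NumericVector x, NumericVector y) {
  std::vector<double> xv(x.begin(), x.end()), yv(y.begin(), y.end());
  return spearman_rho(xv, yv);
}
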