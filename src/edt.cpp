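#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Large finite sentinel for "no feature in reach".  Using a finite value
// keeps every parabola intersection finite (the textbook algorithm breaks
// on +Inf inputs); real squared distances never exceed nr^2 + nc^2, so any
// output >= BIG/2 means "no feature anywhere".
static const double BIG = 1e15;

// 1-D squared-distance transform (lower envelope of parabolas),
// Felzenszwalb & Huttenlocher exact algorithm.
static void dt1d(std::vector<double> &f, std::vector<double> &d, int n) {
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; q++) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      k--;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    d[q] = (double)(q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// Exact squared Euclidean distance (in cell units) from every cell to the
// nearest TRUE cell of `feature`.  A feature cell has distance 0.  If
// `feature` has no TRUE cell the result is +Inf everywhere.
// [[Rcpp::export]]
NumericMatrix edt_squared(LogicalMatrix feature) {
  int nr = feature.nrow(), nc = feature.ncol();
  NumericMatrix out(nr, nc);

  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  // column pass
  for (int j = 0; j < nc; j++) {
    for (int i = 0; i < nr; i++) f[i] = feature(i, j) ? 0.0 : BIG;
    dt1d(f, d, nr);
    for (int i = 0; i < nr; i++) out(i, j) = d[i];
  }
  // row pass
  for (int i = 0; i < nr; i++) {
    for (int j = 0; j < nc; j++) f[j] = out(i, j);
    dt1d(f, d, nc);
    for (int j = 0; j < nc; j++) out(i, j) = d[j];
  }
  for (int i = 0; i < nr * nc; i++)
    if (out[i] >= BIG / 2) out[i] = R_PosInf;
  return out;
}
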