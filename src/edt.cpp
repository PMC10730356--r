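#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact squared Euclidean distance transform on the pixel lattice
// (two-pass lower-envelope algorithm of Felzenszwalb & Huttenlocher).
// `sites` marks the zero-distance pixels (the border set). Distances are
// measured center-to-center in pixel units; squared distances are returned.
// Where no site exists anywhere, values are >= BIG and the caller maps them
// to Inf.

static const double BIG = 1e20;

static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
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
    z[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double dq = q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericMatrix edt_squared(LogicalMatrix sites) {
  int nr = sites.nrow(), nc = sites.ncol();
  int m = std::max(nr, nc);
  NumericMatrix g(nr, nc);
  std::vector<double> f(m), d(m);
  std::vector<int> v(m);
  std::vector<double> z(m + 1);

  // pass 1: within each column
  for (int j = 0; j < nc; j++) {
    for (int i = 0; i < nr; i++) f[i] = sites(i, j) ? 0.0 : BIG;
    dt1d(f, d, nr, v, z);
    for (int i = 0; i < nr; i++) g(i, j) = d[i];
  }
  // pass 2: within each row
  NumericMatrix out(nr, nc);
  for (int i = 0; i < nr; i++) {
    for (int j = 0; j < nc; j++) f[j] = g(i, j);
    dt1d(f, d, nc, v, z);
    for (int j = 0; j < nc; j++) out(i, j) = d[j];
  }
  return out;
}
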