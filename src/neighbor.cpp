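#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Pairwise cell-cell distances below a cutoff, for neighborhood analysis.
// mode 0: centroid-to-centroid distance.
// mode 1: centroid distance minus the two equivalent-circle radii (`ext`),
//         floored at 0 — a border-distance surrogate for point-mode cells.
// mode 2: exact minimum distance between the two cells' boundary pixel sets
//         (`boundaries` is a list of k_i x 2 coordinate matrices, micrometre
//         pixel centers). `ext` must bound the boundary's reach from the
//         centroid so candidate pruning stays exact.
// Returns an edge list (i, j, dist) with 1-based indices, i < j, dist <= maxdist.

// [[Rcpp::export]]
DataFrame neighbor_pairs_cpp(NumericMatrix coords, double maxdist, int mode,
                             NumericVector ext, List boundaries) {
  int n = coords.nrow();
  std::vector<int> ii, jj;
  std::vector<double> dd;
  bool use_ext = (mode >= 1);

  // cache boundary matrices to avoid repeated List extraction
  std::vector<NumericMatrix> bnd;
  if (mode == 2) {
    bnd.reserve(n);
    for (int i = 0; i < n; i++) bnd.push_back(as<NumericMatrix>(boundaries[i]));
  }

  for (int a = 0; a < n; a++) {
    double xa = coords(a, 0), ya = coords(a, 1);
    double ea = use_ext ? ext[a] : 0.0;
    for (int b = a + 1; b < n; b++) {
      double dx = coords(b, 0) - xa;
      if (std::fabs(dx) > maxdist + ea + (use_ext ? ext[b] : 0.0)) continue;
      double dy = coords(b, 1) - ya;
      double eb = use_ext ? ext[b] : 0.0;
      double reach = maxdist + ea + eb;
      if (std::fabs(dy) > reach) continue;
      double dc = std::sqrt(dx * dx + dy * dy);
      if (dc > reach) continue;
      double dist;
      if (mode == 0) {
        dist = dc;
      } else if (mode == 1) {
        dist = dc - ea - eb;
        if (dist < 0.0) dist = 0.0;
      } else {
        const NumericMatrix& A = bnd[a];
        const NumericMatrix& B = bnd[b];
        double best = R_PosInf;
        for (int u = 0; u < A.nrow(); u++) {
          for (int v = 0; v < B.nrow(); v++) {
            double ddx = A(u, 0) - B(v, 0);
            double ddy = A(u, 1) - B(v, 1);
            double d2 = ddx * ddx + ddy * ddy;
            if (d2 < best) best = d2;
          }
        }
        dist = std::sqrt(best);
      }
      if (dist <= maxdist) {
        ii.push_back(a + 1);
        jj.push_back(b + 1);
        dd.push_back(dist);
      }
    }
  }
  return DataFrame::create(_["i"] = ii, _["j"] = jj, _["dist"] = dd);
}
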