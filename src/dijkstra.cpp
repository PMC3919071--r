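// Dijkstra propagation of correlation-deformed distances on the
// 26-connected voxel grid. Edge weights are computed on the fly from the
// 13-map correlation storage: the correlation of voxel v with its neighbor
// at offset o is stored at v when o is a canonical half offset, and at v+o
// under -o otherwise. Correlations are attenuated by the proportional
// tissue rule using the lower tissue probability of the two endpoints,
// then turned into step distances
//   D = sqrt((1-alpha) Dreal^2 + alpha 2 sigma^2 log(1/rho)).
// Expansion stops beyond the cutoff; unreached voxels are +Inf.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector dijkstra_propagate_cpp(NumericVector rho13,
                                     NumericVector tissue,
                                     IntegerVector dim,
                                     NumericVector voxmm,
                                     IntegerMatrix offsets,
                                     IntegerVector half_index,
                                     LogicalVector is_half,
                                     IntegerVector seed0,
                                     double sigma, double alpha,
                                     double cutoff, double tissue_thr) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  const int noff = offsets.nrow();

  std::vector<double> dreal2(noff), dlin(noff);
  for (int j = 0; j < noff; ++j) {
    double dx = offsets(j, 0) * voxmm[0];
    double dy = offsets(j, 1) * voxmm[1];
    double dz = offsets(j, 2) * voxmm[2];
    dreal2[j] = dx * dx + dy * dy + dz * dz;
    dlin[j] = offsets(j, 0) + (R_xlen_t)offsets(j, 1) * nx +
              (R_xlen_t)offsets(j, 2) * nx * ny;
  }

  NumericVector dist(nvox, R_PosInf);
  const R_xlen_t s = seed0[0] + (R_xlen_t)seed0[1] * nx +
                     (R_xlen_t)seed0[2] * nx * ny;
  dist[s] = 0.0;

  typedef std::pair<double, R_xlen_t> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  pq.push(Node(0.0, s));

  const double two_s2 = 2.0 * sigma * sigma;
  while (!pq.empty()) {
    Node top = pq.top();
    pq.pop();
    double du = top.first;
    R_xlen_t u = top.second;
    if (du > dist[u] + 1e-12) continue;  // lazy deletion
    int ux = u % nx, uy = (u / nx) % ny, uz = u / ((R_xlen_t)nx * ny);
    for (int j = 0; j < noff; ++j) {
      int vx = ux + offsets(j, 0), vy = uy + offsets(j, 1),
          vz = uz + offsets(j, 2);
      if (vx < 0 || vx >= nx || vy < 0 || vy >= ny || vz < 0 || vz >= nz)
        continue;
      R_xlen_t v = u + (R_xlen_t)dlin[j];
      double step;
      if (alpha > 0.0) {
        R_xlen_t at = is_half[j] ? u : v;
        double rho = rho13[at + nvox * (half_index[j] - 1)];
        if (ISNAN(rho)) continue;
        double pu = tissue[u], pv = tissue[v];
        double p = (ISNAN(pu) || ISNAN(pv)) ? 0.0 : std::min(pu, pv);
        if (tissue_thr > 0.0 && p < tissue_thr) rho *= p / tissue_thr;
        if (rho <= 0.0) continue;
        if (rho > 1.0 - 1e-12) rho = 1.0;
        step = std::sqrt((1.0 - alpha) * dreal2[j] +
                         alpha * two_s2 * std::log(1.0 / rho));
      } else {
        step = std::sqrt(dreal2[j]);
      }
      double nd = du + step;
      if (nd > cutoff) continue;  // strict cutoff: beyond FWHM -> excluded
      if (nd < dist[v] - 1e-12) {
        dist[v] = nd;
        pq.push(Node(nd, v));
      }
    }
  }
  return dist;
}
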