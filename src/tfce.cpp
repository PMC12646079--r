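#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Union-find with path compression; sizes tracked at roots.
static int uf_find(std::vector<int> &parent, int v) {
  while (parent[v] != v) {
    parent[v] = parent[parent[v]];
    v = parent[v];
  }
  return v;
}

// Neighbour offsets for 6/18/26 connectivity in a 3D grid.
static void neighbour_offsets(int connectivity, std::vector<std::array<int, 3>> &offs) {
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int nz = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (nz == 0) continue;
        if (connectivity == 6 && nz > 1) continue;
        if (connectivity == 18 && nz > 2) continue;
        offs.push_back({dx, dy, dz});
      }
}

// Threshold-free cluster enhancement of the non-negative part of `values`.
// Integrates extent^E * height^H over midpoint thresholds h_k = (k-0.5)*dh,
// k = 1..nsteps covering (0, peak]. Clusters grow incrementally with a
// union-find as the threshold descends, so the cost is O(V * 26 + nsteps * V).
// [[Rcpp::export]]
NumericVector tfce_positive_cpp(NumericVector values, IntegerVector dims,
                                LogicalVector mask, double H, double E,
                                int nsteps, int connectivity) {
  const int dx_ = dims[0], dy_ = dims[1], dz_ = dims[2];
  const int V = dx_ * dy_ * dz_;
  NumericVector out(V);
  double peak = 0.0;
  for (int v = 0; v < V; ++v)
    if (mask[v] && values[v] > peak) peak = values[v];
  if (peak <= 0.0) return out;
  const double dh = peak / nsteps;

  std::vector<std::array<int, 3>> offs;
  neighbour_offsets(connectivity, offs);

  // voxels with positive value inside the mask, sorted by value descending
  std::vector<int> order;
  order.reserve(V);
  for (int v = 0; v < V; ++v)
    if (mask[v] && values[v] > 0.0) order.push_back(v);
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return values[a] > values[b]; });

  std::vector<int> parent(V, -1), csize(V, 0);
  std::vector<int> active;
  active.reserve(order.size());
  std::size_t ptr = 0;

  for (int k = nsteps; k >= 1; --k) {
    const double h = (k - 0.5) * dh;
    // activate voxels whose value reaches this threshold
    while (ptr < order.size() && values[order[ptr]] >= h) {
      const int v = order[ptr++];
      parent[v] = v;
      csize[v] = 1;
      active.push_back(v);
      const int zz = v / (dx_ * dy_);
      const int rem = v - zz * dx_ * dy_;
      const int yy = rem / dx_;
      const int xx = rem - yy * dx_;
      for (const auto &o : offs) {
        const int nx = xx + o[0], ny = yy + o[1], nz2 = zz + o[2];
        if (nx < 0 || nx >= dx_ || ny < 0 || ny >= dy_ || nz2 < 0 || nz2 >= dz_)
          continue;
        const int w = nx + dx_ * (ny + dy_ * nz2);
        if (parent[w] < 0) continue; // neighbour not active yet
        const int rv = uf_find(parent, v), rw = uf_find(parent, w);
        if (rv != rw) { // union by size
          if (csize[rv] < csize[rw]) {
            parent[rv] = rw;
            csize[rw] += csize[rv];
          } else {
            parent[rw] = rv;
            csize[rv] += csize[rw];
          }
        }
      }
    }
    const double hterm = (H == 2.0 ? h * h : std::pow(h, H)) * dh;
    if (E == 0.5) {
      for (const int v : active)
        out[v] += std::sqrt((double)csize[uf_find(parent, v)]) * hterm;
    } else {
      for (const int v : active)
        out[v] += std::pow((double)csize[uf_find(parent, v)], E) * hterm;
    }
  }
  return out;
}

// Maximum of |TFCE| over both tails — the max statistic recorded per
// permutation when building the FWE null. Avoids materialising enhanced
// maps in R for every permutation.
// [[Rcpp::export]]
double tfce_max_abs_cpp(NumericVector values, IntegerVector dims,
                        LogicalVector mask, double H, double E, int nsteps,
                        int connectivity) {
  const int V = values.size();
  NumericVector pos(V), neg(V);
  for (int v = 0; v < V; ++v) {
    pos[v] = values[v] > 0 ? values[v] : 0.0;
    neg[v] = values[v] < 0 ? -values[v] : 0.0;
  }
  double best = 0.0;
  for (const NumericVector &side : {pos, neg}) {
    NumericVector enh = tfce_positive_cpp(side, dims, mask, H, E, nsteps,
                                          connectivity);
    for (int v = 0; v < V; ++v)
      if (enh[v] > best) best = enh[v];
  }
  return best;
}

// Maximal connected-component size over an edge list on `n_nodes` nodes.
// Size in edges (default) or nodes; components are induced by the edges,
// so every component has >= 2 nodes. Returns 0 for an empty edge list.
// [[Rcpp::export]]
double max_component_size_cpp(int n_nodes, IntegerVector edge_i,
                              IntegerVector edge_j, bool size_in_edges) {
  const int m = edge_i.size();
  if (m == 0) return 0.0;
  std::vector<int> parent(n_nodes + 1), nsize(n_nodes + 1, 1);
  for (int v = 0; v <= n_nodes; ++v) parent[v] = v;
  std::vector<int> ecount(n_nodes + 1, 0);
  for (int e = 0; e < m; ++e) {
    int ri = uf_find(parent, edge_i[e]);
    int rj = uf_find(parent, edge_j[e]);
    if (ri != rj) {
      if (nsize[ri] < nsize[rj]) std::swap(ri, rj);
      parent[rj] = ri;
      nsize[ri] += nsize[rj];
      ecount[ri] += ecount[rj];
    }
    ecount[ri] += 1;
  }
  double best = 0.0;
  for (int e = 0; e < m; ++e) {
    const int r = uf_find(parent, edge_i[e]);
    const double sz = size_in_edges ? (double)ecount[r] : (double)nsize[r];
    if (sz > best) best = sz;
  }
  return best;
}
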