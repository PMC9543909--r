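#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Multi-source shortest paths restricted to an open voxel phase.
// 26-connected grid graph; step costs voxel_size * {1, sqrt(2), sqrt(3)}.
// `open` is a linearised (column-major, R array layout) mask of traversable
// voxels, `sources` are 1-based linear indices. Returns distances with Inf for
// voxels that are closed or unreachable.
// [[Rcpp::export]]
NumericVector geodesic_distance_cpp(LogicalVector open, IntegerVector dims,
                                    IntegerVector sources, double voxel_size) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  NumericVector dist(n, R_PosInf);
  typedef std::pair<double, R_xlen_t> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;

  for (int i = 0; i < sources.size(); i++) {
    R_xlen_t s = (R_xlen_t)sources[i] - 1;
    if (s < 0 || s >= n || !open[s]) continue;
    if (dist[s] > 0.0) {
      dist[s] = 0.0;
      pq.push(Node(0.0, s));
    }
  }

  while (!pq.empty()) {
    Node top = pq.top(); pq.pop();
    double d = top.first;
    R_xlen_t u = top.second;
    if (d > dist[u]) continue;
    int i1 = (int)(u % d1);
    R_xlen_t r = u / d1;
    int i2 = (int)(r % d2);
    int i3 = (int)(r / d2);
    for (int a = -1; a <= 1; a++) {
      for (int b = -1; b <= 1; b++) {
        for (int c = -1; c <= 1; c++) {
          if (a == 0 && b == 0 && c == 0) continue;
          int j1 = i1 + a, j2 = i2 + b, j3 = i3 + c;
          if (j1 < 0 || j1 >= d1 || j2 < 0 || j2 >= d2 || j3 < 0 || j3 >= d3)
            continue;
          R_xlen_t v = j1 + (R_xlen_t)d1 * (j2 + (R_xlen_t)d2 * j3);
          if (!open[v]) continue;
          double w = voxel_size * std::sqrt((double)(a * a + b * b + c * c));
          if (d + w < dist[v]) {
            dist[v] = d + w;
            pq.push(Node(dist[v], v));
          }
        }
      }
    }
  }
  return dist;
}

static const double DT_INF = 1e30;

// 1D squared-distance lower envelope (Felzenszwalb & Huttenlocher).
static void dt1d(std::vector<double>& f, std::vector<double>& d, int n,
                 std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
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
    z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact Euclidean distance transform from a feature voxel set, isotropic
// spacing, full grid (obstacles ignored). Returns distances in the units of
// voxel_size; Inf when the feature set is empty.
// [[Rcpp::export]]
NumericVector euclidean_distance_cpp(LogicalVector feature, IntegerVector dims,
                                     double voxel_size) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; i++) g[i] = feature[i] ? 0.0 : DT_INF;

  int nmax = std::max(d1, std::max(d2, d3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along axis 1 (fastest-varying)
  for (int i3 = 0; i3 < d3; i3++) {
    for (int i2 = 0; i2 < d2; i2++) {
      R_xlen_t base = (R_xlen_t)d1 * (i2 + (R_xlen_t)d2 * i3);
      for (int q = 0; q < d1; q++) f[q] = g[base + q];
      dt1d(f, d, d1, v, z);
      for (int q = 0; q < d1; q++) g[base + q] = d[q];
    }
  }
  // axis 2
  for (int i3 = 0; i3 < d3; i3++) {
    for (int i1 = 0; i1 < d1; i1++) {
      R_xlen_t base = i1 + (R_xlen_t)d1 * d2 * (R_xlen_t)i3;
      for (int q = 0; q < d2; q++) f[q] = g[base + (R_xlen_t)d1 * q];
      dt1d(f, d, d2, v, z);
      for (int q = 0; q < d2; q++) g[base + (R_xlen_t)d1 * q] = d[q];
    }
  }
  // axis 3
  for (int i2 = 0; i2 < d2; i2++) {
    for (int i1 = 0; i1 < d1; i1++) {
      R_xlen_t base = i1 + (R_xlen_t)d1 * i2;
      R_xlen_t stride = (R_xlen_t)d1 * d2;
      for (int q = 0; q < d3; q++) f[q] = g[base + stride * q];
      dt1d(f, d, d3, v, z);
      for (int q = 0; q < d3; q++) g[base + stride * q] = d[q];
    }
  }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) {
    out[i] = (g[i] >= DT_INF / 2.0) ? R_PosInf : voxel_size * std::sqrt(g[i]);
  }
  return out;
}

// 8-connected component labelling of a 2D mask (column-major).
// [[Rcpp::export]]
IntegerVector label_components_2d_cpp(LogicalVector mask, int nrow, int ncol) {
  R_xlen_t n = (R_xlen_t)nrow * ncol;
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t i = 0; i < n; i++) {
    if (!mask[i] || lab[i] != 0) continue;
    next++;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t u = stack.back();
      stack.pop_back();
      int r = (int)(u % nrow), c = (int)(u / nrow);
      for (int dr = -1; dr <= 1; dr++) {
        for (int dc = -1; dc <= 1; dc++) {
          if (dr == 0 && dc == 0) continue;
          int rr = r + dr, cc = c + dc;
          if (rr < 0 || rr >= nrow || cc < 0 || cc >= ncol) continue;
          R_xlen_t vv = rr + (R_xlen_t)nrow * cc;
          if (mask[vv] && lab[vv] == 0) {
            lab[vv] = next;
            stack.push_back(vv);
          }
        }
      }
    }
  }
  return lab;
}
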