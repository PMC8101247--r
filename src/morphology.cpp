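// Low-level raster morphology primitives shared by the segmentation and
// quantification code: connected-component labelling, exact Euclidean
// distance transform (Felzenszwalb & Huttenlocher lower-envelope algorithm)
// and marker-driven watershed flooding.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double DT_INF = 1e20;

// 1-D squared distance transform (lower envelope of parabolas).
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
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
    d[q] = (double)(q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// Euclidean distance (in pixels) from every pixel to the nearest TRUE pixel.
// Pixels inside the mask get 0; an all-FALSE mask yields Inf everywhere.
// [[Rcpp::export]]
NumericMatrix cpp_edt(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  NumericMatrix out(nr, nc);
  std::vector<double> g(static_cast<size_t>(nr) * nc);
  for (int j = 0; j < nc; j++)
    for (int i = 0; i < nr; i++)
      g[(size_t)j * nr + i] = mask(i, j) ? 0.0 : DT_INF;

  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  // transform along columns
  for (int j = 0; j < nc; j++) {
    for (int i = 0; i < nr; i++) f[i] = g[(size_t)j * nr + i];
    dt1d(f, d, nr);
    for (int i = 0; i < nr; i++) g[(size_t)j * nr + i] = d[i];
  }
  // transform along rows
  for (int i = 0; i < nr; i++) {
    for (int j = 0; j < nc; j++) f[j] = g[(size_t)j * nr + i];
    dt1d(f, d, nc);
    for (int j = 0; j < nc; j++) g[(size_t)j * nr + i] = d[j];
  }
  for (int j = 0; j < nc; j++)
    for (int i = 0; i < nr; i++) {
      double v = g[(size_t)j * nr + i];
      out(i, j) = (v >= DT_INF / 2) ? R_PosInf : std::sqrt(v);
    }
  return out;
}

// Connected-component labelling; connectivity 4 or 8. Labels are 1..k in
// scan order (column-major), background 0.
// [[Rcpp::export]]
IntegerMatrix cpp_label(LogicalMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  const int dx8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dy8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int nnb = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; j++) {
    for (int i = 0; i < nr; i++) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      next++;
      lab(i, j) = next;
      stack.clear();
      stack.push_back(j * nr + i);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int ci = idx % nr, cj = idx / nr;
        for (int t = 0; t < nnb; t++) {
          int ni = ci + dy8[t], nj = cj + dx8[t];
          if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
          if (mask(ni, nj) && lab(ni, nj) == 0) {
            lab(ni, nj) = next;
            stack.push_back(nj * nr + ni);
          }
        }
      }
    }
  }
  lab.attr("n") = next;
  return lab;
}

struct WsNode {
  double elev;
  long order;
  int idx;
  int label;
};
struct WsCmp {
  bool operator()(const WsNode& a, const WsNode& b) const {
    if (a.elev != b.elev) return a.elev > b.elev;  // min-heap on elevation
    return a.order > b.order;                      // FIFO tie-break
  }
};

// Marker-based watershed: flood `mask` from labelled markers in order of
// increasing elevation. Returns a label matrix covering all of `mask`.
// [[Rcpp::export]]
IntegerMatrix cpp_watershed(NumericMatrix elev, IntegerMatrix markers,
                            LogicalMatrix mask) {
  int nr = elev.nrow(), nc = elev.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  long order = 0;
  for (int j = 0; j < nc; j++)
    for (int i = 0; i < nr; i++)
      if (mask(i, j) && markers(i, j) > 0) {
        lab(i, j) = markers(i, j);
        pq.push(WsNode{elev(i, j), order++, j * nr + i, markers(i, j)});
      }
  const int dx[4] = {-1, 1, 0, 0};
  const int dy[4] = {0, 0, -1, 1};
  while (!pq.empty()) {
    WsNode nd = pq.top();
    pq.pop();
    int ci = nd.idx % nr, cj = nd.idx / nr;
    for (int t = 0; t < 4; t++) {
      int ni = ci + dy[t], nj = cj + dx[t];
      if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
      if (mask(ni, nj) && lab(ni, nj) == 0) {
        lab(ni, nj) = nd.label;
        pq.push(WsNode{elev(ni, nj), order++, nj * nr + ni, nd.label});
      }
    }
  }
  return lab;
}
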