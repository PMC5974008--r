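#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
#include <algorithm>

using namespace Rcpp;

// First-order fast marching on a triangle mesh (eikonal |grad d| = 1).
// Update at vertex C inside triangle (C, A, B) assumes a locally planar
// wavefront d(x) = t + n.x with |n| = 1 constrained by d(A), d(B); the
// larger quadratic root is taken and accepted only when the characteristic
// enters through the wedge at C (upwind condition), otherwise the update
// falls back to the Dijkstra-style edge relaxations. The fallback also
// guarantees fast-marching distances never exceed edge-graph Dijkstra.
static double triangle_update(const double *pC, const double *pA, const double *pB,
                              double dA, double dB) {
  double eA[3], eB[3];
  for (int k = 0; k < 3; ++k) {
    eA[k] = pA[k] - pC[k];
    eB[k] = pB[k] - pC[k];
  }
  double aa = eA[0] * eA[0] + eA[1] * eA[1] + eA[2] * eA[2];
  double bb = eB[0] * eB[0] + eB[1] * eB[1] + eB[2] * eB[2];
  double ab = eA[0] * eB[0] + eA[1] * eB[1] + eA[2] * eB[2];
  double la = std::sqrt(aa), lb = std::sqrt(bb);
  double edge = std::min(dA + la, dB + lb);
  if (!std::isfinite(dA) || !std::isfinite(dB)) return edge;

  // Q = (E^T E)^{-1} with E = [eA eB]
  double det = aa * bb - ab * ab;
  if (det <= 1e-14 * aa * bb) return edge;  // degenerate triangle
  double q11 = bb / det, q22 = aa / det, q12 = -ab / det;

  // quadratic  t^2 (1'Q1) - 2 t (1'Qd) + d'Qd - 1 = 0
  double sQ1 = q11 + 2.0 * q12 + q22;
  double sQd = (q11 + q12) * dA + (q12 + q22) * dB;
  double dQd = q11 * dA * dA + 2.0 * q12 * dA * dB + q22 * dB * dB;
  double disc = sQd * sQd - sQ1 * (dQd - 1.0);
  if (disc < 0.0) return edge;
  double t = (sQd + std::sqrt(disc)) / sQ1;
  if (t < std::max(dA, dB)) return edge;

  // upwind: gamma = -Q (d - t 1) must be componentwise >= 0
  double g1 = -(q11 * (dA - t) + q12 * (dB - t));
  double g2 = -(q12 * (dA - t) + q22 * (dB - t));
  if (g1 < 0.0 || g2 < 0.0) return edge;
  return std::min(t, edge);
}

// [[Rcpp::export]]
NumericVector fmm_geodesic_cpp(NumericMatrix V, IntegerMatrix F, IntegerVector sources) {
  const int nv = V.nrow(), nf = F.nrow();
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> dist(nv, INF);
  std::vector<char> accepted(nv, 0);

  // vertex -> incident triangles
  std::vector<std::vector<int> > vtri(nv);
  for (int f = 0; f < nf; ++f)
    for (int k = 0; k < 3; ++k) vtri[F(f, k)].push_back(f);

  std::vector<double> vx(nv), vy(nv), vz(nv);
  for (int i = 0; i < nv; ++i) { vx[i] = V(i, 0); vy[i] = V(i, 1); vz[i] = V(i, 2); }

  typedef std::pair<double, int> DI;
  std::priority_queue<DI, std::vector<DI>, std::greater<DI> > heap;
  for (int i = 0; i < sources.size(); ++i) {
    int s = sources[i];
    dist[s] = 0.0;
    heap.push(DI(0.0, s));
  }

  while (!heap.empty()) {
    DI top = heap.top(); heap.pop();
    int c = top.second;
    if (accepted[c]) continue;
    accepted[c] = 1;
    // relax every non-accepted vertex of every triangle incident to c
    for (size_t ti = 0; ti < vtri[c].size(); ++ti) {
      int f = vtri[c][ti];
      int tri[3] = { F(f, 0), F(f, 1), F(f, 2) };
      for (int k = 0; k < 3; ++k) {
        int v = tri[k];
        if (accepted[v]) continue;
        int a = tri[(k + 1) % 3], b = tri[(k + 2) % 3];
        double dA = accepted[a] ? dist[a] : INF;
        double dB = accepted[b] ? dist[b] : INF;
        if (!std::isfinite(dA) && !std::isfinite(dB)) continue;
        double pC[3] = { vx[v], vy[v], vz[v] };
        double pA[3] = { vx[a], vy[a], vz[a] };
        double pB[3] = { vx[b], vy[b], vz[b] };
        double t = triangle_update(pC, pA, pB, dA, dB);
        if (t < dist[v]) {
          dist[v] = t;
          heap.push(DI(t, v));
        }
      }
    }
  }

  NumericVector out(nv);
  for (int i = 0; i < nv; ++i) out[i] = dist[i];
  return out;
}

// [[Rcpp::export]]
IntegerVector nn_index_cpp(NumericMatrix query, NumericMatrix ref) {
  const int nq = query.nrow(), nr = ref.nrow();
  IntegerVector idx(nq);
  for (int i = 0; i < nq; ++i) {
    double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    double best = std::numeric_limits<double>::infinity();
    int bi = 0;
    for (int j = 0; j < nr; ++j) {
      double dx = ref(j, 0) - qx, dy = ref(j, 1) - qy, dz = ref(j, 2) - qz;
      double d = dx * dx + dy * dy + dz * dz;
      if (d < best) { best = d; bi = j; }
    }
    idx[i] = bi + 1;  // 1-based, ties resolved to the lowest index
  }
  return idx;
}

// [[Rcpp::export]]
IntegerMatrix knn_index_cpp(NumericMatrix query, NumericMatrix ref, int k) {
  const int nq = query.nrow(), nr = ref.nrow();
  if (k > nr) k = nr;
  IntegerMatrix idx(nq, k);
  std::vector<std::pair<double, int> > d(nr);
  for (int i = 0; i < nq; ++i) {
    double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    for (int j = 0; j < nr; ++j) {
      double dx = ref(j, 0) - qx, dy = ref(j, 1) - qy, dz = ref(j, 2) - qz;
      d[j] = std::make_pair(dx * dx + dy * dy + dz * dz, j);
    }
    std::partial_sort(d.begin(), d.begin() + k, d.end());
    for (int m = 0; m < k; ++m) idx(i, m) = d[m].second + 1;
  }
  return idx;
}
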