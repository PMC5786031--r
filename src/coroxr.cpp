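#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Separable 2D convolution with reflective padding.  k is applied along rows
// (kx) and columns (ky); both kernels must have odd length.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cx_conv_sep(NumericMatrix img, NumericVector kx, NumericVector ky) {
  const int nr = img.nrow(), nc = img.ncol();
  const int hx = kx.size() / 2, hy = ky.size() / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  // along columns (vertical direction, index i) with kernel ky
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double s = 0.0;
      for (int t = -hy; t <= hy; ++t) {
        int ii = i + t;
        if (ii < 0) ii = -ii;                 // reflect
        if (ii >= nr) ii = 2 * nr - 2 - ii;
        s += img(ii, j) * ky[t + hy];
      }
      tmp(i, j) = s;
    }
  }
  // along rows (horizontal direction, index j) with kernel kx
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double s = 0.0;
      for (int t = -hx; t <= hx; ++t) {
        int jj = j + t;
        if (jj < 0) jj = -jj;
        if (jj >= nc) jj = 2 * nc - 2 - jj;
        s += tmp(i, jj) * kx[t + hx];
      }
      out(i, j) = s;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// First-order fast marching solution of |grad T| = 1 / speed on a unit grid.
// Source given as (row, col) 1-based.  Pixels within a 13x13 stencil of the
// source are initialised with the locally-constant-speed exact distance,
// which removes most of the point-source discretisation error.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cx_fmm(NumericMatrix speed, int src_row, int src_col) {
  const int nr = speed.nrow(), nc = speed.ncol();
  const double INF = std::numeric_limits<double>::infinity();
  NumericMatrix T(nr, nc);
  std::vector<int> state(nr * nc, 0); // 0 far, 1 trial, 2 known
  std::vector<char> fixedv(nr * nc, 0); // analytically initialised, immutable
  std::fill(T.begin(), T.end(), INF);

  typedef std::pair<double, int> QE; // (value, flat index)
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > heap;

  const int sr = src_row - 1, sc = src_col - 1;
  if (sr < 0 || sr >= nr || sc < 0 || sc >= nc)
    stop("source outside the grid");
  const double f0 = 1.0 / speed(sr, sc);
  for (int di = -6; di <= 6; ++di) {
    for (int dj = -6; dj <= 6; ++dj) {
      int i = sr + di, j = sc + dj;
      if (i < 0 || i >= nr || j < 0 || j >= nc) continue;
      double d = std::sqrt((double)(di * di + dj * dj)) * f0;
      int id = i + j * nr;
      T(i, j) = d;
      state[id] = 1;
      fixedv[id] = 1;
      heap.push(QE(d, id));
    }
  }

  const int oi[4] = {-1, 1, 0, 0};
  const int oj[4] = {0, 0, -1, 1};

  while (!heap.empty()) {
    QE top = heap.top(); heap.pop();
    int id = top.second;
    if (state[id] == 2) continue;       // stale entry
    state[id] = 2;
    int ci = id % nr, cj = id / nr;
    for (int n = 0; n < 4; ++n) {
      int i = ci + oi[n], j = cj + oj[n];
      if (i < 0 || i >= nr || j < 0 || j >= nc) continue;
      int nid = i + j * nr;
      if (state[nid] == 2 || fixedv[nid]) continue;
      double f = 1.0 / speed(i, j);
      // per-axis upwind value and coefficient (second order where the
      // next-but-one neighbour is also accepted and causally consistent)
      double av[2], cv[2];
      for (int ax = 0; ax < 2; ++ax) {
        double a1 = INF; int d1 = 0;
        int pi1 = ax == 0 ? i - 1 : i, pj1 = ax == 0 ? j : j - 1;
        int pi2 = ax == 0 ? i + 1 : i, pj2 = ax == 0 ? j : j + 1;
        if (pi1 >= 0 && pj1 >= 0 && state[pi1 + pj1 * nr] == 2 &&
            T(pi1, pj1) < a1) { a1 = T(pi1, pj1); d1 = -1; }
        if (pi2 < nr && pj2 < nc && state[pi2 + pj2 * nr] == 2 &&
            T(pi2, pj2) < a1) { a1 = T(pi2, pj2); d1 = +1; }
        av[ax] = a1; cv[ax] = 1.0;
        if (a1 < INF) {
          int qi = ax == 0 ? i + 2 * d1 : i, qj = ax == 0 ? j : j + 2 * d1;
          if (qi >= 0 && qi < nr && qj >= 0 && qj < nc &&
              state[qi + qj * nr] == 2 && T(qi, qj) <= a1) {
            av[ax] = (4.0 * a1 - T(qi, qj)) / 3.0;
            cv[ax] = 1.5;
          }
        }
      }
      // solve sum_ax cv^2 (T - av)^2 = f^2 with causality fallback
      double tnew = INF;
      for (int attempt = 0; attempt < 2; ++attempt) {
        double A = 0, B = 0, C = -f * f;
        int used = 0;
        for (int ax = 0; ax < 2; ++ax) {
          if (av[ax] == INF) continue;
          A += cv[ax] * cv[ax];
          B += cv[ax] * cv[ax] * av[ax];
          C += cv[ax] * cv[ax] * av[ax] * av[ax];
          ++used;
        }
        if (used == 0) break;
        double disc = B * B - A * C;
        if (disc >= 0) {
          double cand = (B + std::sqrt(disc)) / A;
          bool causal = true;
          for (int ax = 0; ax < 2; ++ax)
            if (av[ax] < INF && cand < av[ax]) causal = false;
          if (causal) { tnew = cand; break; }
        }
        // drop the axis with the larger upwind value and retry
        int drop = (av[0] == INF || (av[1] != INF && av[1] > av[0])) ? 1 : 0;
        av[drop] = INF;
      }
      if (tnew == INF) {
        double amin = std::min(av[0], av[1]);
        if (amin < INF) tnew = amin + f;
      }
      if (tnew < T(i, j)) {
        T(i, j) = tnew;
        state[nid] = 1;
        heap.push(QE(tnew, nid));
      }
    }
  }
  return T;
}

// ---------------------------------------------------------------------------
// Dijkstra shortest path on an 8-connected pixel grid with per-node costs.
// Edge weight = mean node cost of its ends times the Euclidean step length.
// blocked: integer matrix, nonzero entries are removed from the graph.
// Returns the path as a matrix of (row, col), 1-based, start to end.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cx_grid_dijkstra(NumericMatrix cost, IntegerMatrix blocked,
                               int start_row, int start_col,
                               int end_row, int end_col) {
  const int nr = cost.nrow(), nc = cost.ncol();
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> dist(nr * nc, INF);
  std::vector<int> prev(nr * nc, -1);
  std::vector<char> done(nr * nc, 0);
  typedef std::pair<double, int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > heap;

  const int s = (start_row - 1) + (start_col - 1) * nr;
  const int e = (end_row - 1) + (end_col - 1) * nr;
  if (blocked[s] || blocked[e]) stop("start or end node is blocked");
  dist[s] = 0.0;
  heap.push(QE(0.0, s));
  const int oi[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int oj[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const double sl[8] = {M_SQRT2, 1, M_SQRT2, 1, 1, M_SQRT2, 1, M_SQRT2};

  while (!heap.empty()) {
    QE top = heap.top(); heap.pop();
    int id = top.second;
    if (done[id]) continue;
    done[id] = 1;
    if (id == e) break;
    int ci = id % nr, cj = id / nr;
    for (int n = 0; n < 8; ++n) {
      int i = ci + oi[n], j = cj + oj[n];
      if (i < 0 || i >= nr || j < 0 || j >= nc) continue;
      int nid = i + j * nr;
      if (done[nid] || blocked[nid]) continue;
      double w = 0.5 * (cost[id] + cost[nid]) * sl[n];
      double nd = dist[id] + w;
      if (nd < dist[nid]) {
        dist[nid] = nd;
        prev[nid] = id;
        heap.push(QE(nd, nid));
      }
    }
  }
  if (!done[e]) stop("no path between the requested end-points");
  std::vector<int> path;
  for (int id = e; id != -1; id = prev[id]) path.push_back(id);
  IntegerMatrix out(path.size(), 2);
  for (int k = (int)path.size() - 1, r = 0; k >= 0; --k, ++r) {
    out(r, 0) = path[k] % nr + 1;
    out(r, 1) = path[k] / nr + 1;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Optimal subsequence bijection: minimum-cost strictly monotone one-to-one
// path through an m x p dissimilarity matrix.  Jumping from pair (q,w) to
// (k,l) (q<k, w<l) costs sqrt((k-q-1)^2 + (l-w-1)^2)*xi + delta(k,l); the
// virtual source is (0,0) and the virtual sink is (m+1, p+1), both with
// zero node cost and the same jump-cost formula.  At least one pair is
// required.  Cost ties are broken
// toward more pairs, then toward lexicographically smaller predecessors.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cx_osb_dp(NumericMatrix delta, double xi) {
  const int m = delta.nrow(), p = delta.ncol();
  const double INF = std::numeric_limits<double>::infinity();
  if (m == 0 || p == 0)
    return List::create(_["pairs"] = IntegerMatrix(0, 2), _["cost"] = 0.0);

  std::vector<double> best((size_t)m * p, INF);
  std::vector<int> npairs((size_t)m * p, 0), pred((size_t)m * p, -1);
  // precomputed jump lengths
  int md = std::max(m, p) + 1;
  std::vector<double> hyp((size_t)md * md);
  for (int a = 0; a < md; ++a)
    for (int b = 0; b < md; ++b)
      hyp[(size_t)a * md + b] = std::sqrt((double)(a * a + b * b));

  for (int k = 1; k <= m; ++k) {
    for (int l = 1; l <= p; ++l) {
      size_t id = (size_t)(k - 1) * p + (l - 1);
      // from source (0,0): skip k-1 and l-1 elements
      double c = hyp[(size_t)(k - 1) * md + (l - 1)] * xi + delta(k - 1, l - 1);
      best[id] = c; npairs[id] = 1; pred[id] = -1;
      for (int q = 1; q < k; ++q) {
        for (int w = 1; w < l; ++w) {
          size_t qid = (size_t)(q - 1) * p + (w - 1);
          double cand = best[qid] +
            hyp[(size_t)(k - q - 1) * md + (l - w - 1)] * xi + delta(k - 1, l - 1);
          int np = npairs[qid] + 1;
          if (cand < best[id] ||
              (cand == best[id] && (np > npairs[id]))) {
            best[id] = cand; npairs[id] = np; pred[id] = (int)qid;
          }
        }
      }
    }
  }
  // termination: any-end sink
  double tot = INF; int endid = -1; int endnp = 0;
  for (int k = 1; k <= m; ++k) {
    for (int l = 1; l <= p; ++l) {
      size_t id = (size_t)(k - 1) * p + (l - 1);
      double endc = xi * hyp[(size_t)(m - k) * md + (p - l)];
      double cand = best[id] + endc;
      if (cand < tot || (cand == tot && npairs[id] > endnp)) {
        tot = cand; endid = (int)id; endnp = npairs[id];
      }
    }
  }
  std::vector<int> chain;
  for (int id = endid; id != -1; id = pred[id]) chain.push_back(id);
  IntegerMatrix pairs(chain.size(), 2);
  for (int i = (int)chain.size() - 1, r = 0; i >= 0; --i, ++r) {
    pairs(r, 0) = chain[i] / p + 1;
    pairs(r, 1) = chain[i] % p + 1;
  }
  return List::create(_["pairs"] = pairs, _["cost"] = tot);
}

// ---------------------------------------------------------------------------
// Closest distance from each query point to a triangulated surface, signed
// by the outward normal of the nearest triangle.  V: nv x 3 vertices,
// F: nf x 3 1-based vertex indices.
// ---------------------------------------------------------------------------

static inline void closestOnTri(const double *P, const double *A,
                                const double *B, const double *C,
                                double *out) {
  // Ericson, Real-Time Collision Detection, 5.1.5
  double ab[3], ac[3], ap[3], bp[3], cp[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = B[i] - A[i]; ac[i] = C[i] - A[i]; ap[i] = P[i] - A[i];
  }
  double d1 = ab[0]*ap[0]+ab[1]*ap[1]+ab[2]*ap[2];
  double d2 = ac[0]*ap[0]+ac[1]*ap[1]+ac[2]*ap[2];
  if (d1 <= 0 && d2 <= 0) { for (int i=0;i<3;++i) out[i]=A[i]; return; }
  for (int i = 0; i < 3; ++i) bp[i] = P[i] - B[i];
  double d3 = ab[0]*bp[0]+ab[1]*bp[1]+ab[2]*bp[2];
  double d4 = ac[0]*bp[0]+ac[1]*bp[1]+ac[2]*bp[2];
  if (d3 >= 0 && d4 <= d3) { for (int i=0;i<3;++i) out[i]=B[i]; return; }
  double vc = d1*d4 - d3*d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    for (int i=0;i<3;++i) out[i] = A[i] + v*ab[i];
    return;
  }
  for (int i = 0; i < 3; ++i) cp[i] = P[i] - C[i];
  double d5 = ab[0]*cp[0]+ab[1]*cp[1]+ab[2]*cp[2];
  double d6 = ac[0]*cp[0]+ac[1]*cp[1]+ac[2]*cp[2];
  if (d6 >= 0 && d5 <= d6) { for (int i=0;i<3;++i) out[i]=C[i]; return; }
  double vb = d5*d2 - d1*d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    for (int i=0;i<3;++i) out[i] = A[i] + w*ac[i];
    return;
  }
  double va = d3*d6 - d5*d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i=0;i<3;++i) out[i] = B[i] + w*(C[i]-B[i]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i=0;i<3;++i) out[i] = A[i] + ab[i]*v + ac[i]*w;
}

// [[Rcpp::export]]
List cx_point_mesh(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  const int np = P.nrow(), nf = F.nrow();
  NumericVector dist(np), sgn(np);
  NumericMatrix closest(np, 3);
  IntegerVector tri(np);
  int ndegen = 0;
  // precompute triangle vertices and normals
  std::vector<double> tv(9 * (size_t)nf), tn(3 * (size_t)nf);
  std::vector<char> degen((size_t)nf, 0);
  for (int f = 0; f < nf; ++f) {
    for (int c = 0; c < 3; ++c) {
      int vi = F(f, c) - 1;
      tv[9*(size_t)f + 3*c + 0] = V(vi, 0);
      tv[9*(size_t)f + 3*c + 1] = V(vi, 1);
      tv[9*(size_t)f + 3*c + 2] = V(vi, 2);
    }
    double *A = &tv[9*(size_t)f], *B = A + 3, *C = A + 6;
    double e1[3], e2[3], n[3];
    for (int i=0;i<3;++i) { e1[i]=B[i]-A[i]; e2[i]=C[i]-A[i]; }
    n[0]=e1[1]*e2[2]-e1[2]*e2[1];
    n[1]=e1[2]*e2[0]-e1[0]*e2[2];
    n[2]=e1[0]*e2[1]-e1[1]*e2[0];
    double nn = std::sqrt(n[0]*n[0]+n[1]*n[1]+n[2]*n[2]);
    if (nn < 1e-14) { degen[f] = 1; ++ndegen; nn = 1.0; }
    for (int i=0;i<3;++i) tn[3*(size_t)f+i] = n[i]/nn;
  }
  for (int q = 0; q < np; ++q) {
    double Pq[3] = {P(q,0), P(q,1), P(q,2)};
    double bestd = std::numeric_limits<double>::infinity();
    int bestf = -1; double bestc[3] = {0,0,0};
    for (int f = 0; f < nf; ++f) {
      if (degen[f]) continue;
      double cpt[3];
      closestOnTri(Pq, &tv[9*(size_t)f], &tv[9*(size_t)f+3], &tv[9*(size_t)f+6], cpt);
      double dx=Pq[0]-cpt[0], dy=Pq[1]-cpt[1], dz=Pq[2]-cpt[2];
      double d2 = dx*dx+dy*dy+dz*dz;
      if (d2 < bestd) { bestd = d2; bestf = f; bestc[0]=cpt[0]; bestc[1]=cpt[1]; bestc[2]=cpt[2]; }
    }
    dist[q] = std::sqrt(bestd);
    tri[q] = bestf + 1;
    closest(q, 0) = bestc[0]; closest(q, 1) = bestc[1]; closest(q, 2) = bestc[2];
    double dp = (Pq[0]-bestc[0])*tn[3*(size_t)bestf] +
                (Pq[1]-bestc[1])*tn[3*(size_t)bestf+1] +
                (Pq[2]-bestc[2])*tn[3*(size_t)bestf+2];
    sgn[q] = (dp >= 0) ? 1.0 : -1.0;
  }
  return List::create(_["dist"] = dist, _["sign"] = sgn, _["tri"] = tri,
                      _["closest"] = closest, _["n_degenerate"] = ndegen);
}
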