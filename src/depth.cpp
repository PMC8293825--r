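#include <RcppArmadillo.h>
#include <algorithm>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Exact trivariate halfspace (Tukey) depth. depth(theta) = min over unit
// vectors u of #{k : u.(x_k - theta) >= 0}, which always includes theta
// (closed half-space). The minimum over all directions is attained in the
// limit at planes through theta and two data points, so it suffices to
// sweep, for every data point x_j, the pencil of planes containing the
// line (theta, x_j): project the remaining points on the plane orthogonal
// to that line and run a circular sweep over their angles. Points on the
// axis line itself can be pushed to either side by an infinitesimal tilt
// of the plane (points at t > 0 move together, opposite to those at
// t < 0), hence contribute min(#t>0, #t<0); points coincident with theta
// can never be separated and always count. O(n^2 log n) per point.

// pseudo-angle: piecewise-rational bijection [0, 4) <-> [0, 2*pi),
// monotone in atan2(y, x); the antipode (-x, -y) maps to key + 2 (mod 4)
static inline double pseudo_angle(double x, double y) {
  double r = y / (std::fabs(x) + std::fabs(y));
  if (x < 0) r = 2.0 - r;
  else if (y < 0) r = 4.0 + r;
  return r;
}

struct DepthWork {
  std::vector<double> D, nrm, w, tmp;
  std::vector<int> cnt;
};

// bucket sort for pseudo-angle keys in [0, 4): counting pass over 1024
// buckets, scatter, then an insertion-sort finish of the nearly-sorted
// array -- much faster than std::sort at the n^2 calls the sweep makes
static void sort_keys(std::vector<double>& key, std::vector<int>& cnt,
                      std::vector<double>& tmp) {
  const int B = 1024;
  const int m = (int)key.size();
  if ((int)cnt.size() < B + 1) cnt.assign(B + 1, 0);
  else std::fill(cnt.begin(), cnt.begin() + B + 1, 0);
  for (int t = 0; t < m; ++t) ++cnt[(int)(key[t] * 256.0) + 1];
  for (int b = 1; b <= B; ++b) cnt[b] += cnt[b - 1];
  tmp.resize(m);
  for (int t = 0; t < m; ++t) tmp[cnt[(int)(key[t] * 256.0)]++] = key[t];
  for (int t = 1; t < m; ++t) {
    double v = tmp[t];
    int q = t;
    while (q > 0 && tmp[q - 1] > v) { tmp[q] = tmp[q - 1]; --q; }
    tmp[q] = v;
  }
  key.swap(tmp);
}

// max number of angles inside a half-open half-turn arc [a, a + pi) over
// all anchors a; keys are sorted pseudo-angles, a half turn is key + 2
static int max_in_half_open_arc(const std::vector<double>& key) {
  const int m = key.size();
  int best = 0;
  size_t e = 0;
  for (int s = 0; s < m; ++s) {
    if (e < (size_t)s) e = s;
    const double lim = key[s] + 2.0 - 1e-12; // exclude the exact antipode
    while (e < (size_t)(s + m)) {
      const double ke = (e < (size_t)m) ? key[e] : key[e - m] + 4.0;
      if (ke < lim) ++e; else break;
    }
    if ((int)(e - s) > best) best = (int)(e - s);
  }
  return best;
}

// exact depth of point i; the axis loop stops early once the running
// minimum reaches `floor_stop` (the smallest value still of interest to
// the caller; pass 1 for the plain exact depth)
static int depth_of_point(const std::vector<double>& pts, int n, int i,
                          double eps, int floor_stop, DepthWork& ws) {
  const double eps2 = eps * eps;
  ws.D.resize(3 * n);
  ws.nrm.resize(n);
  const double tx = pts[3 * i], ty = pts[3 * i + 1], tz = pts[3 * i + 2];
  int coincident = 0;
  for (int k = 0; k < n; ++k) {
    const double dx = pts[3 * k] - tx, dy = pts[3 * k + 1] - ty,
                 dz = pts[3 * k + 2] - tz;
    ws.D[3 * k] = dx; ws.D[3 * k + 1] = dy; ws.D[3 * k + 2] = dz;
    ws.nrm[k] = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (ws.nrm[k] <= eps) ++coincident;
  }
  if (coincident == n) return n;
  const int stop_at = std::max(coincident, floor_stop);

  int best = n;
  for (int j = 0; j < n && best > stop_at; ++j) {
    if (ws.nrm[j] <= eps) continue;
    const double ux = ws.D[3 * j] / ws.nrm[j],
                 uy = ws.D[3 * j + 1] / ws.nrm[j],
                 uz = ws.D[3 * j + 2] / ws.nrm[j];
    // orthonormal basis (e1, e2) of the plane orthogonal to u
    double ax, ay, az;
    if (std::fabs(ux) < 0.9) { ax = 1; ay = 0; az = 0; }
    else { ax = 0; ay = 1; az = 0; }
    const double au = ax * ux + ay * uy + az * uz;
    double e1x = ax - au * ux, e1y = ay - au * uy, e1z = az - au * uz;
    const double e1n = std::sqrt(e1x * e1x + e1y * e1y + e1z * e1z);
    e1x /= e1n; e1y /= e1n; e1z /= e1n;
    const double e2x = uy * e1z - uz * e1y, e2y = uz * e1x - ux * e1z,
                 e2z = ux * e1y - uy * e1x;

    ws.w.clear();
    int pos_line = 0, neg_line = 0;
    for (int k = 0; k < n; ++k) {
      if (ws.nrm[k] <= eps) continue;
      const double dx = ws.D[3 * k], dy = ws.D[3 * k + 1],
                   dz = ws.D[3 * k + 2];
      const double t = dx * ux + dy * uy + dz * uz;
      // in-plane coordinates; wa^2 + wb^2 = |d - t u|^2 exactly
      const double wa = dx * e1x + dy * e1y + dz * e1z;
      const double wb = dx * e2x + dy * e2y + dz * e2z;
      if (wa * wa + wb * wb <= eps2) {
        if (t > 0) ++pos_line; else ++neg_line;
      } else {
        ws.w.push_back(pseudo_angle(wa, wb));
      }
    }
    const int m = (int)ws.w.size();
    int cand;
    if (m == 0) {
      cand = coincident + std::min(pos_line, neg_line);
    } else {
      sort_keys(ws.w, ws.cnt, ws.tmp);
      int arc = max_in_half_open_arc(ws.w);
      cand = coincident + std::min(pos_line, neg_line) + (m - arc);
    }
    if (cand < best) best = cand;
  }
  return best;
}

static std::vector<double> flatten_rows(const arma::mat& P) {
  const int n = P.n_rows;
  std::vector<double> pts(3 * n);
  for (int k = 0; k < n; ++k) {
    pts[3 * k] = P(k, 0);
    pts[3 * k + 1] = P(k, 1);
    pts[3 * k + 2] = P(k, 2);
  }
  return pts;
}

// [[Rcpp::export]]
IntegerVector halfspace_depth_exact_cpp(const arma::mat& P) {
  const int n = P.n_rows;
  IntegerVector depth(n);
  const double eps = 1e-9 * (arma::abs(P).max() + 1e-300);
  std::vector<double> pts = flatten_rows(P);
  DepthWork ws;
  for (int i = 0; i < n; ++i)
    depth[i] = depth_of_point(pts, n, i, eps, 1, ws);
  return depth;
}

// Random-projection approximation: for each of K unit directions, every
// point's candidate depth is the smaller of the weakly-left and
// weakly-right counts of the projected cloud; the depth estimate is the
// minimum over directions. Always >= the exact depth.
// [[Rcpp::export]]
IntegerVector halfspace_depth_projection_cpp(const arma::mat& P,
                                             const arma::mat& U) {
  const int n = P.n_rows, K = U.n_rows;
  const double scale = arma::abs(P).max() + 1e-300;
  const double eps = 1e-12 * scale;
  IntegerVector depth(n, n);
  arma::vec proj(n), sorted(n);
  for (int d = 0; d < K; ++d) {
    proj = P * U.row(d).t();
    sorted = arma::sort(proj);
    const double* s0 = sorted.memptr();
    const double* s1 = s0 + n;
    for (int i = 0; i < n; ++i) {
      int c_le = std::upper_bound(s0, s1, proj[i] + eps) - s0;
      int c_ge = n - (std::lower_bound(s0, s1, proj[i] - eps) - s0);
      int cand = std::min(c_le, c_ge);
      if (cand < depth[i]) depth[i] = cand;
    }
  }
  return depth;
}

// Certified leverage extremes without computing every exact depth.
// Shallow side (lowest depth, ties to the smallest index): scan points in
// index order computing exact depths; once n_each points of depth 1 are
// found no later point can improve on them, so the scan stops.
// Deep side (highest depth): deterministic Fibonacci-sphere projection
// depths give upper bounds U_i >= exact depth; only candidates whose
// bound reaches the current n_each-th best exact depth need an exact
// evaluation, and candidates are visited in decreasing-bound order.
// Returns 1-based index vectors ordered as by (depth, index) comparators.
// [[Rcpp::export]]
List depth_extremes_cpp(const arma::mat& P, int n_each, int K) {
  const int n = P.n_rows;
  const double eps = 1e-9 * (arma::abs(P).max() + 1e-300);
  std::vector<double> pts = flatten_rows(P);
  DepthWork ws;

  // ---- shallow side ----
  typedef std::pair<int, int> DI; // (depth, index)
  std::vector<DI> shallow;
  int ones = 0;
  for (int i = 0; i < n && ones < n_each; ++i) {
    int d = depth_of_point(pts, n, i, eps, 1, ws);
    shallow.push_back(DI(d, i));
    if (d == 1) ++ones;
  }
  std::stable_sort(shallow.begin(), shallow.end());
  std::vector<int> high_idx, high_d;
  for (int t = 0; t < n_each && t < (int)shallow.size(); ++t) {
    high_idx.push_back(shallow[t].second + 1);
    high_d.push_back(shallow[t].first);
  }

  // ---- deep side ----
  // deterministic Fibonacci-sphere directions
  arma::mat U(K, 3);
  const double ga = M_PI * (1.0 + std::sqrt(5.0));
  for (int d = 0; d < K; ++d) {
    const double z = 1.0 - 2.0 * (d + 0.5) / K;
    const double rr = std::sqrt(std::max(0.0, 1.0 - z * z));
    U(d, 0) = rr * std::cos(ga * (d + 0.5));
    U(d, 1) = rr * std::sin(ga * (d + 0.5));
    U(d, 2) = z;
  }
  IntegerVector ub = halfspace_depth_projection_cpp(P, U);
  std::vector<std::pair<int, int> > order(n); // (-bound, index)
  for (int i = 0; i < n; ++i) order[i] = std::make_pair(-ub[i], i);
  std::sort(order.begin(), order.end());

  std::vector<DI> deep; // (-depth, index), best first
  for (int t = 0; t < n; ++t) {
    const int bound = -order[t].first, i = order[t].second;
    if ((int)deep.size() >= n_each && bound < -deep[n_each - 1].first)
      break; // bound below the current n_each-th best exact depth
    int d = depth_of_point(pts, n, i, eps, 1, ws);
    deep.push_back(DI(-d, i));
    std::sort(deep.begin(), deep.end());
  }
  std::vector<int> low_idx, low_d;
  for (int t = 0; t < n_each && t < (int)deep.size(); ++t) {
    low_idx.push_back(deep[t].second + 1);
    low_d.push_back(-deep[t].first);
  }

  return List::create(_["low_leverage"] = wrap(low_idx),
                      _["low_depth"] = wrap(low_d),
                      _["high_leverage"] = wrap(high_idx),
                      _["high_depth"] = wrap(high_d));
}
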