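#include <Rcpp.h>
#include <unordered_map>
#include "kdtree.h"
using namespace Rcpp;

static std::vector<double> flatten(const NumericMatrix& m) {
  int n = m.nrow();
  std::vector<double> out(3 * n);
  for (int i = 0; i < n; ++i) {
    out[3 * i]     = m(i, 0);
    out[3 * i + 1] = m(i, 1);
    out[3 * i + 2] = m(i, 2);
  }
  return out;
}

// k nearest neighbours in `ref` for every row of `query`.
// If exclude_self is true, ref and query are taken to be the same matrix and
// the i-th query skips reference point i. Returns 1-based indices.
// [[Rcpp::export]]
List cpp_knn(NumericMatrix ref, NumericMatrix query, int k, bool exclude_self = false) {
  int n = ref.nrow(), m = query.nrow();
  if (n < 1) stop("empty reference cloud");
  int avail = exclude_self ? n - 1 : n;
  if (k > avail) stop("k larger than available reference points");
  std::vector<double> rp = flatten(ref);
  KDTree tree(rp.data(), n);
  IntegerMatrix oi(m, k);
  NumericMatrix od(m, k);
  std::vector<int> ii(k);
  std::vector<double> dd(k);
  for (int i = 0; i < m; ++i) {
    double q[3] = { query(i, 0), query(i, 1), query(i, 2) };
    tree.knn(q, k, exclude_self ? i : -1, ii.data(), dd.data());
    for (int j = 0; j < k; ++j) { oi(i, j) = ii[j] + 1; od(i, j) = std::sqrt(dd[j]); }
  }
  return List::create(_["idx"] = oi, _["dist"] = od);
}

// Farthest point sampling: n points, seeded by a start index (1-based).
// [[Rcpp::export]]
IntegerVector cpp_fps(NumericMatrix pts, int n, int start) {
  int N = pts.nrow();
  if (n > N) stop("n larger than cloud size");
  if (start < 1 || start > N) stop("bad start index");
  std::vector<double> p = flatten(pts);
  std::vector<double> mind(N, std::numeric_limits<double>::infinity());
  IntegerVector sel(n);
  int cur = start - 1;
  for (int s = 0; s < n; ++s) {
    sel[s] = cur + 1;
    const double* c = p.data() + 3 * cur;
    int nxt = 0;
    double best = -1.0;
    for (int i = 0; i < N; ++i) {
      double dx = p[3 * i] - c[0], dy = p[3 * i + 1] - c[1], dz = p[3 * i + 2] - c[2];
      double d = dx * dx + dy * dy + dz * dz;
      if (d < mind[i]) mind[i] = d;
      if (mind[i] > best) { best = mind[i]; nxt = i; }
    }
    cur = nxt;
  }
  return sel;
}

// Greedy Poisson-disk (dart-throwing) selection: visit points in `order`
// (1-based permutation), accept a point iff no previously accepted point lies
// within radius r. Returns accepted indices (1-based, in acceptance order).
// [[Rcpp::export]]
IntegerVector cpp_poisson_disk(NumericMatrix pts, double r, IntegerVector order) {
  int n = pts.nrow();
  if (r <= 0) {
    IntegerVector all(order.size());
    for (int i = 0; i < order.size(); ++i) all[i] = order[i];
    return all;
  }
  std::vector<double> p = flatten(pts);
  double mn[3] = { R_PosInf, R_PosInf, R_PosInf };
  for (int i = 0; i < n; ++i)
    for (int a = 0; a < 3; ++a) mn[a] = std::min(mn[a], p[3 * i + a]);
  const double cell = r;
  const double r2 = r * r;
  std::unordered_map<long long, std::vector<int> > grid;
  grid.reserve(n / 2);
  std::vector<int> acc;
  acc.reserve(1024);
  for (int oi = 0; oi < order.size(); ++oi) {
    int i = order[oi] - 1;
    const double* q = p.data() + 3 * i;
    long long cx = (long long)std::floor((q[0] - mn[0]) / cell);
    long long cy = (long long)std::floor((q[1] - mn[1]) / cell);
    long long cz = (long long)std::floor((q[2] - mn[2]) / cell);
    bool ok = true;
    for (long long ax = cx - 1; ax <= cx + 1 && ok; ++ax)
      for (long long ay = cy - 1; ay <= cy + 1 && ok; ++ay)
        for (long long az = cz - 1; az <= cz + 1 && ok; ++az) {
          long long key = (ax * 73856093LL) ^ (ay * 19349663LL) ^ (az * 83492791LL);
          auto it = grid.find(key);
          if (it == grid.end()) continue;
          for (int j : it->second) {
            const double* a = p.data() + 3 * j;
            double dx = a[0] - q[0], dy = a[1] - q[1], dz = a[2] - q[2];
            if (dx * dx + dy * dy + dz * dz < r2) { ok = false; break; }
          }
        }
    if (ok) {
      long long key = (cx * 73856093LL) ^ (cy * 19349663LL) ^ (cz * 83492791LL);
      grid[key].push_back(i);
      acc.push_back(i + 1);
    }
  }
  return IntegerVector(acc.begin(), acc.end());
}
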