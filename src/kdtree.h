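#pragma once
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>

// Static 3-d kd-tree over a flat row-major (n x 3) point array.
// Median split along the widest axis; leaves hold up to 16 points.
struct KDTree {
  const double* pts;
  int n;
  std::vector<int> idx;
  struct Node { int lo, hi, axis, left, right; double split; };
  std::vector<Node> nodes;
  int root;
  static const int LEAF = 16;

  KDTree(const double* p, int n_) : pts(p), n(n_) {
    idx.resize(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    nodes.reserve(2 * n / LEAF + 4);
    root = build(0, n);
  }

  int build(int lo, int hi) {
    int me = (int)nodes.size();
    nodes.push_back(Node{lo, hi, 0, -1, -1, 0.0});
    if (hi - lo <= LEAF) return me;
    double mn[3] = { std::numeric_limits<double>::infinity(),
                     std::numeric_limits<double>::infinity(),
                     std::numeric_limits<double>::infinity() };
    double mx[3] = { -mn[0], -mn[1], -mn[2] };
    for (int i = lo; i < hi; ++i) {
      const double* q = pts + 3 * idx[i];
      for (int a = 0; a < 3; ++a) {
        if (q[a] < mn[a]) mn[a] = q[a];
        if (q[a] > mx[a]) mx[a] = q[a];
      }
    }
    int ax = 0;
    double best = mx[0] - mn[0];
    for (int a = 1; a < 3; ++a)
      if (mx[a] - mn[a] > best) { best = mx[a] - mn[a]; ax = a; }
    if (best <= 0.0) return me;  // all points identical: leave as leaf
    int mid = (lo + hi) / 2;
    std::nth_element(idx.begin() + lo, idx.begin() + mid, idx.begin() + hi,
                     [&](int a, int b) { return pts[3 * a + ax] < pts[3 * b + ax]; });
    double sp = pts[3 * idx[mid] + ax];
    int l = build(lo, mid);
    int r = build(mid, hi);
    nodes[me].axis = ax; nodes[me].split = sp;
    nodes[me].left = l; nodes[me].right = r;
    return me;
  }

  // k best kept in simple insertion-sorted arrays (k is small).
  struct KBest {
    int k;
    std::vector<int> id;
    std::vector<double> d2;
    KBest(int k_) : k(k_), id(k_, -1), d2(k_, std::numeric_limits<double>::infinity()) {}
    double worst() const { return d2[k - 1]; }
    void push(int i, double dd) {
      if (dd >= d2[k - 1]) return;
      int j = k - 1;
      while (j > 0 && d2[j - 1] > dd) { d2[j] = d2[j - 1]; id[j] = id[j - 1]; --j; }
      d2[j] = dd; id[j] = i;
    }
  };

  void search(int node, const double* q, KBest& kb, int exclude) const {
    const Node& nd = nodes[node];
    if (nd.left < 0) {
      for (int i = nd.lo; i < nd.hi; ++i) {
        int pi = idx[i];
        if (pi == exclude) continue;
        const double* p = pts + 3 * pi;
        double dx = p[0] - q[0], dy = p[1] - q[1], dz = p[2] - q[2];
        kb.push(pi, dx * dx + dy * dy + dz * dz);
      }
      return;
    }
    double diff = q[nd.axis] - nd.split;
    int near = diff <= 0 ? nd.left : nd.right;
    int far  = diff <= 0 ? nd.right : nd.left;
    search(near, q, kb, exclude);
    if (diff * diff < kb.worst()) search(far, q, kb, exclude);
  }

  void knn(const double* q, int k, int exclude, int* out_idx, double* out_d2) const {
    KBest kb(k);
    search(root, q, kb, exclude);
    for (int j = 0; j < k; ++j) { out_idx[j] = kb.id[j]; out_d2[j] = kb.d2[j]; }
  }
};
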