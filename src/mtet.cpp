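#include <Rcpp.h>
#include <unordered_map>
using namespace Rcpp;

// Iso-surface extraction by marching tetrahedra on the Freudenthal (6-tet)
// decomposition of a uniform grid. The decomposition is face-consistent
// across neighbouring cells, so the extracted surface of a level set that
// stays inside the grid is a crack-free closed 2-manifold. Vertices on cell
// edges are welded exactly via (grid-node, grid-node) edge keys.
//
// field: G^3 values in R array order (x fastest), dims = (nx, ny, nz).
// Positive field = inside; triangles are wound so normals point outside.
// [[Rcpp::export]]
List cpp_marching_tets(NumericVector field, IntegerVector dims,
                       NumericVector origin, double h) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long long NXY = (long long)nx * ny;
  auto gid = [&](int i, int j, int k) { return (long long)i + nx * ((long long)j + (long long)ny * k); };

  // Freudenthal: 6 tets per cube, each a monotone path 000 -> 111.
  static const int perms[6][3] = { {0,1,2},{0,2,1},{1,0,2},{1,2,0},{2,0,1},{2,1,0} };

  std::unordered_map<unsigned long long, int> vmap;
  std::vector<double> verts;
  std::vector<int> faces;
  // endpoints of emitted interpolated vertices (for downstream attribute lookup)
  std::vector<long long> vend1, vend2;

  auto fval = [&](long long g) {
    double v = field[g];
    if (v == 0.0) v = 1e-300;  // nudge exact zeros so the surface avoids nodes
    return v;
  };

  auto edge_vertex = [&](long long ga, long long gb, double va, double vb) {
    unsigned long long key;
    long long lo = std::min(ga, gb), hi = std::max(ga, gb);
    key = (unsigned long long)lo * (unsigned long long)(NXY * nz) + (unsigned long long)hi;
    auto it = vmap.find(key);
    if (it != vmap.end()) return it->second;
    double t = va / (va - vb);
    if (t < 0) t = 0; if (t > 1) t = 1;
    int ai = (int)(ga % nx), aj = (int)((ga / nx) % ny), ak = (int)(ga / NXY);
    int bi = (int)(gb % nx), bj = (int)((gb / nx) % ny), bk = (int)(gb / NXY);
    double px = origin[0] + h * (ai + t * (bi - ai));
    double py = origin[1] + h * (aj + t * (bj - aj));
    double pz = origin[2] + h * (ak + t * (bk - ak));
    int id = (int)(verts.size() / 3);
    verts.push_back(px); verts.push_back(py); verts.push_back(pz);
    vend1.push_back(ga); vend2.push_back(gb);
    vmap.emplace(key, id);
    return id;
  };

  auto emit = [&](int v0, int v1, int v2, const double* toward, bool point_at) {
    // orient so the normal points toward (point_at) or away from `toward`
    const double* a = verts.data() + 3 * v0;
    const double* b = verts.data() + 3 * v1;
    const double* c = verts.data() + 3 * v2;
    double e1[3] = { b[0]-a[0], b[1]-a[1], b[2]-a[2] };
    double e2[3] = { c[0]-a[0], c[1]-a[1], c[2]-a[2] };
    double nrm[3] = { e1[1]*e2[2]-e1[2]*e2[1], e1[2]*e2[0]-e1[0]*e2[2], e1[0]*e2[1]-e1[1]*e2[0] };
    double d = nrm[0]*(toward[0]-a[0]) + nrm[1]*(toward[1]-a[1]) + nrm[2]*(toward[2]-a[2]);
    bool flip = point_at ? (d < 0) : (d > 0);
    if (flip) std::swap(v1, v2);
    faces.push_back(v0 + 1); faces.push_back(v1 + 1); faces.push_back(v2 + 1);
  };

  long long tg[4];
  double tv[4], corner_pos[3];
  int off[4][3];

  for (int k = 0; k < nz - 1; ++k)
    for (int j = 0; j < ny - 1; ++j)
      for (int i = 0; i < nx - 1; ++i) {
        // quick reject: all 8 corners same sign
        bool any_pos = false, any_neg = false;
        for (int c = 0; c < 8; ++c) {
          double v = fval(gid(i + (c & 1), j + ((c >> 1) & 1), k + ((c >> 2) & 1)));
          if (v > 0) any_pos = true; else any_neg = true;
        }
        if (!any_pos || !any_neg) continue;
        for (int t = 0; t < 6; ++t) {
          off[0][0] = 0; off[0][1] = 0; off[0][2] = 0;
          for (int s = 0; s < 3; ++s) {
            off[s + 1][0] = off[s][0]; off[s + 1][1] = off[s][1]; off[s + 1][2] = off[s][2];
            off[s + 1][perms[t][s]] += 1;
          }
          int npos = 0;
          for (int c = 0; c < 4; ++c) {
            tg[c] = gid(i + off[c][0], j + off[c][1], k + off[c][2]);
            tv[c] = fval(tg[c]);
            if (tv[c] > 0) ++npos;
          }
          if (npos == 0 || npos == 4) continue;
          if (npos == 1 || npos == 3) {
            bool lone_pos = (npos == 1);
            int lone = -1;
            for (int c = 0; c < 4; ++c)
              if ((tv[c] > 0) == lone_pos) { lone = c; break; }
            int others[3], m = 0;
            for (int c = 0; c < 4; ++c) if (c != lone) others[m++] = c;
            int e0 = edge_vertex(tg[lone], tg[others[0]], tv[lone], tv[others[0]]);
            int e1 = edge_vertex(tg[lone], tg[others[1]], tv[lone], tv[others[1]]);
            int e2 = edge_vertex(tg[lone], tg[others[2]], tv[lone], tv[others[2]]);
            corner_pos[0] = origin[0] + h * (i + off[lone][0]);
            corner_pos[1] = origin[1] + h * (j + off[lone][1]);
            corner_pos[2] = origin[2] + h * (k + off[lone][2]);
            // normal must point toward the negative (outside) region:
            // away from a lone positive corner, at a lone negative corner.
            emit(e0, e1, e2, corner_pos, !lone_pos);
          } else {
            int pos[2], neg[2], mp = 0, mn = 0;
            for (int c = 0; c < 4; ++c) {
              if (tv[c] > 0) pos[mp++] = c; else neg[mn++] = c;
            }
            int q0 = edge_vertex(tg[pos[0]], tg[neg[0]], tv[pos[0]], tv[neg[0]]);
            int q1 = edge_vertex(tg[pos[0]], tg[neg[1]], tv[pos[0]], tv[neg[1]]);
            int q2 = edge_vertex(tg[pos[1]], tg[neg[1]], tv[pos[1]], tv[neg[1]]);
            int q3 = edge_vertex(tg[pos[1]], tg[neg[0]], tv[pos[1]], tv[neg[0]]);
            corner_pos[0] = origin[0] + h * (i + off[neg[0]][0]);
            corner_pos[1] = origin[1] + h * (j + off[neg[0]][1]);
            corner_pos[2] = origin[2] + h * (k + off[neg[0]][2]);
            emit(q0, q1, q2, corner_pos, true);
            emit(q0, q2, q3, corner_pos, true);
          }
        }
      }

  int nvtx = (int)(verts.size() / 3);
  NumericMatrix Vm(nvtx, 3);
  for (int v = 0; v < nvtx; ++v) {
    Vm(v, 0) = verts[3 * v]; Vm(v, 1) = verts[3 * v + 1]; Vm(v, 2) = verts[3 * v + 2];
  }
  int nfc = (int)(faces.size() / 3);
  IntegerMatrix Fm(nfc, 3);
  for (int f = 0; f < nfc; ++f) {
    Fm(f, 0) = faces[3 * f]; Fm(f, 1) = faces[3 * f + 1]; Fm(f, 2) = faces[3 * f + 2];
  }
  return List::create(_["vertices"] = Vm, _["faces"] = Fm);
}
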