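#include <Rcpp.h>
using namespace Rcpp;

// Orthographic z-buffer rasterizer.
// rot: 3x3, rows are the camera axes (right, up, forward) in world coords.
// cam: camera position (world, mm). A world point p maps to camera coords
//   c = rot %*% (p - cam); depth is c[2] (distance along the view direction).
// Pixel (row i, col j), both 0-based here, has camera-plane coords
//   x = ext_x * ((j + 0.5)/W - 0.5),  y = ext_y * ((i + 0.5)/H - 0.5).
// Returns the HxW depth matrix (NA background) and the 1-based triangle id
// that won the z-test at each pixel (0 background).
// [[Rcpp::export]]
List cpp_render_depth(NumericMatrix V, IntegerMatrix F, NumericMatrix rot,
                      NumericVector cam, double ext_x, double ext_y,
                      int W, int H) {
  int nv = V.nrow(), nf = F.nrow();
  std::vector<double> cx(nv), cy(nv), cz(nv);
  for (int i = 0; i < nv; ++i) {
    double p0 = V(i, 0) - cam[0], p1 = V(i, 1) - cam[1], p2 = V(i, 2) - cam[2];
    cx[i] = rot(0, 0) * p0 + rot(0, 1) * p1 + rot(0, 2) * p2;
    cy[i] = rot(1, 0) * p0 + rot(1, 1) * p1 + rot(1, 2) * p2;
    cz[i] = rot(2, 0) * p0 + rot(2, 1) * p1 + rot(2, 2) * p2;
  }
  NumericMatrix depth(H, W);
  IntegerMatrix tri(H, W);
  std::fill(depth.begin(), depth.end(), R_PosInf);
  // pixel coords: u = (x/ext_x + 0.5) * W - 0.5
  auto to_u = [&](double x) { return (x / ext_x + 0.5) * W - 0.5; };
  auto to_v = [&](double y) { return (y / ext_y + 0.5) * H - 0.5; };
  for (int f = 0; f < nf; ++f) {
    int a = F(f, 0) - 1, b = F(f, 1) - 1, c = F(f, 2) - 1;
    double ua = to_u(cx[a]), va = to_v(cy[a]), za = cz[a];
    double ub = to_u(cx[b]), vb = to_v(cy[b]), zb = cz[b];
    double uc = to_u(cx[c]), vc = to_v(cy[c]), zc = cz[c];
    if (!R_finite(ua) || !R_finite(ub) || !R_finite(uc) ||
        !R_finite(va) || !R_finite(vb) || !R_finite(vc)) continue;
    double area = (ub - ua) * (vc - va) - (uc - ua) * (vb - va);
    if (std::fabs(area) < 1e-12) continue;
    int j0 = std::max(0, (int)std::ceil(std::min(ua, std::min(ub, uc))));
    int j1 = std::min(W - 1, (int)std::floor(std::max(ua, std::max(ub, uc))));
    int i0 = std::max(0, (int)std::ceil(std::min(va, std::min(vb, vc))));
    int i1 = std::min(H - 1, (int)std::floor(std::max(va, std::max(vb, vc))));
    double inv = 1.0 / area;
    for (int i = i0; i <= i1; ++i) {
      for (int j = j0; j <= j1; ++j) {
        double pu = j, pv = i;
        double w0 = ((ub - pu) * (vc - pv) - (uc - pu) * (vb - pv)) * inv;
        double w1 = ((uc - pu) * (va - pv) - (ua - pu) * (vc - pv)) * inv;
        double w2 = 1.0 - w0 - w1;
        if (w0 < 0 || w1 < 0 || w2 < 0) continue;
        double z = w0 * za + w1 * zb + w2 * zc;
        if (z < depth(i, j)) { depth(i, j) = z; tri(i, j) = f + 1; }
      }
    }
  }
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j)
      if (!R_finite(depth(i, j))) depth(i, j) = NA_REAL;
  return List::create(_["depth"] = depth, _["tri"] = tri);
}
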