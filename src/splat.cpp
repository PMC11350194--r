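#include <Rcpp.h>
using namespace Rcpp;

// Trilinear splat of oriented points onto a uniform G^3 grid: a vector field
// carrying the normals and a scalar sample-density field. Grid node (i,j,k)
// sits at origin + h*(i,j,k); arrays are in R order (x fastest).
// [[Rcpp::export]]
List cpp_splat_field(NumericMatrix pts, NumericMatrix normals, int G,
                     NumericVector origin, double h) {
  long long NG = (long long)G * G * G;
  NumericVector vx(NG), vy(NG), vz(NG), dens(NG);
  int n = pts.nrow();
  for (int p = 0; p < n; ++p) {
    double gx = (pts(p, 0) - origin[0]) / h;
    double gy = (pts(p, 1) - origin[1]) / h;
    double gz = (pts(p, 2) - origin[2]) / h;
    int i0 = (int)std::floor(gx), j0 = (int)std::floor(gy), k0 = (int)std::floor(gz);
    if (i0 < 0 || j0 < 0 || k0 < 0 || i0 >= G - 1 || j0 >= G - 1 || k0 >= G - 1)
      continue;
    double fx = gx - i0, fy = gy - j0, fz = gz - k0;
    for (int di = 0; di < 2; ++di)
      for (int dj = 0; dj < 2; ++dj)
        for (int dk = 0; dk < 2; ++dk) {
          double w = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) * (dk ? fz : 1 - fz);
          long long idx = (long long)(i0 + di) +
                          (long long)G * ((j0 + dj) + (long long)G * (k0 + dk));
          vx[idx] += w * normals(p, 0);
          vy[idx] += w * normals(p, 1);
          vz[idx] += w * normals(p, 2);
          dens[idx] += w;
        }
  }
  return List::create(_["vx"] = vx, _["vy"] = vy, _["vz"] = vz, _["density"] = dens);
}

// Trilinear interpolation of a G^3 scalar field at query points.
// Out-of-grid queries return 0.
// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector field, int G, NumericVector origin,
                            double h, NumericMatrix q) {
  int n = q.nrow();
  NumericVector out(n);
  for (int p = 0; p < n; ++p) {
    double gx = (q(p, 0) - origin[0]) / h;
    double gy = (q(p, 1) - origin[1]) / h;
    double gz = (q(p, 2) - origin[2]) / h;
    int i0 = (int)std::floor(gx), j0 = (int)std::floor(gy), k0 = (int)std::floor(gz);
    if (i0 < 0 || j0 < 0 || k0 < 0 || i0 >= G - 1 || j0 >= G - 1 || k0 >= G - 1) {
      out[p] = 0.0;
      continue;
    }
    double fx = gx - i0, fy = gy - j0, fz = gz - k0;
    double acc = 0.0;
    for (int di = 0; di < 2; ++di)
      for (int dj = 0; dj < 2; ++dj)
        for (int dk = 0; dk < 2; ++dk) {
          double w = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) * (dk ? fz : 1 - fz);
          long long idx = (long long)(i0 + di) +
                          (long long)G * ((j0 + dj) + (long long)G * (k0 + dk));
          acc += w * field[idx];
        }
    out[p] = acc;
  }
  return out;
}
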