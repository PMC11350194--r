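#include <Rcpp.h>
#include "kdtree.h"
using namespace Rcpp;

// Jacobi eigen-decomposition of a symmetric 3x3 matrix.
// Returns eigenvalues ascending and the eigenvector of the smallest.
static void eig3_smallest(double a[3][3], double* evec, double* evals) {
  double v[3][3] = { {1,0,0},{0,1,0},{0,0,1} };
  for (int sweep = 0; sweep < 50; ++sweep) {
    double off = std::fabs(a[0][1]) + std::fabs(a[0][2]) + std::fabs(a[1][2]);
    if (off < 1e-30) break;
    for (int p = 0; p < 2; ++p)
      for (int q = p + 1; q < 3; ++q) {
        if (std::fabs(a[p][q]) < 1e-300) continue;
        double theta = (a[q][q] - a[p][p]) / (2.0 * a[p][q]);
        double t = (theta >= 0 ? 1.0 : -1.0) /
                   (std::fabs(theta) + std::sqrt(theta * theta + 1.0));
        double c = 1.0 / std::sqrt(t * t + 1.0), s = t * c;
        for (int k = 0; k < 3; ++k) {
          double akp = a[k][p], akq = a[k][q];
          a[k][p] = c * akp - s * akq;
          a[k][q] = s * akp + c * akq;
        }
        for (int k = 0; k < 3; ++k) {
          double apk = a[p][k], aqk = a[q][k];
          a[p][k] = c * apk - s * aqk;
          a[q][k] = s * apk + c * aqk;
        }
        for (int k = 0; k < 3; ++k) {
          double vkp = v[k][p], vkq = v[k][q];
          v[k][p] = c * vkp - s * vkq;
          v[k][q] = s * vkp + c * vkq;
        }
      }
  }
  int order[3] = {0, 1, 2};
  double d[3] = { a[0][0], a[1][1], a[2][2] };
  for (int i = 0; i < 2; ++i)
    for (int j = i + 1; j < 3; ++j)
      if (d[order[j]] < d[order[i]]) std::swap(order[i], order[j]);
  for (int i = 0; i < 3; ++i) evals[i] = d[order[i]];
  for (int k = 0; k < 3; ++k) evec[k] = v[k][order[0]];
}

// Per-point PCA normals: covariance of the k nearest neighbours (excluding
// the point itself), smallest-eigenvalue eigenvector, arbitrary sign.
// reliable[i] is FALSE when the neighbourhood is rank-deficient (middle
// eigenvalue negligible relative to the largest).
// [[Rcpp::export]]
List cpp_pca_normals(NumericMatrix pts, int k) {
  int n = pts.nrow();
  if (n <= k) stop("need more than k points");
  std::vector<double> p(3 * n);
  for (int i = 0; i < n; ++i)
    for (int a = 0; a < 3; ++a) p[3 * i + a] = pts(i, a);
  KDTree tree(p.data(), n);
  NumericMatrix nrm(n, 3);
  LogicalVector reliable(n);
  std::vector<int> ii(k);
  std::vector<double> dd(k);
  for (int i = 0; i < n; ++i) {
    tree.knn(p.data() + 3 * i, k, i, ii.data(), dd.data());
    double mean[3] = {0, 0, 0};
    for (int j = 0; j < k; ++j)
      for (int a = 0; a < 3; ++a) mean[a] += p[3 * ii[j] + a];
    for (int a = 0; a < 3; ++a) mean[a] /= k;
    double cov[3][3] = { {0,0,0},{0,0,0},{0,0,0} };
    for (int j = 0; j < k; ++j) {
      double d0 = p[3 * ii[j]] - mean[0];
      double d1 = p[3 * ii[j] + 1] - mean[1];
      double d2 = p[3 * ii[j] + 2] - mean[2];
      cov[0][0] += d0 * d0; cov[0][1] += d0 * d1; cov[0][2] += d0 * d2;
      cov[1][1] += d1 * d1; cov[1][2] += d1 * d2; cov[2][2] += d2 * d2;
    }
    cov[1][0] = cov[0][1]; cov[2][0] = cov[0][2]; cov[2][1] = cov[1][2];
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b) cov[a][b] /= k;
    double evec[3], evals[3];
    eig3_smallest(cov, evec, evals);
    double len = std::sqrt(evec[0]*evec[0] + evec[1]*evec[1] + evec[2]*evec[2]);
    for (int a = 0; a < 3; ++a) nrm(i, a) = evec[a] / len;
    reliable[i] = evals[2] > 0 && evals[1] > 1e-9 * evals[2];
  }
  return List::create(_["normals"] = nrm, _["reliable"] = reliable);
}
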