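// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <vector>
#include <cmath>

// Bandwidth-controlled curvature energy: for each vertex, a Gaussian-weighted
// least-squares quadric is fitted over all vertices within the kernel support
// in a local tangent frame, and the per-vertex energy is the sum of squared
// principal curvatures of that quadric at the vertex. The caller rescales the
// mesh to unit total surface area so that the bandwidth eps is dimensionless.

// [[Rcpp::export(name = ".cpp_ariadne_energy")]]
Rcpp::List cpp_ariadne_energy(const arma::mat& V, const arma::imat& F,
                              const arma::mat& VN, double eps) {
  const int nv = V.n_rows, nf = F.n_rows;
  const double cutoff = 4.0 * eps, cutoff2 = cutoff * cutoff;
  const double inv_eps2 = 1.0 / (eps * eps);

  // spatial hash grid
  arma::rowvec lo = arma::min(V, 0), hi = arma::max(V, 0);
  double cell = cutoff;
  int gx = std::max(1, (int)std::floor((hi(0) - lo(0)) / cell) + 1);
  int gy = std::max(1, (int)std::floor((hi(1) - lo(1)) / cell) + 1);
  int gz = std::max(1, (int)std::floor((hi(2) - lo(2)) / cell) + 1);
  std::vector<std::vector<int> > grid((size_t)gx * gy * gz);
  std::vector<int> cix(nv), ciy(nv), ciz(nv);
  for (int i = 0; i < nv; ++i) {
    cix[i] = std::min(gx - 1, (int)std::floor((V(i,0) - lo(0)) / cell));
    ciy[i] = std::min(gy - 1, (int)std::floor((V(i,1) - lo(1)) / cell));
    ciz[i] = std::min(gz - 1, (int)std::floor((V(i,2) - lo(2)) / cell));
    grid[(size_t)cix[i] + (size_t)gx * (ciy[i] + (size_t)gy * ciz[i])].push_back(i);
  }

  arma::vec energy(nv, arma::fill::zeros);
  arma::ivec nNeigh(nv, arma::fill::zeros);

  std::vector<int> neigh;
  arma::mat A;
  arma::vec b, w;

  for (int i = 0; i < nv; ++i) {
    neigh.clear();
    for (int dx = -1; dx <= 1; ++dx) {
      int x = cix[i] + dx; if (x < 0 || x >= gx) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        int y = ciy[i] + dy; if (y < 0 || y >= gy) continue;
        for (int dz = -1; dz <= 1; ++dz) {
          int z = ciz[i] + dz; if (z < 0 || z >= gz) continue;
          const std::vector<int>& cellv = grid[(size_t)x + (size_t)gx * (y + (size_t)gy * z)];
          for (size_t k = 0; k < cellv.size(); ++k) {
            int j = cellv[k];
            double ddx = V(j,0)-V(i,0), ddy = V(j,1)-V(i,1), ddz = V(j,2)-V(i,2);
            if (ddx*ddx + ddy*ddy + ddz*ddz <= cutoff2) neigh.push_back(j);
          }
        }
      }
    }
    int m = (int)neigh.size();
    nNeigh(i) = m;
    if (m < 6) {
      energy(i) = arma::datum::nan; // flagged; caller raises a bandwidth error
      continue;
    }
    // local frame: normal as w-axis
    arma::vec3 nrm = VN.row(i).t();
    double nl = arma::norm(nrm);
    if (nl < 1e-300) { energy(i) = arma::datum::nan; continue; }
    nrm /= nl;
    arma::vec3 t1;
    if (std::fabs(nrm(0)) < 0.9) { t1 = {1.0, 0.0, 0.0}; } else { t1 = {0.0, 1.0, 0.0}; }
    t1 = t1 - arma::dot(t1, nrm) * nrm;
    t1 /= arma::norm(t1);
    arma::vec3 t2 = arma::cross(nrm, t1);

    A.set_size(m, 6);
    b.set_size(m);
    w.set_size(m);
    for (int k = 0; k < m; ++k) {
      int j = neigh[k];
      arma::vec3 d = {V(j,0)-V(i,0), V(j,1)-V(i,1), V(j,2)-V(i,2)};
      double x = arma::dot(d, t1), y = arma::dot(d, t2), z = arma::dot(d, nrm);
      double r2 = arma::dot(d, d);
      double wk = std::exp(-r2 * inv_eps2);
      A(k,0) = x*x; A(k,1) = x*y; A(k,2) = y*y; A(k,3) = x; A(k,4) = y; A(k,5) = 1.0;
      b(k) = z;
      w(k) = wk;
    }
    arma::mat Aw = A.each_col() % w;
    arma::mat AtA = A.t() * Aw;
    arma::vec Atb = Aw.t() * b;
    arma::vec coef;
    bool ok = arma::solve(coef, AtA, Atb, arma::solve_opts::likely_sympd + arma::solve_opts::no_approx);
    if (!ok) {
      ok = arma::solve(coef, AtA + 1e-12 * arma::eye(6,6), Atb);
      if (!ok) { energy(i) = arma::datum::nan; continue; }
    }
    double a = coef(0), bb = coef(1), c = coef(2), d1 = coef(3), e1 = coef(4);
    // fundamental forms of z = a x^2 + b xy + c y^2 + d x + e y + f at (0,0)
    double E = 1.0 + d1*d1, Fm = d1*e1, G = 1.0 + e1*e1;
    double s = std::sqrt(1.0 + d1*d1 + e1*e1);
    double L = 2.0*a/s, M = bb/s, N = 2.0*c/s;
    double det1 = E*G - Fm*Fm;
    if (det1 < 1e-300) { energy(i) = arma::datum::nan; continue; }
    // shape operator S = I^-1 II
    double s11 = ( G*L - Fm*M) / det1, s12 = ( G*M - Fm*N) / det1;
    double s21 = (-Fm*L + E*M) / det1, s22 = (-Fm*M + E*N) / det1;
    double tr = s11 + s22, dt = s11*s22 - s12*s21;
    energy(i) = tr*tr - 2.0*dt; // k1^2 + k2^2
    if (energy(i) < 0 && energy(i) > -1e-12) energy(i) = 0.0;
  }

  // barycentric vertex areas
  arma::vec varea(nv, arma::fill::zeros);
  for (int f = 0; f < nf; ++f) {
    int a = F(f,0), bb = F(f,1), c = F(f,2);
    arma::vec3 u = {V(bb,0)-V(a,0), V(bb,1)-V(a,1), V(bb,2)-V(a,2)};
    arma::vec3 v = {V(c,0)-V(a,0), V(c,1)-V(a,1), V(c,2)-V(a,2)};
    double ar = 0.5 * arma::norm(arma::cross(u, v));
    varea(a) += ar / 3.0; varea(bb) += ar / 3.0; varea(c) += ar / 3.0;
  }

  return Rcpp::List::create(Rcpp::Named("energy") = energy,
                            Rcpp::Named("vertex_area") = varea,
                            Rcpp::Named("n_neighbours") = nNeigh);
}
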