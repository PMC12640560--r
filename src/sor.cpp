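#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Finite-difference solve of div(sigma grad phi) = 0 on a regular isotropic
// grid (spacing h, mm; sigma S/m), successive over-relaxation.
//
// Cell roles (array `fixed`): -1 free, -2 excluded (electrode interior,
// sigma irrelevant, no flux), k >= 0 Dirichlet cell held at values[k].
//
// Face conductances (units: mA/V with mm and S/m):
//   free-free      g = 2 sa sb / (sa + sb) * h   (harmonic mean)
//   free-Dirichlet g = 2 s_free * h              (metal face at half cell)
//   any-excluded   g = 0
// Outer boundary faces of free cells:
//   boundary = 0 (radiation): g = s_i h^2 / r_face, r_face = distance from
//     the source centroid to the face centre -- transparent to a 1/r field,
//     i.e. ground at infinity;
//   boundary = 1 (hard ground): g = 2 s_i h to a 0 V wall.

struct Grid {
  int nx, ny, nz;
  inline int id(int i, int j, int k) const { return i + nx * (j + ny * k); }
};

// [[Rcpp::export]]
List sor_solve(NumericVector sigma, IntegerVector fixed, NumericVector values,
               IntegerVector dims, double h, NumericVector origin,
               NumericVector source_center, int boundary,
               double omega, double tol, int max_iter) {
  Grid g{dims[0], dims[1], dims[2]};
  const int n = g.nx * g.ny * g.nz;
  std::vector<double> phi(n, 0.0);
  std::vector<float> gxp(n, 0.0f), gyp(n, 0.0f), gzp(n, 0.0f), gb(n, 0.0f);

  double vscale = 0.0;
  for (int c = 0; c < n; ++c)
    if (fixed[c] >= 0) {
      phi[c] = values[fixed[c]];
      if (std::fabs(phi[c]) > vscale) vscale = std::fabs(phi[c]);
    }
  if (vscale == 0.0) vscale = 1.0;

  auto cond = [&](int a, int b) -> double {
    if (fixed[a] == -2 || fixed[b] == -2) return 0.0;
    if (fixed[a] >= 0 && fixed[b] >= 0) return 0.0; // metal-metal: no tissue flux
    if (fixed[a] >= 0) return 2.0 * sigma[b] * h;
    if (fixed[b] >= 0) return 2.0 * sigma[a] * h;
    double sa = sigma[a], sb = sigma[b];
    if (sa <= 0.0 || sb <= 0.0) return 0.0;
    return 2.0 * sa * sb / (sa + sb) * h;
  };

  // precompute +x, +y, +z face conductances and boundary conductance
  for (int k = 0; k < g.nz; ++k)
    for (int j = 0; j < g.ny; ++j)
      for (int i = 0; i < g.nx; ++i) {
        int c = g.id(i, j, k);
        if (i + 1 < g.nx) gxp[c] = (float)cond(c, g.id(i + 1, j, k));
        if (j + 1 < g.ny) gyp[c] = (float)cond(c, g.id(i, j + 1, k));
        if (k + 1 < g.nz) gzp[c] = (float)cond(c, g.id(i, j, k + 1));
        if (fixed[c] != -1) continue;
        double si = sigma[c];
        double x = origin[0] + i * h, y = origin[1] + j * h, z = origin[2] + k * h;
        double gbc = 0.0;
        // radiation condition: for a 1/r field the outward flux density
        // through a face with unit normal n is sigma * phi * (n . rhat) / r,
        // so the face conductance to the ground at infinity is
        // sigma h^2 |dn| / r^2 with dn the normal component of (x - source)
        auto face = [&](double fx, double fy, double fz, int axis) {
          if (boundary == 1) { gbc += 2.0 * si * h; return; }
          double d[3] = {fx - source_center[0], fy - source_center[1],
                         fz - source_center[2]};
          double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
          if (r2 < h * h) r2 = h * h;
          gbc += si * h * h * std::fabs(d[axis]) / r2;
        };
        if (i == 0)          face(x - h / 2, y, z, 0);
        if (i == g.nx - 1)   face(x + h / 2, y, z, 0);
        if (j == 0)          face(x, y - h / 2, z, 1);
        if (j == g.ny - 1)   face(x, y + h / 2, z, 1);
        if (k == 0)          face(x, y, z - h / 2, 2);
        if (k == g.nz - 1)   face(x, y, z + h / 2, 2);
        gb[c] = (float)gbc;
      }

  const int nx = g.nx, nxy = g.nx * g.ny;
  double maxdelta = 0.0;
  int iter = 0;
  for (iter = 1; iter <= max_iter; ++iter) {
    maxdelta = 0.0;
    for (int k = 0; k < g.nz; ++k)
      for (int j = 0; j < g.ny; ++j) {
        int c0 = g.id(0, j, k);
        for (int i = 0; i < g.nx; ++i) {
          int c = c0 + i;
          if (fixed[c] != -1) continue;
          double num = 0.0, den = gb[c];
          if (i > 0)          { double w = gxp[c - 1];   num += w * phi[c - 1];   den += w; }
          if (i + 1 < nx)     { double w = gxp[c];       num += w * phi[c + 1];   den += w; }
          if (j > 0)          { double w = gyp[c - nx];  num += w * phi[c - nx];  den += w; }
          if (j + 1 < g.ny)   { double w = gyp[c];       num += w * phi[c + nx];  den += w; }
          if (k > 0)          { double w = gzp[c - nxy]; num += w * phi[c - nxy]; den += w; }
          if (k + 1 < g.nz)   { double w = gzp[c];       num += w * phi[c + nxy]; den += w; }
          if (den <= 0.0) continue;
          double upd = num / den;
          double nv = phi[c] + omega * (upd - phi[c]);
          double d = std::fabs(nv - phi[c]);
          if (d > maxdelta) maxdelta = d;
          phi[c] = nv;
        }
      }
    if (maxdelta < tol * vscale) break;
  }

  NumericVector out(n);
  std::copy(phi.begin(), phi.end(), out.begin());
  out.attr("dim") = dims;
  return List::create(_["potential"] = out,
                      _["iterations"] = iter,
                      _["max_delta"] = maxdelta,
                      _["converged"] = (maxdelta < tol * vscale));
}

// Net current (mA) into the tissue through each Dirichlet contact surface.
// [[Rcpp::export]]
NumericVector contact_currents(NumericVector phi, NumericVector sigma,
                               IntegerVector fixed, IntegerVector dims,
                               double h, int ncontacts) {
  Grid g{dims[0], dims[1], dims[2]};
  NumericVector cur(ncontacts);
  auto add = [&](int c, int nb) {
    int id = fixed[c];
    if (id < 0 || fixed[nb] != -1) return;
    double w = 2.0 * sigma[nb] * h;
    cur[id] += w * (phi[c] - phi[nb]);
  };
  for (int k = 0; k < g.nz; ++k)
    for (int j = 0; j < g.ny; ++j)
      for (int i = 0; i < g.nx; ++i) {
        int c = g.id(i, j, k);
        if (fixed[c] < 0) continue;
        if (i > 0)        add(c, g.id(i - 1, j, k));
        if (i + 1 < g.nx) add(c, g.id(i + 1, j, k));
        if (j > 0)        add(c, g.id(i, j - 1, k));
        if (j + 1 < g.ny) add(c, g.id(i, j + 1, k));
        if (k > 0)        add(c, g.id(i, j, k - 1));
        if (k + 1 < g.nz) add(c, g.id(i, j, k + 1));
      }
  return cur;
}

// 26-connected flood fill of `mask` from `seeds` (1-based linear indices).
// [[Rcpp::export]]
LogicalVector flood26(LogicalVector mask, IntegerVector dims,
                      IntegerVector seeds) {
  Grid g{dims[0], dims[1], dims[2]};
  const int n = g.nx * g.ny * g.nz;
  LogicalVector out(n);
  out.attr("dim") = dims;
  std::vector<int> stack;
  for (int s : seeds) {
    int c = s - 1;
    if (c >= 0 && c < n && mask[c] && !out[c]) { out[c] = true; stack.push_back(c); }
  }
  while (!stack.empty()) {
    int c = stack.back(); stack.pop_back();
    int k = c / (g.nx * g.ny), rem = c % (g.nx * g.ny);
    int j = rem / g.nx, i = rem % g.nx;
    for (int dk = -1; dk <= 1; ++dk)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          if (di == 0 && dj == 0 && dk == 0) continue;
          int ii = i + di, jj = j + dj, kk = k + dk;
          if (ii < 0 || ii >= g.nx || jj < 0 || jj >= g.ny ||
              kk < 0 || kk >= g.nz) continue;
          int nb = g.id(ii, jj, kk);
          if (mask[nb] && !out[nb]) { out[nb] = true; stack.push_back(nb); }
        }
  }
  return out;
}
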