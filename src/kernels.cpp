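#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Minimal heavy-atom distance between every residue of chain A and every
// residue of chain B. coords are n x 3; res gives the 1-based residue index
// of each atom. Residues without atoms come back as Inf (masked upstream).
// [[Rcpp::export]]
NumericMatrix cpp_min_dist_map(NumericMatrix ca, IntegerVector ra, int La,
                               NumericMatrix cb, IntegerVector rb, int Lb) {
  NumericMatrix out(La, Lb);
  std::fill(out.begin(), out.end(), R_PosInf);
  const int na = ca.nrow(), nb = cb.nrow();
  for (int i = 0; i < na; ++i) {
    const double xi = ca(i, 0), yi = ca(i, 1), zi = ca(i, 2);
    const int ri = ra[i] - 1;
    for (int j = 0; j < nb; ++j) {
      const double dx = xi - cb(j, 0), dy = yi - cb(j, 1), dz = zi - cb(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      const int rj = rb[j] - 1;
      if (d2 < out(ri, rj)) out(ri, rj) = d2;
    }
  }
  for (R_xlen_t k = 0; k < out.size(); ++k)
    if (R_finite(out[k])) out[k] = std::sqrt(out[k]);
  return out;
}

// Union of inter-chain contact maps over many rigid-body translations of a
// pre-rotated second copy. Residue-centroid prefilter keeps the atom loops
// rare. Returns an L x L logical matrix.
// [[Rcpp::export]]
LogicalMatrix cpp_union_pose_contacts(NumericMatrix ca, IntegerVector ra,
                                      NumericMatrix cb, IntegerVector rb,
                                      int L, NumericMatrix trans,
                                      double cutoff) {
  LogicalMatrix out(L, L);
  const int na = ca.nrow(), nb = cb.nrow(), np = trans.nrow();
  std::vector<std::vector<int> > ga(L), gb(L);
  for (int i = 0; i < na; ++i) ga[ra[i] - 1].push_back(i);
  for (int j = 0; j < nb; ++j) gb[rb[j] - 1].push_back(j);

  // centroids and bounding radii per residue
  std::vector<double> cax(L), cay(L), caz(L), rad_a(L, 0.0);
  std::vector<double> cbx(L), cby(L), cbz(L), rad_b(L, 0.0);
  for (int r = 0; r < L; ++r) {
    double sx = 0, sy = 0, sz = 0;
    for (size_t k = 0; k < ga[r].size(); ++k) {
      sx += ca(ga[r][k], 0); sy += ca(ga[r][k], 1); sz += ca(ga[r][k], 2);
    }
    const int n = ga[r].size();
    if (n > 0) { cax[r] = sx / n; cay[r] = sy / n; caz[r] = sz / n; }
    for (size_t k = 0; k < ga[r].size(); ++k) {
      const double dx = ca(ga[r][k], 0) - cax[r], dy = ca(ga[r][k], 1) - cay[r],
                   dz = ca(ga[r][k], 2) - caz[r];
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d > rad_a[r]) rad_a[r] = d;
    }
    sx = sy = sz = 0;
    for (size_t k = 0; k < gb[r].size(); ++k) {
      sx += cb(gb[r][k], 0); sy += cb(gb[r][k], 1); sz += cb(gb[r][k], 2);
    }
    const int m = gb[r].size();
    if (m > 0) { cbx[r] = sx / m; cby[r] = sy / m; cbz[r] = sz / m; }
    for (size_t k = 0; k < gb[r].size(); ++k) {
      const double dx = cb(gb[r][k], 0) - cbx[r], dy = cb(gb[r][k], 1) - cby[r],
                   dz = cb(gb[r][k], 2) - cbz[r];
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d > rad_b[r]) rad_b[r] = d;
    }
  }

  const double c2 = cutoff * cutoff;
  for (int p = 0; p < np; ++p) {
    const double tx = trans(p, 0), ty = trans(p, 1), tz = trans(p, 2);
    for (int i = 0; i < L; ++i) {
      if (ga[i].empty()) continue;
      for (int j = 0; j < L; ++j) {
        if (out(i, j) || gb[j].empty()) continue;
        const double dx = cax[i] - (cbx[j] + tx);
        const double dy = cay[i] - (cby[j] + ty);
        const double dz = caz[i] - (cbz[j] + tz);
        const double lim = cutoff + rad_a[i] + rad_b[j];
        if (dx * dx + dy * dy + dz * dz > lim * lim) continue;
        bool hit = false;
        for (size_t u = 0; u < ga[i].size() && !hit; ++u) {
          const double ax = ca(ga[i][u], 0), ay = ca(ga[i][u], 1),
                       az = ca(ga[i][u], 2);
          for (size_t v = 0; v < gb[j].size(); ++v) {
            const double bx = cb(gb[j][v], 0) + tx, by = cb(gb[j][v], 1) + ty,
                         bz = cb(gb[j][v], 2) + tz;
            const double ex = ax - bx, ey = ay - by, ez = az - bz;
            if (ex * ex + ey * ey + ez * ez <= c2) { hit = true; break; }
          }
        }
        if (hit) out(i, j) = true;
      }
    }
  }
  return out;
}

// Discretise a set of atom coordinates onto a cubic grid.
// Label 2 = core (within fill_radius of an atom centre),
// label 1 = surface (within fill_radius + surf_thickness, not core),
// label 0 = empty. Returned as an integer vector with dim attribute.
// [[Rcpp::export]]
IntegerVector cpp_fill_grid(NumericMatrix coords, IntegerVector dims,
                            NumericVector origin, double spacing,
                            double fill_radius, double surf_thickness) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector lab(nx * ny * nz);
  const double rout = fill_radius + surf_thickness;
  const double r2in = fill_radius * fill_radius, r2out = rout * rout;
  const int reach = (int)std::ceil(rout / spacing);
  const int n = coords.nrow();
  for (int a = 0; a < n; ++a) {
    const double x = coords(a, 0), y = coords(a, 1), z = coords(a, 2);
    const int ix = (int)std::floor((x - origin[0]) / spacing + 0.5);
    const int iy = (int)std::floor((y - origin[1]) / spacing + 0.5);
    const int iz = (int)std::floor((z - origin[2]) / spacing + 0.5);
    for (int dx = -reach; dx <= reach; ++dx) {
      const int cx = ix + dx;
      if (cx < 0 || cx >= nx) continue;
      const double ex = origin[0] + cx * spacing - x;
      for (int dy = -reach; dy <= reach; ++dy) {
        const int cy = iy + dy;
        if (cy < 0 || cy >= ny) continue;
        const double ey = origin[1] + cy * spacing - y;
        for (int dz = -reach; dz <= reach; ++dz) {
          const int cz = iz + dz;
          if (cz < 0 || cz >= nz) continue;
          const double ez = origin[2] + cz * spacing - z;
          const double d2 = ex * ex + ey * ey + ez * ez;
          if (d2 > r2out) continue;
          const int idx = cx + nx * (cy + ny * cz);
          if (d2 <= r2in) lab[idx] = 2;
          else if (lab[idx] == 0) lab[idx] = 1;
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}
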