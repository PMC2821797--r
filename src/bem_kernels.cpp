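#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Analytic potential integrals for linear-collocation BEM.
//
// For an observation point x and a triangle (y1,y2,y3) the double-layer
// integral of a linearly interpolated potential over the triangle,
//   \int_T N_k(y) dOmega_x(y),  k = 1..3,
// has a closed form built from the van Oosterom & Strackee triangle solid
// angle and edge logarithms (de Munck's linear potential coefficients).
// omega_k below are those three weights; they sum to the triangle's solid
// angle seen from x.

static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

// beta factor for the edge a -> b as seen from the observation point
static inline double calc_beta(const double* va, double la,
                               const double* vb, double lb) {
  double e[3] = {vb[0] - va[0], vb[1] - va[1], vb[2] - va[2]};
  double len = std::sqrt(dot3(e, e));
  e[0] /= len; e[1] /= len; e[2] /= len;
  double num = la + dot3(va, e);
  double den = lb + dot3(vb, e);
  return std::log(num / den) / len;
}

// Linear solid-angle weights of one triangle for one observation point.
// y: 3x3 vertex coords (rows y1,y2,y3), nn unit normal, area triangle area.
static void lin_pot_weights(const double* x, const double y[3][3],
                            const double* nn, double area, double* omega) {
  double v1[3], v2[3], v3[3];
  for (int c = 0; c < 3; ++c) {
    v1[c] = y[0][c] - x[c];
    v2[c] = y[1][c] - x[c];
    v3[c] = y[2][c] - x[c];
  }
  double c23[3];
  cross3(v2, v3, c23);
  double triple = dot3(v1, c23);
  double l1 = std::sqrt(dot3(v1, v1));
  double l2 = std::sqrt(dot3(v2, v2));
  double l3 = std::sqrt(dot3(v3, v3));
  double ss = l1 * l2 * l3 + dot3(v1, v2) * l3 + dot3(v1, v3) * l2 +
              dot3(v2, v3) * l1;
  double solid = 2.0 * std::atan2(triple, ss);
  if (std::fabs(solid) < M_PI / 1e6) {
    omega[0] = omega[1] = omega[2] = 0.0;
    return;
  }
  double b12 = calc_beta(v1, l1, v2, l2);
  double b23 = calc_beta(v2, l2, v3, l3);
  double b31 = calc_beta(v3, l3, v1, l1);
  double vecw[3];
  for (int c = 0; c < 3; ++c)
    vecw[c] = (b31 - b12) * v1[c] + (b12 - b23) * v2[c] + (b23 - b31) * v3[c];
  double area2 = 2.0 * area;
  double n2 = 1.0 / (area2 * area2);
  const double* vv[3] = {v1, v2, v3};
  // cyclic: for k, zdot = (v_{k+1} x v_{k+2}) . n, diff = v_{k+2} - v_{k+1}
  for (int k = 0; k < 3; ++k) {
    int ka = (k + 1) % 3, kb = (k + 2) % 3;
    double cx[3];
    cross3(vv[ka], vv[kb], cx);
    double zdot = dot3(cx, nn);
    double diff[3] = {vv[kb][0] - vv[ka][0], vv[kb][1] - vv[ka][1],
                      vv[kb][2] - vv[ka][2]};
    omega[k] = -n2 * (area2 * zdot * solid - triple * dot3(diff, vecw));
  }
}

// [[Rcpp::export(name = ".bem_lin_pot_coeff")]]
NumericMatrix bem_lin_pot_coeff(NumericMatrix rr, IntegerMatrix tris,
                                IntegerVector tri_surf,
                                IntegerVector vert_surf) {
  int n = rr.nrow(), m = tris.nrow();
  NumericMatrix coeff(n, n);
  std::vector<double> xs(3 * n);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) xs[3 * i + c] = rr(i, c);

  for (int t = 0; t < m; ++t) {
    int a = tris(t, 0), b = tris(t, 1), cidx = tris(t, 2);
    double y[3][3];
    for (int c = 0; c < 3; ++c) {
      y[0][c] = rr(a, c);
      y[1][c] = rr(b, c);
      y[2][c] = rr(cidx, c);
    }
    double e1[3] = {y[1][0] - y[0][0], y[1][1] - y[0][1], y[1][2] - y[0][2]};
    double e2[3] = {y[2][0] - y[0][0], y[2][1] - y[0][1], y[2][2] - y[0][2]};
    double nn[3];
    cross3(e1, e2, nn);
    double n2l = std::sqrt(dot3(nn, nn));
    double area = 0.5 * n2l;
    nn[0] /= n2l; nn[1] /= n2l; nn[2] /= n2l;
    int ts = tri_surf[t];
    double om[3];
    for (int i = 0; i < n; ++i) {
      if (vert_surf[i] == ts && (i == a || i == b || i == cidx)) continue;
      lin_pot_weights(&xs[3 * i], y, nn, area, om);
      coeff(i, a) -= om[0];
      coeff(i, b) -= om[1];
      coeff(i, cidx) -= om[2];
    }
  }
  return coeff;
}

// Improve the auto (same-surface) elements: the self solid angle of the
// tangent plane is 2*pi; the deficit of each row within its own surface is
// assigned half to the vertex itself and the rest spread over the other
// vertices of the triangles meeting at it.
// [[Rcpp::export(name = ".bem_correct_auto")]]
void bem_correct_auto(NumericMatrix coeff, IntegerMatrix tris,
                      IntegerVector tri_surf, IntegerVector vert_surf,
                      IntegerVector surf_offsets) {
  int n = coeff.nrow(), m = tris.nrow();
  int nsurf = surf_offsets.size() - 1;
  // adjacency: triangles per vertex
  std::vector<std::vector<int> > vtris(n);
  for (int t = 0; t < m; ++t)
    for (int k = 0; k < 3; ++k) vtris[tris(t, k)].push_back(t);

  for (int s = 0; s < nsurf; ++s) {
    int lo = surf_offsets[s], hi = surf_offsets[s + 1];
    for (int j = lo; j < hi; ++j) {
      double rowsum = 0.0;
      for (int k = lo; k < hi; ++k) rowsum += coeff(j, k);
      double miss = 2.0 * M_PI - rowsum;
      int nmemb = (int)vtris[j].size();
      coeff(j, j) = miss / 2.0;
      double part = miss / (4.0 * nmemb);
      for (size_t q = 0; q < vtris[j].size(); ++q) {
        int t = vtris[j][q];
        for (int k = 0; k < 3; ++k) {
          int v = tris(t, k);
          if (v != j) coeff(j, v) += part;
        }
      }
    }
  }
}

// Infinite-medium dipole potentials at collocation points, scaled by the
// per-vertex source multiplier / 4 pi: one column per (source, orientation).
// pos: nsrc x 3, mom: nmom x 3 unit moments; columns ordered source-major
// within each moment block when interleave = FALSE:
//   result is n x (nsrc * nmom), column index = (imom * nsrc) + isrc.
// [[Rcpp::export(name = ".bem_inf_rhs")]]
NumericMatrix bem_inf_rhs(NumericMatrix rr, NumericVector mults,
                          NumericMatrix pos, NumericMatrix mom) {
  int n = rr.nrow(), ns = pos.nrow(), nm = mom.nrow();
  NumericMatrix out(n, ns * nm);
  for (int s = 0; s < ns; ++s) {
    double p0 = pos(s, 0), p1 = pos(s, 1), p2 = pos(s, 2);
    for (int i = 0; i < n; ++i) {
      double d0 = rr(i, 0) - p0, d1 = rr(i, 1) - p1, d2 = rr(i, 2) - p2;
      double r2 = d0 * d0 + d1 * d1 + d2 * d2;
      double ir3 = 1.0 / (r2 * std::sqrt(r2));
      double f = mults[i] * ir3 / (4.0 * M_PI);
      for (int q = 0; q < nm; ++q) {
        out(i, q * ns + s) =
            f * (mom(q, 0) * d0 + mom(q, 1) * d1 + mom(q, 2) * d2);
      }
    }
  }
  return out;
}

// Radial ray casting against a triangle mesh for star-shaped surfaces:
// for each unit direction from the origin, the largest intersection
// parameter t (distance) over all triangles; -1 when no hit.
// [[Rcpp::export(name = ".ray_mesh_radius")]]
NumericVector ray_mesh_radius(NumericMatrix dirs, NumericMatrix rr,
                              IntegerMatrix tris) {
  int nd = dirs.nrow(), m = tris.nrow();
  NumericVector out(nd, -1.0);
  std::vector<double> e1(3 * m), e2(3 * m), v0(3 * m);
  for (int t = 0; t < m; ++t) {
    int a = tris(t, 0) - 1, b = tris(t, 1) - 1, c = tris(t, 2) - 1;
    for (int k = 0; k < 3; ++k) {
      v0[3 * t + k] = rr(a, k);
      e1[3 * t + k] = rr(b, k) - rr(a, k);
      e2[3 * t + k] = rr(c, k) - rr(a, k);
    }
  }
  const double eps = 1e-12;
  for (int d = 0; d < nd; ++d) {
    double dir[3] = {dirs(d, 0), dirs(d, 1), dirs(d, 2)};
    double best = -1.0;
    for (int t = 0; t < m; ++t) {
      const double* E1 = &e1[3 * t];
      const double* E2 = &e2[3 * t];
      const double* V0 = &v0[3 * t];
      double pv[3];
      cross3(dir, E2, pv);
      double det = dot3(E1, pv);
      if (std::fabs(det) < eps) continue;
      double inv = 1.0 / det;
      double tv[3] = {-V0[0], -V0[1], -V0[2]};
      double u = dot3(tv, pv) * inv;
      if (u < -1e-9 || u > 1.0 + 1e-9) continue;
      double qv[3];
      cross3(tv, E1, qv);
      double v = dot3(dir, qv) * inv;
      if (v < -1e-9 || u + v > 1.0 + 1e-9) continue;
      double tt = dot3(E2, qv) * inv;
      if (tt > best) best = tt;
    }
    out[d] = best;
  }
  return out;
}

// Radial ray cast returning the outermost hit with triangle id and
// barycentric coordinates: columns (t, tri_index_1based, w0, w1, w2).
// [[Rcpp::export(name = ".ray_mesh_hit")]]
NumericMatrix ray_mesh_hit(NumericMatrix dirs, NumericMatrix rr,
                           IntegerMatrix tris) {
  int nd = dirs.nrow(), m = tris.nrow();
  NumericMatrix out(nd, 5);
  const double eps = 1e-12;
  for (int d = 0; d < nd; ++d) {
    double dir[3] = {dirs(d, 0), dirs(d, 1), dirs(d, 2)};
    double best = -1.0;
    int bt = -1;
    double bu = 0, bv = 0;
    for (int t = 0; t < m; ++t) {
      int a = tris(t, 0) - 1, b = tris(t, 1) - 1, c = tris(t, 2) - 1;
      double E1[3], E2[3], V0[3];
      for (int k = 0; k < 3; ++k) {
        V0[k] = rr(a, k);
        E1[k] = rr(b, k) - rr(a, k);
        E2[k] = rr(c, k) - rr(a, k);
      }
      double pv[3];
      cross3(dir, E2, pv);
      double det = dot3(E1, pv);
      if (std::fabs(det) < eps) continue;
      double inv = 1.0 / det;
      double tv[3] = {-V0[0], -V0[1], -V0[2]};
      double u = dot3(tv, pv) * inv;
      if (u < -1e-9 || u > 1.0 + 1e-9) continue;
      double qv[3];
      cross3(tv, E1, qv);
      double v = dot3(dir, qv) * inv;
      if (v < -1e-9 || u + v > 1.0 + 1e-9) continue;
      double tt = dot3(E2, qv) * inv;
      if (tt > best) { best = tt; bt = t; bu = u; bv = v; }
    }
    out(d, 0) = best;
    out(d, 1) = bt + 1;
    out(d, 2) = 1.0 - bu - bv;
    out(d, 3) = bu;
    out(d, 4) = bv;
  }
  return out;
}
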