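#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

// Finite-difference volume conductor: conservative 7-point stencil with
// harmonic-mean face conductances on a regular voxel grid,
//   (A v)_i = sum_faces g_f (v_i - v_j),  g_f = h * 2 s_i s_j / (s_i + s_j),
// homogeneous Neumann at the conductor/air boundary (absent faces).

static inline double face_g(double s1, double s2, double h) {
  if (s1 <= 0.0 || s2 <= 0.0) return 0.0;
  return h * 2.0 * s1 * s2 / (s1 + s2);
}

struct Grid {
  int nx, ny, nz;
  inline int idx(int i, int j, int k) const { return i + nx * (j + ny * k); }
};

// Conductive connected components (6-connectivity). Returns component id per
// voxel (0 = non-conductive, 1..ncomp), largest first.
// [[Rcpp::export(name = ".fdm_components")]]
IntegerVector fdm_components(IntegerVector labels, IntegerVector dims,
                             NumericVector sigma) {
  Grid g{dims[0], dims[1], dims[2]};
  int n = g.nx * g.ny * g.nz;
  IntegerVector comp(n, 0);
  std::vector<int> sizes;
  int cur = 0;
  for (int start = 0; start < n; ++start) {
    if (comp[start] != 0 || sigma[labels[start]] <= 0.0) continue;
    ++cur;
    sizes.push_back(0);
    std::queue<int> q;
    q.push(start);
    comp[start] = cur;
    while (!q.empty()) {
      int v = q.front(); q.pop();
      ++sizes[cur - 1];
      int k = v / (g.nx * g.ny), rem = v % (g.nx * g.ny);
      int j = rem / g.nx, i = rem % g.nx;
      const int di[6] = {1, -1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, 1, -1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, 1, -1};
      for (int t = 0; t < 6; ++t) {
        int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
        if (ii < 0 || ii >= g.nx || jj < 0 || jj >= g.ny || kk < 0 || kk >= g.nz)
          continue;
        int w = g.idx(ii, jj, kk);
        if (comp[w] == 0 && sigma[labels[w]] > 0.0) {
          comp[w] = cur;
          q.push(w);
        }
      }
    }
  }
  // relabel so component 1 is the largest
  if (cur > 1) {
    std::vector<int> order(cur);
    for (int c = 0; c < cur; ++c) order[c] = c;
    std::sort(order.begin(), order.end(),
              [&](int a, int b) { return sizes[a] > sizes[b]; });
    std::vector<int> remap(cur + 1, 0);
    for (int r = 0; r < cur; ++r) remap[order[r] + 1] = r + 1;
    for (int v = 0; v < n; ++v) comp[v] = remap[comp[v]];
  }
  comp.attr("sizes") = wrap(sizes);
  return comp;
}

struct Faces {
  std::vector<double> gx, gy, gz, diag;
};

static void build_faces(const IntegerVector& labels, const Grid& g,
                        const NumericVector& sigma, double h, Faces& f) {
  int n = g.nx * g.ny * g.nz;
  f.gx.assign(n, 0.0); f.gy.assign(n, 0.0); f.gz.assign(n, 0.0);
  f.diag.assign(n, 0.0);
  for (int k = 0; k < g.nz; ++k)
    for (int j = 0; j < g.ny; ++j)
      for (int i = 0; i < g.nx; ++i) {
        int v = g.idx(i, j, k);
        double sv = sigma[labels[v]];
        if (sv <= 0.0) continue;
        if (i + 1 < g.nx) {
          double gg = face_g(sv, sigma[labels[g.idx(i + 1, j, k)]], h);
          f.gx[v] = gg;
          f.diag[v] += gg;
          f.diag[g.idx(i + 1, j, k)] += gg;
        }
        if (j + 1 < g.ny) {
          double gg = face_g(sv, sigma[labels[g.idx(i, j + 1, k)]], h);
          f.gy[v] = gg;
          f.diag[v] += gg;
          f.diag[g.idx(i, j + 1, k)] += gg;
        }
        if (k + 1 < g.nz) {
          double gg = face_g(sv, sigma[labels[g.idx(i, j, k + 1)]], h);
          f.gz[v] = gg;
          f.diag[v] += gg;
          f.diag[g.idx(i, j, k + 1)] += gg;
        }
      }
}

// One stencil row (for tests): returns the dense row of A for voxel v0.
// [[Rcpp::export(name = ".fdm_row")]]
NumericVector fdm_row(IntegerVector labels, IntegerVector dims,
                      NumericVector sigma, double h, int v0) {
  Grid g{dims[0], dims[1], dims[2]};
  Faces f;
  build_faces(labels, g, sigma, h, f);
  int n = g.nx * g.ny * g.nz;
  NumericVector row(n, 0.0);
  int k = v0 / (g.nx * g.ny), rem = v0 % (g.nx * g.ny);
  int j = rem / g.nx, i = rem % g.nx;
  row[v0] = f.diag[v0];
  if (i + 1 < g.nx) row[g.idx(i + 1, j, k)] -= f.gx[v0];
  if (i > 0) row[g.idx(i - 1, j, k)] -= f.gx[g.idx(i - 1, j, k)];
  if (j + 1 < g.ny) row[g.idx(i, j + 1, k)] -= f.gy[v0];
  if (j > 0) row[g.idx(i, j - 1, k)] -= f.gy[g.idx(i, j - 1, k)];
  if (k + 1 < g.nz) row[g.idx(i, j, k + 1)] -= f.gz[v0];
  if (k > 0) row[g.idx(i, j, k - 1)] -= f.gz[g.idx(i, j, k - 1)];
  return row;
}

// Jacobi-preconditioned conjugate gradients on the compressed set of
// conductive voxels (CSR-like neighbour lists keep the matvec tight).
// b over the full grid; ground: 0-based voxel pinned to zero potential
// (pass a conductive voxel); tol is the relative residual target.
// [[Rcpp::export(name = ".fdm_pcg")]]
List fdm_pcg(IntegerVector labels, IntegerVector dims, NumericVector sigma,
             double h, NumericVector b, int ground, double tol, int maxit) {
  Grid g{dims[0], dims[1], dims[2]};
  int n = g.nx * g.ny * g.nz;
  Faces f;
  build_faces(labels, g, sigma, h, f);
  // compress to active (conductive, non-ground) unknowns
  std::vector<int> id(n, -1), back;
  back.reserve(n);
  for (int v = 0; v < n; ++v)
    if (sigma[labels[v]] > 0.0 && v != ground) {
      id[v] = (int)back.size();
      back.push_back(v);
    }
  int na = (int)back.size();
  std::vector<int> nb(6 * (size_t)na, -1);
  std::vector<double> ng(6 * (size_t)na, 0.0), diag(na), dinv(na);
  int nxy = g.nx * g.ny;
  for (int a = 0; a < na; ++a) {
    int v = back[a];
    diag[a] = f.diag[v];
    dinv[a] = 1.0 / f.diag[v];
    const int offs[6] = {1, -1, g.nx, -g.nx, nxy, -nxy};
    double gs[6] = {f.gx[v], (v >= 1) ? f.gx[v - 1] : 0.0,
                    f.gy[v], (v >= g.nx) ? f.gy[v - g.nx] : 0.0,
                    f.gz[v], (v >= nxy) ? f.gz[v - nxy] : 0.0};
    for (int q = 0; q < 6; ++q) {
      if (gs[q] == 0.0) continue;
      int w = v + offs[q];
      if (w < 0 || w >= n || id[w] < 0) continue;  // ground or outside
      nb[6 * (size_t)a + q] = id[w];
      ng[6 * (size_t)a + q] = gs[q];
    }
  }
  std::vector<double> x(na, 0.0), r(na), z(na), p(na), ap(na);
  double bnorm = 0.0;
  for (int a = 0; a < na; ++a) {
    r[a] = b[back[a]];
    bnorm += r[a] * r[a];
  }
  bnorm = std::sqrt(bnorm);
  NumericVector xfull(n, 0.0);
  if (bnorm == 0.0)
    return List::create(_["x"] = xfull, _["iters"] = 0, _["relres"] = 0.0);
  double rz = 0.0;
  for (int a = 0; a < na; ++a) {
    z[a] = dinv[a] * r[a];
    p[a] = z[a];
    rz += r[a] * z[a];
  }
  int it = 0;
  double relres = 1.0;
  for (it = 1; it <= maxit; ++it) {
    double pap = 0.0;
    for (int a = 0; a < na; ++a) {
      const int* nbi = &nb[6 * (size_t)a];
      const double* ngi = &ng[6 * (size_t)a];
      double acc = diag[a] * p[a];
      for (int q = 0; q < 6; ++q)
        if (nbi[q] >= 0) acc -= ngi[q] * p[nbi[q]];
      ap[a] = acc;
      pap += p[a] * acc;
    }
    double alpha = rz / pap;
    double rn = 0.0;
    for (int a = 0; a < na; ++a) {
      x[a] += alpha * p[a];
      r[a] -= alpha * ap[a];
      rn += r[a] * r[a];
    }
    relres = std::sqrt(rn) / bnorm;
    if (relres < tol) break;
    double rz_new = 0.0;
    for (int a = 0; a < na; ++a) {
      z[a] = dinv[a] * r[a];
      rz_new += r[a] * z[a];
    }
    double beta = rz_new / rz;
    rz = rz_new;
    for (int a = 0; a < na; ++a) p[a] = z[a] + beta * p[a];
  }
  for (int a = 0; a < na; ++a) xfull[back[a]] = x[a];
  return List::create(_["x"] = xfull, _["iters"] = it,
                      _["relres"] = relres);
}
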