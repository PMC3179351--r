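#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// 3D voxel kernels shared by the segmentation and micro-FE stages.
// Arrays are R column-major with dims (nx, ny, nz); axis 3 is superoinferior.

static const int OFF6[6][3] = {
  {0,0,-1},{0,0,1},{0,-1,0},{0,1,0},{-1,0,0},{1,0,0}
};

struct Grid {
  int nx, ny, nz;
  Grid(IntegerVector dims) : nx(dims[0]), ny(dims[1]), nz(dims[2]) {}
  inline bool in(int x, int y, int z) const {
    return x >= 0 && x < nx && y >= 0 && y < ny && z >= 0 && z < nz;
  }
  inline R_xlen_t idx(int x, int y, int z) const {
    return (R_xlen_t)x + (R_xlen_t)nx * ((R_xlen_t)y + (R_xlen_t)ny * z);
  }
};

// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  Grid g(dims);
  R_xlen_t n = (R_xlen_t)g.nx * g.ny * g.nz;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      int x = cur % g.nx, y = (cur / g.nx) % g.ny, z = cur / ((R_xlen_t)g.nx * g.ny);
      if (connectivity == 6) {
        for (int d = 0; d < 6; ++d) {
          int xx = x + OFF6[d][0], yy = y + OFF6[d][1], zz = z + OFF6[d][2];
          if (!g.in(xx, yy, zz)) continue;
          R_xlen_t q = g.idx(xx, yy, zz);
          if (mask[q] && lab[q] == 0) { lab[q] = next; stack.push_back(q); }
        }
      } else {
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              int xx = x + dx, yy = y + dy, zz = z + dz;
              if (!g.in(xx, yy, zz)) continue;
              R_xlen_t q = g.idx(xx, yy, zz);
              if (mask[q] && lab[q] == 0) { lab[q] = next; stack.push_back(q); }
            }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// --- simple-point machinery (26-connectivity for bone, 6 for marrow) ------

// nb: 27 local occupancies, index (dx+1) + 3*(dy+1) + 9*(dz+1); center = 13.

static inline int nbi(int dx, int dy, int dz) {
  return (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
}

// number of 26-components of foreground within N26(p) \ {p}
static int fg_components26(const bool nb[27]) {
  bool seen[27] = {false};
  int comps = 0;
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !nb[i] || seen[i]) continue;
    ++comps;
    std::vector<int> st{i};
    seen[i] = true;
    while (!st.empty()) {
      int c = st.back(); st.pop_back();
      int cx = c % 3 - 1, cy = (c / 3) % 3 - 1, cz = c / 9 - 1;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int xx = cx + dx, yy = cy + dy, zz = cz + dz;
            if (xx < -1 || xx > 1 || yy < -1 || yy > 1 || zz < -1 || zz > 1)
              continue;
            int j = nbi(xx, yy, zz);
            if (j == 13 || j == c || !nb[j] || seen[j]) continue;
            seen[j] = true;
            st.push_back(j);
          }
    }
  }
  return comps;
}

// number of 6-components of background within N18(p) that touch a 6-neighbour
static int bg_components6(const bool nb[27]) {
  bool in18[27], seen[27] = {false};
  for (int i = 0; i < 27; ++i) {
    int x = i % 3 - 1, y = (i / 3) % 3 - 1, z = i / 9 - 1;
    int m = std::abs(x) + std::abs(y) + std::abs(z);
    in18[i] = (m >= 1 && m <= 2);
  }
  int comps = 0;
  for (int d = 0; d < 6; ++d) {
    int i = nbi(OFF6[d][0], OFF6[d][1], OFF6[d][2]);
    if (nb[i] || seen[i]) continue;  // background face neighbour, unseen
    ++comps;
    std::vector<int> st{i};
    seen[i] = true;
    while (!st.empty()) {
      int c = st.back(); st.pop_back();
      int cx = c % 3 - 1, cy = (c / 3) % 3 - 1, cz = c / 9 - 1;
      for (int d2 = 0; d2 < 6; ++d2) {
        int xx = cx + OFF6[d2][0], yy = cy + OFF6[d2][1], zz = cz + OFF6[d2][2];
        if (xx < -1 || xx > 1 || yy < -1 || yy > 1 || zz < -1 || zz > 1) continue;
        int j = nbi(xx, yy, zz);
        if (!in18[j] || nb[j] || seen[j]) continue;
        seen[j] = true;
        st.push_back(j);
      }
    }
  }
  return comps;
}

static inline void fill_nb(const std::vector<char> &fg, const Grid &g,
                           int x, int y, int z, bool nb[27]) {
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int xx = x + dx, yy = y + dy, zz = z + dz;
        nb[nbi(dx, dy, dz)] =
          g.in(xx, yy, zz) ? (bool)fg[g.idx(xx, yy, zz)] : false;
      }
}

static inline bool is_simple(const bool nb[27]) {
  return fg_components26(nb) == 1 && bg_components6(nb) == 1;
}

// locally one voxel thick along some axis => medial surface/curve voxel
static inline int thin_axes(const bool nb[27]) {
  int a = 0;
  if (!nb[nbi(-1,0,0)] && !nb[nbi(1,0,0)]) ++a;
  if (!nb[nbi(0,-1,0)] && !nb[nbi(0,1,0)]) ++a;
  if (!nb[nbi(0,0,-1)] && !nb[nbi(0,0,1)]) ++a;
  return a;
}

static inline int fg26_count(const bool nb[27]) {
  int n = 0;
  for (int i = 0; i < 27; ++i) if (i != 13 && nb[i]) ++n;
  return n;
}

// preserve curve end points, and medial sheet/curve voxels: thin along an
// axis with every foreground neighbour lying in that axis' mid-plane (this
// rejects the diagonal-bundle artifacts naive thinness preservation keeps)
static inline bool preserve_point(const bool nb[27]) {
  if (fg26_count(nb) <= 1) return true;
  for (int ax = 0; ax < 3; ++ax) {
    int lo = (ax == 0) ? nbi(-1,0,0) : (ax == 1) ? nbi(0,-1,0) : nbi(0,0,-1);
    int hi = (ax == 0) ? nbi(1,0,0) : (ax == 1) ? nbi(0,1,0) : nbi(0,0,1);
    if (nb[lo] || nb[hi]) continue;
    bool planar = true;
    for (int i = 0; i < 27 && planar; ++i) {
      if (i == 13 || !nb[i]) continue;
      int off = (ax == 0) ? (i % 3 - 1) : (ax == 1) ? ((i / 3) % 3 - 1)
                                        : (i / 9 - 1);
      if (off != 0) planar = false;
    }
    if (planar) return true;
  }
  return false;
}

// Surface-preserving topological thinning. Deterministic: six directional
// subiterations per pass, raster order, sequential deletion with simplicity
// re-checked at deletion time. Returns 0 background, 1 curve, 2 surface,
// 3 junction.
// [[Rcpp::export(name = ".thin_skeleton_cpp")]]
IntegerVector thin_skeleton_cpp(LogicalVector mask, IntegerVector dims,
                                int rim_passes, bool curve_only) {
  Grid g(dims);
  R_xlen_t n = (R_xlen_t)g.nx * g.ny * g.nz;
  std::vector<char> fg(n);
  for (R_xlen_t i = 0; i < n; ++i) fg[i] = mask[i] ? 1 : 0;

  bool nb[27];
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      // collect candidates border in direction d
      std::vector<R_xlen_t> cand;
      for (int z = 0; z < g.nz; ++z)
        for (int y = 0; y < g.ny; ++y)
          for (int x = 0; x < g.nx; ++x) {
            R_xlen_t i = g.idx(x, y, z);
            if (!fg[i]) continue;
            int xx = x + OFF6[d][0], yy = y + OFF6[d][1], zz = z + OFF6[d][2];
            bool bg_nb = !g.in(xx, yy, zz) || !fg[g.idx(xx, yy, zz)];
            if (bg_nb) cand.push_back(i);
          }
      for (R_xlen_t i : cand) {
        if (!fg[i]) continue;
        int x = i % g.nx, y = (i / g.nx) % g.ny, z = i / ((R_xlen_t)g.nx * g.ny);
        fill_nb(fg, g, x, y, z, nb);
        if (curve_only ? (fg26_count(nb) <= 1) : preserve_point(nb))
          continue;                             // medial sheet/curve/endpoint
        if (!is_simple(nb)) continue;           // topology would change
        fg[i] = 0;
        changed = true;
      }
    }
  }

  // rim erosion: a bounded number of passes peeling sheet rims so that
  // strut-scale ribbons collapse to curves while extended plates remain
  // sheets; curves (thin in >= 2 axes) and endpoints are protected, and
  // topology is preserved throughout
  for (int pass = 0; pass < (curve_only ? 0 : rim_passes); ++pass) {
    // snapshot the rim candidates so one pass peels exactly one ring
    std::vector<R_xlen_t> cand;
    for (int z = 0; z < g.nz; ++z)
      for (int y = 0; y < g.ny; ++y)
        for (int x = 0; x < g.nx; ++x) {
          R_xlen_t i = g.idx(x, y, z);
          if (!fg[i]) continue;
          fill_nb(fg, g, x, y, z, nb);
          if (fg26_count(nb) <= 1) continue;    // endpoint
          if (thin_axes(nb) != 1) continue;     // not a sheet voxel
          // rim: some in-plane face neighbour is background
          int nbg = 0;
          for (int d = 0; d < 6; ++d)
            if (!nb[nbi(OFF6[d][0], OFF6[d][1], OFF6[d][2])]) ++nbg;
          if (nbg <= 2) continue;               // sheet interior (normal only)
          cand.push_back(i);
        }
    bool any = false;
    for (R_xlen_t i : cand) {
      if (!fg[i]) continue;
      int x = i % g.nx, y = (i / g.nx) % g.ny, z = i / ((R_xlen_t)g.nx * g.ny);
      fill_nb(fg, g, x, y, z, nb);
      if (fg26_count(nb) <= 1 || thin_axes(nb) != 1) continue;
      if (!is_simple(nb)) continue;
      fg[i] = 0;
      any = true;
    }
    if (!any) break;
  }

  IntegerVector out(n, 0);
  for (int z = 0; z < g.nz; ++z)
    for (int y = 0; y < g.ny; ++y)
      for (int x = 0; x < g.nx; ++x) {
        R_xlen_t i = g.idx(x, y, z);
        if (!fg[i]) continue;
        fill_nb(fg, g, x, y, z, nb);
        if (curve_only) {
          // one-voxel curves: classify by neighbour count
          out[i] = (fg26_count(nb) >= 3) ? 3 : 1;
        } else {
          int a = thin_axes(nb);
          int c = fg_components26(nb);
          if (c >= 3 || a == 0) out[i] = 3;      // junction
          else if (a >= 2) out[i] = 1;           // curve
          else out[i] = 2;                       // surface
        }
      }
  out.attr("dim") = dims;
  return out;
}

// Distance-ordered (level-synchronous BFS, 26-connectivity) region growing
// from labelled seeds over a mask; ties resolved to the lower label.
// [[Rcpp::export(name = ".grow_regions_cpp")]]
IntegerVector grow_regions_cpp(IntegerVector seeds, LogicalVector mask,
                               IntegerVector dims) {
  Grid g(dims);
  R_xlen_t n = (R_xlen_t)g.nx * g.ny * g.nz;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> frontier;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (seeds[i] > 0 && mask[i]) { lab[i] = seeds[i]; frontier.push_back(i); }
  }
  std::vector<R_xlen_t> touched;
  std::vector<int> best(n, 0);
  while (!frontier.empty()) {
    touched.clear();
    for (R_xlen_t i : frontier) {
      int x = i % g.nx, y = (i / g.nx) % g.ny, z = i / ((R_xlen_t)g.nx * g.ny);
      int l = lab[i];
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (!g.in(xx, yy, zz)) continue;
            R_xlen_t q = g.idx(xx, yy, zz);
            if (!mask[q] || lab[q] != 0) continue;
            if (best[q] == 0) { best[q] = l; touched.push_back(q); }
            else if (l < best[q]) best[q] = l;
          }
    }
    frontier.clear();
    for (R_xlen_t q : touched) {
      lab[q] = best[q];
      best[q] = 0;
      frontier.push_back(q);
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// --- matrix-free hexahedral FE --------------------------------------------

// y = K x, element-by-element; elems is nel x 8 (0-based compact node ids),
// per-element stiffness = ke[matid] * escale.
static void matvec(const IntegerMatrix &elems, const NumericVector &escale,
                   const IntegerVector &matid,
                   const std::vector<const double*> &kes,
                   const double *x, double *y, R_xlen_t ndof) {
  for (R_xlen_t i = 0; i < ndof; ++i) y[i] = 0.0;
  int nel = elems.nrow();
  double xe[24], ye[24];
  for (int e = 0; e < nel; ++e) {
    const double *ke = kes[matid[e]];
    double s = escale[e];
    int dof[24];
    for (int a = 0; a < 8; ++a) {
      int node = elems(e, a);
      for (int c = 0; c < 3; ++c) dof[3 * a + c] = 3 * node + c;
    }
    for (int j = 0; j < 24; ++j) xe[j] = x[dof[j]];
    for (int r = 0; r < 24; ++r) {
      double acc = 0.0;
      const double *row = ke + (R_xlen_t)r * 24;
      for (int j = 0; j < 24; ++j) acc += row[j] * xe[j];
      ye[r] = s * acc;
    }
    for (int r = 0; r < 24; ++r) y[dof[r]] += ye[r];
  }
}

// [[Rcpp::export(name = ".hex_matvec_cpp")]]
NumericVector hex_matvec_cpp(IntegerMatrix elems, NumericVector escale,
                             IntegerVector matid, List ke_list, int nnode,
                             NumericVector x) {
  R_xlen_t ndof = 3 * (R_xlen_t)nnode;
  std::vector<NumericMatrix> kemats;
  std::vector<const double*> kes;
  for (int i = 0; i < ke_list.size(); ++i) {
    kemats.push_back(as<NumericMatrix>(ke_list[i]));
  }
  // row-major copies for cache-friendly row access
  std::vector<std::vector<double>> kerow(kemats.size());
  for (size_t i = 0; i < kemats.size(); ++i) {
    kerow[i].resize(576);
    for (int r = 0; r < 24; ++r)
      for (int c = 0; c < 24; ++c) kerow[i][r * 24 + c] = kemats[i](r, c);
    kes.push_back(kerow[i].data());
  }
  NumericVector y(ndof);
  matvec(elems, escale, matid, kes, REAL(x), REAL(y), ndof);
  return y;
}

// Jacobi-preconditioned conjugate gradients with Dirichlet dofs eliminated by
// zero-masking. Returns the full displacement vector (fixed values included).
// [[Rcpp::export(name = ".hex_pcg_cpp")]]
List hex_pcg_cpp(IntegerMatrix elems, NumericVector escale, IntegerVector matid,
                 List ke_list, int nnode, IntegerVector fixed_dofs,
                 NumericVector fixed_vals, double tol, int maxit) {
  R_xlen_t ndof = 3 * (R_xlen_t)nnode;
  int nel = elems.nrow();

  std::vector<NumericMatrix> kemats;
  for (int i = 0; i < ke_list.size(); ++i)
    kemats.push_back(as<NumericMatrix>(ke_list[i]));
  std::vector<std::vector<double>> kerow(kemats.size());
  std::vector<const double*> kes;
  for (size_t i = 0; i < kemats.size(); ++i) {
    kerow[i].resize(576);
    for (int r = 0; r < 24; ++r)
      for (int c = 0; c < 24; ++c) kerow[i][r * 24 + c] = kemats[i](r, c);
    kes.push_back(kerow[i].data());
  }

  std::vector<char> isfixed(ndof, 0);
  for (int i = 0; i < fixed_dofs.size(); ++i) isfixed[fixed_dofs[i]] = 1;

  // diagonal of K over free dofs (Jacobi preconditioner)
  std::vector<double> diag(ndof, 0.0);
  for (int e = 0; e < nel; ++e) {
    const double *ke = kes[matid[e]];
    double s = escale[e];
    for (int a = 0; a < 8; ++a) {
      int node = elems(e, a);
      for (int c = 0; c < 3; ++c) {
        int ldof = 3 * a + c;
        diag[3 * (R_xlen_t)node + c] += s * ke[(R_xlen_t)ldof * 24 + ldof];
      }
    }
  }

  std::vector<double> u(ndof, 0.0), b(ndof), x(ndof, 0.0), r(ndof), z(ndof),
      p(ndof), Ap(ndof);
  for (int i = 0; i < fixed_dofs.size(); ++i) u[fixed_dofs[i]] = fixed_vals[i];

  // b = -K u_dirichlet on free dofs
  matvec(elems, escale, matid, kes, u.data(), b.data(), ndof);
  double bnorm2 = 0.0;
  for (R_xlen_t i = 0; i < ndof; ++i) {
    b[i] = isfixed[i] ? 0.0 : -b[i];
    bnorm2 += b[i] * b[i];
  }
  double bnorm = std::sqrt(bnorm2);
  int iter = 0;
  double relres = 0.0;
  bool converged = true;
  if (bnorm > 0.0) {
    for (R_xlen_t i = 0; i < ndof; ++i) r[i] = b[i];
    double rz = 0.0;
    for (R_xlen_t i = 0; i < ndof; ++i) {
      z[i] = (isfixed[i] || diag[i] == 0.0) ? 0.0 : r[i] / diag[i];
      p[i] = z[i];
      rz += r[i] * z[i];
    }
    converged = false;
    for (iter = 1; iter <= maxit; ++iter) {
      matvec(elems, escale, matid, kes, p.data(), Ap.data(), ndof);
      double pAp = 0.0;
      for (R_xlen_t i = 0; i < ndof; ++i) {
        if (isfixed[i]) Ap[i] = 0.0;
        pAp += p[i] * Ap[i];
      }
      if (pAp <= 0.0) break;  // singular or indefinite restriction
      double alpha = rz / pAp;
      double rnorm2 = 0.0;
      for (R_xlen_t i = 0; i < ndof; ++i) {
        x[i] += alpha * p[i];
        r[i] -= alpha * Ap[i];
        rnorm2 += r[i] * r[i];
      }
      relres = std::sqrt(rnorm2) / bnorm;
      if (relres <= tol) { converged = true; break; }
      double rznew = 0.0;
      for (R_xlen_t i = 0; i < ndof; ++i) {
        z[i] = (isfixed[i] || diag[i] == 0.0) ? 0.0 : r[i] / diag[i];
        rznew += r[i] * z[i];
      }
      double beta = rznew / rz;
      rz = rznew;
      for (R_xlen_t i = 0; i < ndof; ++i) p[i] = z[i] + beta * p[i];
    }
  }

  NumericVector ufull(ndof);
  for (R_xlen_t i = 0; i < ndof; ++i) ufull[i] = u[i] + x[i];
  return List::create(_["u"] = ufull, _["iterations"] = iter,
                      _["relres"] = relres, _["converged"] = converged,
                      _["force_norm"] = bnorm);
}
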