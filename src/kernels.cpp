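// Core numerical kernels: D3Q19 lattice Boltzmann (BGK + Guo forcing,
// Hecht-Harting on-site velocity walls at the z-faces, periodic x/y),
// immersed-boundary spreading/interpolation (4-point cosine kernel),
// hybrid membrane forces (spring network, area/volume constraints,
// cotangent-Laplacian bending), stochastic adhesive dynamics, and the
// coupled time loop. All quantities in lattice units (h = dt = rho0 = 1);
// unit conversion lives on the R side.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// ---------------------------------------------------------------- D3Q19 ---
// 0: rest; 1-6: axis; 7-18: face diagonals.
static const int CX[19] = {0, 1,-1, 0, 0, 0, 0, 1,-1, 1,-1, 1,-1, 1,-1, 0, 0, 0, 0};
static const int CY[19] = {0, 0, 0, 1,-1, 0, 0, 1,-1,-1, 1, 0, 0, 0, 0, 1,-1, 1,-1};
static const int CZ[19] = {0, 0, 0, 0, 0, 1,-1, 0, 0, 0, 0, 1,-1,-1, 1, 1,-1,-1, 1};
static const double CXd[19] = {0, 1,-1, 0, 0, 0, 0, 1,-1, 1,-1, 1,-1, 1,-1, 0, 0, 0, 0};
static const double CYd[19] = {0, 0, 0, 1,-1, 0, 0, 1,-1,-1, 1, 0, 0, 0, 0, 1,-1, 1,-1};
static const double CZd[19] = {0, 0, 0, 0, 0, 1,-1, 0, 0, 0, 0, 1,-1,-1, 1, 1,-1,-1, 1};
static const double W19[19] = {
  1.0/3,
  1.0/18, 1.0/18, 1.0/18, 1.0/18, 1.0/18, 1.0/18,
  1.0/36, 1.0/36, 1.0/36, 1.0/36, 1.0/36, 1.0/36,
  1.0/36, 1.0/36, 1.0/36, 1.0/36, 1.0/36, 1.0/36};

// [[Rcpp::export]]
List d3q19_tables() {
  IntegerMatrix c(19, 3);
  NumericVector w(19);
  for (int i = 0; i < 19; ++i) {
    c(i, 0) = CX[i]; c(i, 1) = CY[i]; c(i, 2) = CZ[i];
    w[i] = W19[i];
  }
  return List::create(_["c"] = c, _["w"] = w);
}

static inline int cell(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

static inline double feq_i(int i, double rho, double vx, double vy, double vz) {
  double cv = CX[i] * vx + CY[i] * vy + CZ[i] * vz;
  double v2 = vx * vx + vy * vy + vz * vz;
  return W19[i] * rho * (1.0 + 3.0 * cv + 4.5 * cv * cv - 1.5 * v2);
}

// [[Rcpp::export]]
arma::mat lbm_equilibrium_cpp(const arma::vec& rho, const arma::mat& v) {
  int n = rho.n_elem;
  arma::mat f(19, n);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < 19; ++i)
      f(i, j) = feq_i(i, rho[j], v(j, 0), v(j, 1), v(j, 2));
  return f;
}

// [[Rcpp::export]]
List lbm_macroscopic_cpp(const arma::mat& f, const arma::mat& force) {
  int n = f.n_cols;
  arma::vec rho(n);
  arma::mat v(n, 3);
  bool hasF = force.n_rows == (unsigned)n;
  for (int j = 0; j < n; ++j) {
    double r = 0, mx = 0, my = 0, mz = 0;
    for (int i = 0; i < 19; ++i) {
      double fi = f(i, j);
      r += fi; mx += CX[i] * fi; my += CY[i] * fi; mz += CZ[i] * fi;
    }
    rho[j] = r;
    double Fx = hasF ? force(j, 0) : 0.0;
    double Fy = hasF ? force(j, 1) : 0.0;
    double Fz = hasF ? force(j, 2) : 0.0;
    v(j, 0) = (mx + 0.5 * Fx) / r;
    v(j, 1) = (my + 0.5 * Fy) / r;
    v(j, 2) = (mz + 0.5 * Fz) / r;
  }
  return List::create(_["rho"] = rho, _["v"] = v);
}

// Hecht-Harting on-site velocity reconstruction for one z-wall node.
// `up` = true for the bottom wall z=0 (unknown populations travel +z).
// Wall density is computed from the known populations (not imposed); the
// unknowns are rebuilt as f_i = f_opp(i) + rho (c_i.v)/(3 or 6) minus the
// transverse momentum corrections N_x, N_y, which makes the post-BC node
// moments equal (rho_wall, v_wall) exactly.
static void hh_wall_node(double* f, bool up, double vx, double vy, double vz) {
  // direction indices by (cx,cy,cz):
  // +z set: 5 (0,0,1), 11 (1,0,1), 14 (-1,0,1), 15 (0,1,1), 18 (0,-1,1)
  // -z set: 6 (0,0,-1), 12 (-1,0,-1), 13 (1,0,-1), 16 (0,-1,-1), 17 (0,1,-1)
  static const int unkP[5] = {5, 11, 14, 15, 18};
  static const int oppP[5] = {6, 12, 13, 16, 17};
  static const int unkM[5] = {6, 12, 13, 16, 17};
  static const int oppM[5] = {5, 11, 14, 15, 18};
  const int* unk = up ? unkP : unkM;
  const int* opp = up ? oppP : oppM;
  double vn = up ? vz : -vz;           // normal velocity into the fluid
  double szero = 0, sknown = 0, px = 0, py = 0;
  for (int i = 0; i < 19; ++i) {
    if (CZ[i] == 0) {
      szero += f[i]; px += CX[i] * f[i]; py += CY[i] * f[i];
    }
  }
  for (int k = 0; k < 5; ++k) sknown += f[opp[k]];
  double rho = (szero + 2.0 * sknown) / (1.0 - vn);
  double Nx = 0.5 * px - rho * vx / 3.0;
  double Ny = 0.5 * py - rho * vy / 3.0;
  for (int k = 0; k < 5; ++k) {
    int i = unk[k];
    double cdotv = CX[i] * vx + CY[i] * vy + CZ[i] * vz;
    double denom = (CX[i] == 0 && CY[i] == 0) ? 3.0 : 6.0;
    f[i] = f[opp[k]] + rho * cdotv / denom - CX[i] * Nx - CY[i] * Ny;
  }
}

// Precompute pull-streaming sources: nbr[19*j + i] = source cell for
// population i at cell j (periodic wrap in all axes; the z-wall BC
// overwrites the populations that would have wrapped through a wall).
static std::vector<int> build_nbr(int nx, int ny, int nz) {
  int ncell = nx * ny * nz;
  std::vector<int> nbr((size_t)19 * ncell);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int j = cell(x, y, z, nx, ny);
        for (int i = 0; i < 19; ++i) {
          int xs = x - CX[i]; if (xs < 0) xs += nx; else if (xs >= nx) xs -= nx;
          int ys = y - CY[i]; if (ys < 0) ys += ny; else if (ys >= ny) ys -= ny;
          int zs = z - CZ[i]; if (zs < 0) zs += nz; else if (zs >= nz) zs -= nz;
          nbr[(size_t)19 * j + i] = cell(xs, ys, zs, nx, ny);
        }
      }
  return nbr;
}

// One collide+stream+BC step over the whole lattice.
// f: 19 x ncell, force: ncell x 3 (may be 0 x 3), walls move in x/y plane.
static void lbm_step_once(arma::mat& f, arma::mat& fbuf,
                          int nx, int ny, int nz, double tau,
                          const arma::mat& force,
                          bool wall_z, const double* vbot, const double* vtop,
                          const std::vector<int>& nbr) {
  int ncell = nx * ny * nz;
  bool hasF = force.n_rows == (unsigned)ncell;
  double om = 1.0 / tau;
  double pref = 1.0 - 0.5 * om;
  // collide in place
  for (int j = 0; j < ncell; ++j) {
    double r = 0, mx = 0, my = 0, mz = 0;
    double* fj = f.colptr(j);
    for (int i = 0; i < 19; ++i) {
      r += fj[i]; mx += CXd[i] * fj[i]; my += CYd[i] * fj[i]; mz += CZd[i] * fj[i];
    }
    double Fx = hasF ? force(j, 0) : 0.0;
    double Fy = hasF ? force(j, 1) : 0.0;
    double Fz = hasF ? force(j, 2) : 0.0;
    double rinv = 1.0 / r;
    double vx = (mx + 0.5 * Fx) * rinv;
    double vy = (my + 0.5 * Fy) * rinv;
    double vz = (mz + 0.5 * Fz) * rinv;
    double v2 = vx * vx + vy * vy + vz * vz;
    double base = 1.0 - 1.5 * v2;
    for (int i = 0; i < 19; ++i) {
      double cv = CXd[i] * vx + CYd[i] * vy + CZd[i] * vz;
      double feq = W19[i] * r * (base + 3.0 * cv + 4.5 * cv * cv);
      double guo = 0.0;
      if (hasF) {
        double cFx = CXd[i] - vx + 3.0 * cv * CXd[i];
        double cFy = CYd[i] - vy + 3.0 * cv * CYd[i];
        double cFz = CZd[i] - vz + 3.0 * cv * CZd[i];
        guo = pref * W19[i] * 3.0 * (cFx * Fx + cFy * Fy + cFz * Fz);
      }
      fj[i] = fj[i] - om * (fj[i] - feq) + guo;
    }
  }
  // stream (pull) into fbuf; z wraps too, wall BC overwrites unknowns after
  const double* fp = f.memptr();
  double* fb = fbuf.memptr();
  for (int j = 0; j < ncell; ++j) {
    const int* nb = &nbr[(size_t)19 * j];
    double* fd = fb + (size_t)19 * j;
    for (int i = 0; i < 19; ++i) fd[i] = fp[(size_t)19 * nb[i] + i];
  }
  f.swap(fbuf);
  if (wall_z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        hh_wall_node(f.colptr(cell(x, y, 0, nx, ny)), true,
                     vbot[0], vbot[1], vbot[2]);
        hh_wall_node(f.colptr(cell(x, y, nz - 1, nx, ny)), false,
                     vtop[0], vtop[1], vtop[2]);
      }
    }
  }
}

// [[Rcpp::export]]
arma::mat lbm_run_cpp(arma::mat f, int nx, int ny, int nz, double tau,
                      const arma::mat& force, int nsteps,
                      bool wall_z, NumericVector v_bottom, NumericVector v_top) {
  arma::mat fbuf(19, nx * ny * nz);
  std::vector<int> nbr = build_nbr(nx, ny, nz);
  double vb[3] = {v_bottom[0], v_bottom[1], v_bottom[2]};
  double vt[3] = {v_top[0], v_top[1], v_top[2]};
  for (int s = 0; s < nsteps; ++s) {
    lbm_step_once(f, fbuf, nx, ny, nz, tau, force, wall_z, vb, vt, nbr);
    if ((s & 1023) == 0 && !f.is_finite())
      stop("LBM diverged (non-finite distributions) at step %d", s + 1);
  }
  if (!f.is_finite()) stop("LBM diverged (non-finite distributions)");
  return f;
}

// [[Rcpp::export]]
arma::mat hh_apply_cpp(arma::mat f, int nx, int ny, int nz,
                       bool bottom, NumericVector v_wall) {
  int z = bottom ? 0 : nz - 1;
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x)
      hh_wall_node(f.colptr(cell(x, y, z, nx, ny)), bottom,
                   v_wall[0], v_wall[1], v_wall[2]);
  return f;
}

// ------------------------------------------------------------------ IBM ---
static inline double phi4(double r) {
  double a = std::fabs(r);
  if (a >= 2.0) return 0.0;
  return 0.25 * (1.0 + std::cos(M_PI * a / 2.0));
}

// [[Rcpp::export]]
double delta_kernel_cpp(double rx, double ry, double rz) {
  return phi4(rx) * phi4(ry) * phi4(rz);
}

// Spread Lagrangian point forces F (lattice force units) at positions X
// (lattice coords) onto the grid as a force density (h = 1). Periodic in
// x/y; kernel support crossing a z-face is truncated (the wall absorbs it).
static void spread_into(arma::mat& g, const arma::mat& X, const arma::mat& F,
                        int nx, int ny, int nz) {
  int m = X.n_rows;
  for (int p = 0; p < m; ++p) {
    double xx = X(p, 0), yy = X(p, 1), zz = X(p, 2);
    int x0 = (int)std::floor(xx) - 1, y0 = (int)std::floor(yy) - 1,
        z0 = (int)std::floor(zz) - 1;
    for (int dz = 0; dz < 4; ++dz) {
      int z = z0 + dz; if (z < 0 || z >= nz) continue;
      double wz = phi4(zz - z); if (wz == 0) continue;
      for (int dy = 0; dy < 4; ++dy) {
        int y = y0 + dy;
        double wy = phi4(yy - (y0 + dy)); if (wy == 0) continue;
        int yw = ((y % ny) + ny) % ny;
        for (int dx = 0; dx < 4; ++dx) {
          int x = x0 + dx;
          double wx = phi4(xx - x); if (wx == 0) continue;
          int xw = ((x % nx) + nx) % nx;
          double w = wx * wy * wz;
          int j = cell(xw, yw, z, nx, ny);
          g(j, 0) += w * F(p, 0);
          g(j, 1) += w * F(p, 1);
          g(j, 2) += w * F(p, 2);
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::mat ibm_spread_cpp(const arma::mat& X, const arma::mat& F,
                         int nx, int ny, int nz) {
  arma::mat g(nx * ny * nz, 3, arma::fill::zeros);
  spread_into(g, X, F, nx, ny, nz);
  return g;
}

static void interp_into(arma::mat& U, const arma::mat& v, const arma::mat& X,
                        int nx, int ny, int nz) {
  int m = X.n_rows;
  for (int p = 0; p < m; ++p) {
    double xx = X(p, 0), yy = X(p, 1), zz = X(p, 2);
    int x0 = (int)std::floor(xx) - 1, y0 = (int)std::floor(yy) - 1,
        z0 = (int)std::floor(zz) - 1;
    double ux = 0, uy = 0, uz = 0;
    for (int dz = 0; dz < 4; ++dz) {
      int z = z0 + dz; if (z < 0 || z >= nz) continue;
      double wz = phi4(zz - z); if (wz == 0) continue;
      for (int dy = 0; dy < 4; ++dy) {
        int y = y0 + dy;
        double wy = phi4(yy - y); if (wy == 0) continue;
        int yw = ((y % ny) + ny) % ny;
        for (int dx = 0; dx < 4; ++dx) {
          int x = x0 + dx;
          double wx = phi4(xx - x); if (wx == 0) continue;
          int xw = ((x % nx) + nx) % nx;
          double w = wx * wy * wz;
          int j = cell(xw, yw, z, nx, ny);
          ux += w * v(j, 0); uy += w * v(j, 1); uz += w * v(j, 2);
        }
      }
    }
    U(p, 0) = ux; U(p, 1) = uy; U(p, 2) = uz;
  }
}

// [[Rcpp::export]]
arma::mat ibm_interp_cpp(const arma::mat& v, const arma::mat& X,
                         int nx, int ny, int nz) {
  arma::mat U(X.n_rows, 3, arma::fill::zeros);
  interp_into(U, v, X, nx, ny, nz);
  return U;
}


// Meyer mixed (Voronoi-safe) vertex areas, cotangent mean curvature and a
// ripple-damped surface Laplacian of K. The curvature field is smoothed by
// two umbrella passes before the Laplacian: the cotangent Laplacian
// amplifies lattice-scale ripple in K (which sits exactly at the grid
// frequency) ahead of the smooth 2K^3 term otherwise.
struct CurvOut {
  arma::vec Avert, K, lapK;
  arma::mat nvert;
};

static void curvature_impl(const arma::mat& X, const arma::imat& tris,
                           CurvOut& out) {
  int nv = X.n_rows, nf = tris.n_rows;
  arma::vec S(nf);
  arma::mat fn(nf, 3);
  out.Avert.zeros(nv);
  out.nvert.zeros(nv, 3);
  std::vector<double> cotw(3 * nf);
  // first pass: face geometry, corner cotangents, mixed areas
  for (int t = 0; t < nf; ++t) {
    int i = tris(t,0), j = tris(t,1), k = tris(t,2);
    double e1x = X(j,0)-X(i,0), e1y = X(j,1)-X(i,1), e1z = X(j,2)-X(i,2);
    double e2x = X(k,0)-X(i,0), e2y = X(k,1)-X(i,1), e2z = X(k,2)-X(i,2);
    double cxv = e1y*e2z - e1z*e2y, cyv = e1z*e2x - e1x*e2z, czv = e1x*e2y - e1y*e2x;
    fn(t,0)=0.5*cxv; fn(t,1)=0.5*cyv; fn(t,2)=0.5*czv;
    S[t] = 0.5*std::sqrt(cxv*cxv+cyv*cyv+czv*czv);
    const int vv[3] = {i, j, k};
    double cot[3];
    double el2[3];   // squared length of edge opposite corner c
    for (int c = 0; c < 3; ++c) {
      int a = vv[c], b = vv[(c+1)%3], d = vv[(c+2)%3];
      double ux = X(b,0)-X(a,0), uy = X(b,1)-X(a,1), uz = X(b,2)-X(a,2);
      double wx = X(d,0)-X(a,0), wy = X(d,1)-X(a,1), wz = X(d,2)-X(a,2);
      double dot = ux*wx + uy*wy + uz*wz;
      double crx = uy*wz-uz*wy, cry = uz*wx-ux*wz, crz = ux*wy-uy*wx;
      double crn = std::sqrt(crx*crx+cry*cry+crz*crz);
      cot[c] = crn > 1e-300 ? dot/crn : 0.0;
      cotw[3*t + c] = cot[c];
      double ox = X(d,0)-X(b,0), oy = X(d,1)-X(b,1), oz = X(d,2)-X(b,2);
      el2[c] = ox*ox + oy*oy + oz*oz;
    }
    bool obtuse[3];
    int nob = -1;
    for (int c = 0; c < 3; ++c) { obtuse[c] = cot[c] < 0; if (obtuse[c]) nob = c; }
    for (int c = 0; c < 3; ++c) {
      int a = vv[c];
      double Am;
      if (nob < 0) {
        // Voronoi: 1/8 (|e_b|^2 cot_b + |e_d|^2 cot_d) with e_* the edges
        // incident at a, cot at the opposite corners
        Am = 0.125 * (el2[(c+1)%3] * cot[(c+1)%3] + el2[(c+2)%3] * cot[(c+2)%3]);
      } else {
        Am = (nob == c) ? S[t] / 2.0 : S[t] / 4.0;
      }
      out.Avert[a] += Am;
      out.nvert(a,0)+=fn(t,0); out.nvert(a,1)+=fn(t,1); out.nvert(a,2)+=fn(t,2);
    }
  }
  for (int i = 0; i < nv; ++i) {
    double nn = std::sqrt(out.nvert(i,0)*out.nvert(i,0)
                        + out.nvert(i,1)*out.nvert(i,1)
                        + out.nvert(i,2)*out.nvert(i,2));
    if (nn > 0) { out.nvert(i,0)/=nn; out.nvert(i,1)/=nn; out.nvert(i,2)/=nn; }
  }
  // mean curvature normal
  arma::mat Lx(nv, 3, arma::fill::zeros);
  for (int t = 0; t < nf; ++t) {
    const int vv[3] = {(int)tris(t,0), (int)tris(t,1), (int)tris(t,2)};
    for (int c = 0; c < 3; ++c) {
      int b = vv[(c+1)%3], d = vv[(c+2)%3];
      double hw = 0.5 * cotw[3*t + c];
      for (int dd = 0; dd < 3; ++dd) {
        double diff = X(d,dd)-X(b,dd);
        Lx(b,dd) += hw*diff; Lx(d,dd) -= hw*diff;
      }
    }
  }
  out.K.set_size(nv);
  for (int i = 0; i < nv; ++i)
    out.K[i] = -(Lx(i,0)*out.nvert(i,0) + Lx(i,1)*out.nvert(i,1)
               + Lx(i,2)*out.nvert(i,2)) / (2.0*out.Avert[i]);
  // two umbrella passes on K (area-weighted neighbour average)
  arma::vec Ks = out.K;
  for (int pass = 0; pass < 2; ++pass) {
    arma::vec acc(nv, arma::fill::zeros), wsum(nv, arma::fill::zeros);
    for (int t = 0; t < nf; ++t) {
      const int vv[3] = {(int)tris(t,0), (int)tris(t,1), (int)tris(t,2)};
      for (int c = 0; c < 3; ++c) {
        int a = vv[c], b = vv[(c+1)%3];
        acc[a] += Ks[b]; wsum[a] += 1.0;
        acc[b] += Ks[a]; wsum[b] += 1.0;
      }
    }
    for (int i = 0; i < nv; ++i)
      if (wsum[i] > 0) Ks[i] = 0.5 * Ks[i] + 0.5 * acc[i] / wsum[i];
  }
  arma::vec LK(nv, arma::fill::zeros);
  for (int t = 0; t < nf; ++t) {
    const int vv[3] = {(int)tris(t,0), (int)tris(t,1), (int)tris(t,2)};
    for (int c = 0; c < 3; ++c) {
      int b = vv[(c+1)%3], d = vv[(c+2)%3];
      double hw = 0.5*cotw[3*t + c];
      LK[b] += hw*(Ks[d]-Ks[b]); LK[d] += hw*(Ks[b]-Ks[d]);
    }
  }
  out.lapK = LK / out.Avert;
}

// ------------------------------------------------------- membrane forces ---
// tris/edges are 0-based index matrices.
struct MembraneOut {
  arma::mat F_spring, F_area, F_vol, F_bend;
  double E_spring, E_area_g, E_area_l, E_vol, E_bend, area, volume;
};

static void membrane_forces_impl(const arma::mat& X, const arma::imat& tris,
                                 const arma::imat& edges, const arma::vec& rest,
                                 const arma::vec& S0, double area0, double V0,
                                 double k_spring, double ks, double kt,
                                 double kv, double k0b, bool bending,
                                 MembraneOut& out) {
  int nv = X.n_rows, nf = tris.n_rows, ne = edges.n_rows;
  out.F_spring.zeros(nv, 3); out.F_area.zeros(nv, 3);
  out.F_vol.zeros(nv, 3); out.F_bend.zeros(nv, 3);
  out.E_spring = out.E_area_g = out.E_area_l = out.E_vol = out.E_bend = 0;

  // springs
  for (int e = 0; e < ne; ++e) {
    int i = edges(e, 0), j = edges(e, 1);
    double dx = X(j, 0) - X(i, 0), dy = X(j, 1) - X(i, 1), dz = X(j, 2) - X(i, 2);
    double L = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (L <= 0) stop("degenerate geometry: coincident vertices on edge %d", e + 1);
    double s = k_spring * (L - rest[e]);
    out.E_spring += 0.5 * k_spring * (L - rest[e]) * (L - rest[e]);
    double fx = s * dx / L, fy = s * dy / L, fz = s * dz / L;
    out.F_spring(i, 0) += fx; out.F_spring(i, 1) += fy; out.F_spring(i, 2) += fz;
    out.F_spring(j, 0) -= fx; out.F_spring(j, 1) -= fy; out.F_spring(j, 2) -= fz;
  }

  // triangle geometry
  arma::mat fn(nf, 3);      // area-weighted face normals (0.5 * cross)
  arma::vec S(nf);
  double area = 0, vol = 0;
  for (int t = 0; t < nf; ++t) {
    int i = tris(t, 0), j = tris(t, 1), k = tris(t, 2);
    double e1x = X(j,0)-X(i,0), e1y = X(j,1)-X(i,1), e1z = X(j,2)-X(i,2);
    double e2x = X(k,0)-X(i,0), e2y = X(k,1)-X(i,1), e2z = X(k,2)-X(i,2);
    double cxv = e1y*e2z - e1z*e2y, cyv = e1z*e2x - e1x*e2z, czv = e1x*e2y - e1y*e2x;
    fn(t,0) = 0.5*cxv; fn(t,1) = 0.5*cyv; fn(t,2) = 0.5*czv;
    S[t] = 0.5*std::sqrt(cxv*cxv + cyv*cyv + czv*czv);
    area += S[t];
    vol += (X(i,0)*(X(j,1)*X(k,2)-X(j,2)*X(k,1))
          - X(i,1)*(X(j,0)*X(k,2)-X(j,2)*X(k,0))
          + X(i,2)*(X(j,0)*X(k,1)-X(j,1)*X(k,0))) / 6.0;
  }
  out.area = area; out.volume = vol;

  // area constraints: global ks*(A-A0)^2/(2A0) + local kt*(S-S0)^2/(2S0)
  out.E_area_g = ks * (area - area0) * (area - area0) / (2.0 * area0);
  double cg = ks * (area - area0) / area0;
  for (int t = 0; t < nf; ++t) {
    double Sl = S[t] > 1e-300 ? S[t] : 1e-300;
    double cl = kt * (S[t] - S0[t]) / S0[t];
    out.E_area_l += kt * (S[t]-S0[t]) * (S[t]-S0[t]) / (2.0 * S0[t]);
    double c = cg + cl;
    // grad of S wrt vertex a = 0.5 * (b - c) x n_hat, with n_hat = fn/S
    int ia = tris(t,0), ib = tris(t,1), ic = tris(t,2);
    double nhx = fn(t,0)/Sl, nhy = fn(t,1)/Sl, nhz = fn(t,2)/Sl;
    const int va[3] = {ia, ib, ic};
    for (int corner = 0; corner < 3; ++corner) {
      int a = va[corner], b = va[(corner+1)%3], cc = va[(corner+2)%3];
      double ex = X(b,0)-X(cc,0), ey = X(b,1)-X(cc,1), ez = X(b,2)-X(cc,2);
      // grad_a S = 0.5 * (edge_bc) x n_hat  (with edge = b - cc)
      double gx = 0.5*(ey*nhz - ez*nhy);
      double gy = 0.5*(ez*nhx - ex*nhz);
      double gz = 0.5*(ex*nhy - ey*nhx);
      out.F_area(a,0) -= c*gx; out.F_area(a,1) -= c*gy; out.F_area(a,2) -= c*gz;
    }
  }

  // volume constraint kv*(V-V0)^2/(2V0); grad_a V = sum faces (b x c)/6
  out.E_vol = kv * (vol - V0) * (vol - V0) / (2.0 * V0);
  double cv = kv * (vol - V0) / V0;
  for (int t = 0; t < nf; ++t) {
    int ia = tris(t,0), ib = tris(t,1), ic = tris(t,2);
    const int v3[3] = {ia, ib, ic};
    for (int corner = 0; corner < 3; ++corner) {
      int a = v3[corner], b = v3[(corner+1)%3], cc = v3[(corner+2)%3];
      double gx = (X(b,1)*X(cc,2) - X(b,2)*X(cc,1)) / 6.0;
      double gy = (X(b,2)*X(cc,0) - X(b,0)*X(cc,2)) / 6.0;
      double gz = (X(b,0)*X(cc,1) - X(b,1)*X(cc,0)) / 6.0;
      out.F_vol(a,0) -= cv*gx; out.F_vol(a,1) -= cv*gy; out.F_vol(a,2) -= cv*gz;
    }
  }

  if (!bending || k0b == 0) return;

  CurvOut co;
  curvature_impl(X, tris, co);
  for (int i = 0; i < nv; ++i) {
    double mag = k0b * (co.lapK[i] + 2.0 * co.K[i]*co.K[i]*co.K[i]) * co.Avert[i];
    out.F_bend(i,0) = mag * co.nvert(i,0);
    out.F_bend(i,1) = mag * co.nvert(i,1);
    out.F_bend(i,2) = mag * co.nvert(i,2);
    out.E_bend += 0.5 * k0b * (2.0*co.K[i]) * (2.0*co.K[i]) * co.Avert[i];
  }
}

// [[Rcpp::export]]
List membrane_forces_cpp(const arma::mat& X, const arma::imat& tris,
                         const arma::imat& edges, const arma::vec& rest,
                         const arma::vec& S0, double area0, double V0,
                         double k_spring, double ks, double kt, double kv,
                         double k0b, bool bending) {
  MembraneOut out;
  membrane_forces_impl(X, tris, edges, rest, S0, area0, V0,
                       k_spring, ks, kt, kv, k0b, bending, out);
  return List::create(
    _["F_spring"] = out.F_spring, _["F_area"] = out.F_area,
    _["F_vol"] = out.F_vol, _["F_bend"] = out.F_bend,
    _["E_spring"] = out.E_spring, _["E_area_global"] = out.E_area_g,
    _["E_area_local"] = out.E_area_l, _["E_vol"] = out.E_vol,
    _["E_bend"] = out.E_bend, _["area"] = out.area, _["volume"] = out.volume);
}

// curvature diagnostics (K, vertex areas, normals, Laplacian of K)
// [[Rcpp::export]]
List curvature_cpp(const arma::mat& X, const arma::imat& tris) {
  CurvOut cv;
  curvature_impl(X, tris, cv);
  return List::create(_["K"] = cv.K, _["lapK"] = cv.lapK,
                      _["A_vertex"] = cv.Avert, _["normals"] = cv.nvert);
}

// ------------------------------------------------------ adhesion dynamics ---
// Wall repulsion magnitude, eps in lattice lengths, params in lattice units.
static inline double frep(double eps, double F0tau, double taurep,
                          double eps_min) {
  if (eps < eps_min) eps = eps_min;
  double e = std::exp(-taurep * eps);
  return F0tau * e / (1.0 - e);
}

// One Monte Carlo adhesion update (wall bonds). Operates on explicit site
// positions; used standalone (R-level mc_update) and inside the coupled
// loop. site_bond: -1 free, else ligand index. Uses the R RNG.
static void mc_update_impl(const arma::mat& sitepos, arma::ivec& site_bond,
                           arma::ivec& lig_count, const arma::mat& ligpos,
                           double kon0, double koff0, double gbell,
                           double sigma, double sigma_on, double lb,
                           double rbind, double dt_mc, int max_per_lig,
                           std::vector<double>* events, double tnow) {
  int ns = sitepos.n_rows, nl = ligpos.n_rows;
  // candidate free pairs within rbind
  std::vector<std::pair<int,int> > cand;
  for (int s = 0; s < ns; ++s) {
    if (site_bond[s] >= 0) continue;
    double z = sitepos(s, 2);
    if (z > rbind || z < -rbind) continue;
    for (int l = 0; l < nl; ++l) {
      if (lig_count[l] >= max_per_lig) continue;
      double dx = sitepos(s,0)-ligpos(l,0), dy = sitepos(s,1)-ligpos(l,1);
      double d2 = dx*dx + dy*dy + z*z;
      if (d2 < rbind*rbind) cand.push_back(std::make_pair(s, l));
    }
  }
  // randomized processing order (avoids index bias in rule-(ii) competition)
  int nc = cand.size();
  for (int i = nc - 1; i > 0; --i) {
    int j = (int)std::floor(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(cand[i], cand[j]);
  }
  for (int i = 0; i < nc; ++i) {
    int s = cand[i].first, l = cand[i].second;
    if (site_bond[s] >= 0 || lig_count[l] >= max_per_lig) continue;
    double dx = sitepos(s,0)-ligpos(l,0), dy = sitepos(s,1)-ligpos(l,1),
           dz = sitepos(s,2)-ligpos(l,2);
    double xb = std::sqrt(dx*dx + dy*dy + dz*dz);
    double kon = kon0 * std::exp(-sigma_on * (xb-lb)*(xb-lb) / 2.0);
    double Pf = 1.0 - std::exp(-kon * dt_mc);
    if (unif_rand() < Pf) {
      site_bond[s] = l; lig_count[l] += 1;
      if (events) {
        events->push_back(tnow); events->push_back(1);
        events->push_back(s + 1); events->push_back(l + 1);
        events->push_back(xb); events->push_back(sigma * (xb - lb));
      }
    }
  }
  // breakage test for existing bonds
  for (int s = 0; s < ns; ++s) {
    int l = site_bond[s];
    if (l < 0) continue;
    double dx = sitepos(s,0)-ligpos(l,0), dy = sitepos(s,1)-ligpos(l,1),
           dz = sitepos(s,2)-ligpos(l,2);
    double xb = std::sqrt(dx*dx + dy*dy + dz*dz);
    double Fb = sigma * (xb - lb); if (Fb < 0) Fb = 0;  // tension only
    double koff = koff0 * std::exp(gbell * Fb);
    double Pr = 1.0 - std::exp(-koff * dt_mc);
    if (unif_rand() < Pr) {
      site_bond[s] = -1; lig_count[l] -= 1;
      if (events) {
        events->push_back(tnow); events->push_back(-1);
        events->push_back(s + 1); events->push_back(l + 1);
        events->push_back(xb); events->push_back(sigma * (xb - lb));
      }
    }
  }
}

// [[Rcpp::export]]
List mc_update_cpp(const arma::mat& sitepos, arma::ivec site_bond,
                   arma::ivec lig_count, const arma::mat& ligpos,
                   double kon0, double koff0, double gbell, double sigma,
                   double sigma_on, double lb, double rbind, double dt_mc,
                   int max_per_lig) {
  RNGScope scope;
  std::vector<double> ev;
  mc_update_impl(sitepos, site_bond, lig_count, ligpos, kon0, koff0, gbell,
                 sigma, sigma_on, lb, rbind, dt_mc, max_per_lig, &ev, 0.0);
  int nev = ev.size() / 6;
  NumericMatrix events(nev, 6);
  for (int i = 0; i < nev; ++i)
    for (int j = 0; j < 6; ++j) events(i, j) = ev[6*i + j];
  return List::create(_["site_bond"] = site_bond, _["lig_count"] = lig_count,
                      _["events"] = events);
}

// Vectorized survival sampler for the per-step breakage scheme: n bonds
// under constant force, per-step breakage probability 1-exp(-koff(F)*dt).
// Returns lifetimes (multiples of dt). Used by the kinetics oracle.
// [[Rcpp::export]]
NumericVector bond_lifetimes_cpp(int n, double koff, double dt, int max_steps) {
  RNGScope scope;
  NumericVector out(n);
  double Pr = 1.0 - std::exp(-koff * dt);
  for (int i = 0; i < n; ++i) {
    int s = 1;
    while (s < max_steps && unif_rand() >= Pr) ++s;
    out[i] = s * dt;
  }
  return out;
}

// ------------------------------------------------------- coupled stepper ---
struct Platelet {
  arma::mat X;            // nv x 3, lattice coords
  arma::imat tris, edges;
  arma::vec rest, S0;
  double area0, V0;
  arma::imat site_tri;    // ns x 1
  arma::vec site_u, site_v;
};

static void site_positions(const Platelet& P, arma::mat& sp) {
  int ns = P.site_tri.n_rows;
  sp.set_size(ns, 3);
  for (int s = 0; s < ns; ++s) {
    int t = P.site_tri(s, 0);
    int i = P.tris(t,0), j = P.tris(t,1), k = P.tris(t,2);
    double u = P.site_u[s], v = P.site_v[s], w = 1.0 - u - v;
    for (int d = 0; d < 3; ++d)
      sp(s, d) = u * P.X(i,d) + v * P.X(j,d) + w * P.X(k,d);
  }
}

// distribute a site force to its triangle's vertices by barycentric weights
static inline void site_force_to_vertices(const Platelet& P, int s,
                                          const double* F, arma::mat& Fv) {
  int t = P.site_tri(s, 0);
  int i = P.tris(t,0), j = P.tris(t,1), k = P.tris(t,2);
  double u = P.site_u[s], v = P.site_v[s], w = 1.0 - u - v;
  for (int d = 0; d < 3; ++d) {
    Fv(i,d) += u * F[d]; Fv(j,d) += v * F[d]; Fv(k,d) += w * F[d];
  }
}

// [[Rcpp::export]]
List run_coupled_cpp(arma::mat f, int nx, int ny, int nz, double tau,
                     NumericVector v_bottom, NumericVector v_top,
                     List platelets, List mech, List adh, List rep,
                     arma::mat ligpos, arma::ivec lig_count,
                     List bond_state, int nsteps, int frame_every,
                     bool record_events, double t0) {
  RNGScope scope;
  int np = platelets.size();
  std::vector<Platelet> P(np);
  for (int p = 0; p < np; ++p) {
    List pl = platelets[p];
    P[p].X = as<arma::mat>(pl["X"]);
    P[p].tris = as<arma::imat>(pl["tris"]);
    P[p].edges = as<arma::imat>(pl["edges"]);
    P[p].rest = as<arma::vec>(pl["rest"]);
    P[p].S0 = as<arma::vec>(pl["S0"]);
    P[p].area0 = as<double>(pl["area0"]);
    P[p].V0 = as<double>(pl["V0"]);
    P[p].site_tri = as<arma::imat>(pl["site_tri"]);
    P[p].site_u = as<arma::vec>(pl["site_u"]);
    P[p].site_v = as<arma::vec>(pl["site_v"]);
  }
  double k_spring = as<double>(mech["k_spring"]), ks = as<double>(mech["ks"]),
         kt = as<double>(mech["kt"]), kv = as<double>(mech["kv"]),
         k0b = as<double>(mech["k0_bend"]);
  double kon0 = as<double>(adh["kon0"]), koff0 = as<double>(adh["koff0"]),
         gbell = as<double>(adh["gbell"]), sigma = as<double>(adh["sigma"]),
         sigma_on = as<double>(adh["sigma_on"]),
         lb = as<double>(adh["lb"]), rbind = as<double>(adh["rbind"]);
  int n_sub = as<int>(adh["n_sub"]), max_per_lig = as<int>(adh["max_per_lig"]);
  double F0tau = as<double>(rep["F0tau"]), taurep = as<double>(rep["taurep"]),
         eps_min = as<double>(rep["eps_min"]), rcut = as<double>(rep["cutoff"]);

  // bond state: per platelet, site_bond vectors; inter-platelet bonds for
  // platelet 0 sites onto platelet 1 sites stored in pp_bond (or -1)
  std::vector<arma::ivec> site_bond(np);
  for (int p = 0; p < np; ++p)
    site_bond[p] = as<arma::ivec>(as<List>(bond_state["wall"])[p]);
  arma::ivec pp_bond = as<arma::ivec>(bond_state["pp"]);   // len = ns of plat 0
  arma::ivec pp_busy = as<arma::ivec>(bond_state["pp_busy"]); // plat 1 sites

  int ncell = nx * ny * nz;
  arma::mat fbuf(19, ncell), gforce(ncell, 3), vel(ncell, 3, arma::fill::zeros);
  std::vector<int> nbr = build_nbr(nx, ny, nz);
  double vb[3] = {v_bottom[0], v_bottom[1], v_bottom[2]};
  double vt[3] = {v_top[0], v_top[1], v_top[2]};
  MembraneOut mo;
  std::vector<arma::mat> sp(np), Fv(np), U(np);
  std::vector<double> events;
  int nframes = nsteps / frame_every + 1;
  arma::mat frames(nframes, 2 + np * 7);
  int fr = 0;

  for (int step = 0; step <= nsteps; ++step) {
    double tnow = t0 + step;
    // (1) membrane + bond + repulsion forces
    gforce.zeros();
    int total_bonds = 0;
    double fbond_sum = 0;
    for (int p = 0; p < np; ++p) {
      membrane_forces_impl(P[p].X, P[p].tris, P[p].edges, P[p].rest, P[p].S0,
                           P[p].area0, P[p].V0, k_spring, ks, kt, kv, k0b,
                           k0b > 0, mo);
      Fv[p] = mo.F_spring + mo.F_area + mo.F_vol + mo.F_bend;
      // wall repulsion on vertices
      int nvp = P[p].X.n_rows;
      for (int i = 0; i < nvp; ++i) {
        double eps = P[p].X(i, 2);
        if (eps < rcut) Fv[p](i, 2) += frep(eps, F0tau, taurep, eps_min);
      }
      site_positions(P[p], sp[p]);
      // wall bond forces
      int ns = sp[p].n_rows;
      for (int s = 0; s < ns; ++s) {
        int l = site_bond[p][s];
        if (l < 0) continue;
        double d[3] = {ligpos(l,0)-sp[p](s,0), ligpos(l,1)-sp[p](s,1),
                       ligpos(l,2)-sp[p](s,2)};
        double xb = std::sqrt(d[0]*d[0]+d[1]*d[1]+d[2]*d[2]);
        if (xb < 1e-12) continue;
        double mag = sigma * (xb - lb);
        double F[3] = {mag*d[0]/xb, mag*d[1]/xb, mag*d[2]/xb};
        site_force_to_vertices(P[p], s, F, Fv[p]);
        total_bonds += 1;
        fbond_sum += std::fabs(mag);
      }
    }
    // platelet-platelet bonds + pairwise vertex repulsion
    if (np == 2) {
      int ns0 = sp[0].n_rows;
      for (int s = 0; s < ns0; ++s) {
        int s2 = pp_bond[s];
        if (s2 < 0) continue;
        double d[3];
        for (int dd = 0; dd < 3; ++dd) d[dd] = sp[1](s2,dd) - sp[0](s,dd);
        double xb = std::sqrt(d[0]*d[0]+d[1]*d[1]+d[2]*d[2]);
        if (xb < 1e-12) continue;
        double mag = sigma * (xb - lb);
        double F0v[3] = {mag*d[0]/xb, mag*d[1]/xb, mag*d[2]/xb};
        double F1v[3] = {-F0v[0], -F0v[1], -F0v[2]};
        site_force_to_vertices(P[0], s, F0v, Fv[0]);
        site_force_to_vertices(P[1], s2, F1v, Fv[1]);
        total_bonds += 1; fbond_sum += std::fabs(mag);
      }
      // nearest-vertex repulsion between the two membranes
      int n0 = P[0].X.n_rows, n1 = P[1].X.n_rows;
      for (int i = 0; i < n0; ++i) {
        double best = rcut * rcut; int jb = -1;
        for (int j = 0; j < n1; ++j) {
          double dx = P[1].X(j,0)-P[0].X(i,0), dy = P[1].X(j,1)-P[0].X(i,1),
                 dz = P[1].X(j,2)-P[0].X(i,2);
          double d2 = dx*dx+dy*dy+dz*dz;
          if (d2 < best) { best = d2; jb = j; }
        }
        if (jb >= 0 && best > 0) {
          double d = std::sqrt(best);
          double mag = frep(d, F0tau, taurep, eps_min);
          for (int dd = 0; dd < 3; ++dd) {
            double dir = (P[0].X(i,dd) - P[1].X(jb,dd)) / d;
            Fv[0](i,dd) += mag * dir;
            Fv[1](jb,dd) -= mag * dir;
          }
        }
      }
    }
    // frame record (pre-update state at t = tnow)
    if (step % frame_every == 0 && fr < nframes) {
      frames(fr, 0) = tnow;
      frames(fr, 1) = total_bonds;
      for (int p = 0; p < np; ++p) {
        arma::rowvec cen = arma::mean(P[p].X, 0);
        arma::mat Xi = P[p].X.each_row() - cen;
        arma::mat C = Xi.t() * Xi;
        arma::vec eval; arma::mat evec;
        arma::eig_sym(eval, evec, C);
        frames(fr, 2 + 7*p + 0) = cen[0];
        frames(fr, 2 + 7*p + 1) = cen[1];
        frames(fr, 2 + 7*p + 2) = cen[2];
        frames(fr, 2 + 7*p + 3) = evec(0, 0);  // minor axis (symmetry axis)
        frames(fr, 2 + 7*p + 4) = evec(1, 0);
        frames(fr, 2 + 7*p + 5) = evec(2, 0);
        frames(fr, 2 + 7*p + 6) = total_bonds > 0 ? fbond_sum / total_bonds : 0;
      }
      ++fr;
    }
    if (step == nsteps) break;
    // (2) spread vertex forces to the fluid grid
    for (int p = 0; p < np; ++p) spread_into(gforce, P[p].X, Fv[p], nx, ny, nz);
    // (3) LBM collide/stream + walls
    lbm_step_once(f, fbuf, nx, ny, nz, tau, gforce, true, vb, vt, nbr);
    // (4) macroscopic velocity where the membranes can sample it (kernel
    // support boxes around the platelets), then interpolate at vertices
    for (int p = 0; p < np; ++p) {
      double lo[3], hi[3];
      for (int d = 0; d < 3; ++d) {
        lo[d] = P[p].X.col(d).min(); hi[d] = P[p].X.col(d).max();
      }
      int zlo = std::max(0, (int)std::floor(lo[2]) - 2);
      int zhi = std::min(nz - 1, (int)std::ceil(hi[2]) + 2);
      int ylo = (int)std::floor(lo[1]) - 2, yhi = (int)std::ceil(hi[1]) + 2;
      int xlo = (int)std::floor(lo[0]) - 2, xhi = (int)std::ceil(hi[0]) + 2;
      for (int z = zlo; z <= zhi; ++z)
        for (int by = ylo; by <= yhi; ++by) {
          int y = ((by % ny) + ny) % ny;
          for (int bx = xlo; bx <= xhi; ++bx) {
            int x = ((bx % nx) + nx) % nx;
            int j = cell(x, y, z, nx, ny);
            double r = 0, mx = 0, my = 0, mz = 0;
            const double* fj = f.colptr(j);
            for (int i = 0; i < 19; ++i) {
              r += fj[i]; mx += CX[i]*fj[i]; my += CY[i]*fj[i]; mz += CZ[i]*fj[i];
            }
            vel(j,0) = (mx + 0.5*gforce(j,0)) / r;
            vel(j,1) = (my + 0.5*gforce(j,1)) / r;
            vel(j,2) = (mz + 0.5*gforce(j,2)) / r;
          }
        }
    }
    for (int p = 0; p < np; ++p) {
      U[p].set_size(P[p].X.n_rows, 3);
      interp_into(U[p], vel, P[p].X, nx, ny, nz);
      // (5) advect vertices, forward Euler (dt = 1 lattice); the walls are
      // impenetrable -- clamp any vertex that would cross a z-face
      P[p].X += U[p];
      for (unsigned i = 0; i < P[p].X.n_rows; ++i) {
        if (P[p].X(i, 2) < 0.05) P[p].X(i, 2) = 0.05;
        if (P[p].X(i, 2) > nz - 1.05) P[p].X(i, 2) = nz - 1.05;
      }
      double vmax = arma::abs(U[p]).max();
      if (vmax > 0.4)
        stop("vertex velocity %g exceeds lattice CFL bound at step %d", vmax, step);
    }
    // (6) adhesion MC every n_sub steps
    if ((step + 1) % n_sub == 0) {
      for (int p = 0; p < np; ++p) {
        site_positions(P[p], sp[p]);
        mc_update_impl(sp[p], site_bond[p], lig_count, ligpos,
                       kon0, koff0, gbell, sigma, sigma_on, lb, rbind,
                       (double)n_sub, max_per_lig,
                       record_events ? &events : 0, tnow);
      }
      if (np == 2) {
        // platelet-platelet bond formation/breakage, same rate laws
        int ns0 = sp[0].n_rows, ns1 = sp[1].n_rows;
        std::vector<std::pair<int,int> > cand;
        for (int s = 0; s < ns0; ++s) {
          if (pp_bond[s] >= 0 || site_bond[0][s] >= 0) continue;
          for (int s2 = 0; s2 < ns1; ++s2) {
            if (pp_busy[s2] || site_bond[1][s2] >= 0) continue;
            double dx = sp[1](s2,0)-sp[0](s,0), dy = sp[1](s2,1)-sp[0](s,1),
                   dz = sp[1](s2,2)-sp[0](s,2);
            if (dx*dx+dy*dy+dz*dz < rbind*rbind)
              cand.push_back(std::make_pair(s, s2));
          }
        }
        int nc = cand.size();
        for (int i = nc - 1; i > 0; --i) {
          int j = (int)std::floor(unif_rand() * (i + 1)); if (j > i) j = i;
          std::swap(cand[i], cand[j]);
        }
        for (int i = 0; i < nc; ++i) {
          int s = cand[i].first, s2 = cand[i].second;
          if (pp_bond[s] >= 0 || pp_busy[s2]) continue;
          double dx = sp[1](s2,0)-sp[0](s,0), dy = sp[1](s2,1)-sp[0](s,1),
                 dz = sp[1](s2,2)-sp[0](s,2);
          double xb = std::sqrt(dx*dx+dy*dy+dz*dz);
          double kon = kon0 * std::exp(-sigma_on*(xb-lb)*(xb-lb)/2.0);
          if (unif_rand() < 1.0 - std::exp(-kon * n_sub)) {
            pp_bond[s] = s2; pp_busy[s2] = 1;
          }
        }
        for (int s = 0; s < ns0; ++s) {
          int s2 = pp_bond[s];
          if (s2 < 0) continue;
          double dx = sp[1](s2,0)-sp[0](s,0), dy = sp[1](s2,1)-sp[0](s,1),
                 dz = sp[1](s2,2)-sp[0](s,2);
          double xb = std::sqrt(dx*dx+dy*dy+dz*dz);
          double Fb = sigma * (xb - lb); if (Fb < 0) Fb = 0;
          double koff = koff0 * std::exp(gbell * Fb);
          if (unif_rand() < 1.0 - std::exp(-koff * n_sub)) {
            pp_busy[s2] = 0; pp_bond[s] = -1;
          }
        }
      }
    }
  }

  List pout(np);
  for (int p = 0; p < np; ++p)
    pout[p] = List::create(_["X"] = P[p].X, _["site_bond"] = site_bond[p]);
  int nev = events.size() / 6;
  NumericMatrix evm(nev, 6);
  for (int i = 0; i < nev; ++i)
    for (int j = 0; j < 6; ++j) evm(i, j) = events[6*i + j];
  return List::create(
    _["f"] = f, _["platelets"] = pout, _["lig_count"] = lig_count,
    _["pp_bond"] = pp_bond, _["pp_busy"] = pp_busy,
    _["frames"] = frames.rows(0, fr - 1), _["events"] = evm,
    _["t_end"] = t0 + nsteps);
}
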