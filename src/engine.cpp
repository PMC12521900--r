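// Tabulated-potential MD engine for bead-spring polymer melts, plus the
// tight numerical kernels used by the distribution and structure analyses.
//
// Unit system (GROMACS-style): length nm, time ps, mass g/mol, energy kJ/mol.
// In these units a = F/m holds directly and k_B = 0.0083145 kJ/mol/K.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstdint>

using namespace Rcpp;

static const double KB = 0.0083145;        // kJ/mol/K
static const double PRESS_UNIT = 16.6054;  // 1 kJ/mol/nm^3 in bar
static const double DEG = 57.29577951308232;

// ---------------------------------------------------------------------------
// deterministic RNG (xorshift64* + Box-Muller), independent of R's RNG
// ---------------------------------------------------------------------------
struct Rng {
  uint64_t s;
  bool have_spare = false;
  double spare = 0.0;
  explicit Rng(uint64_t seed) : s(seed ? seed : 0x9e3779b97f4a7c15ULL) {
    for (int i = 0; i < 8; ++i) next();
  }
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  double unif() {  // (0,1)
    return (next() >> 11) * (1.0 / 9007199254740992.0) + 5e-17;
  }
  double gauss() {
    if (have_spare) { have_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1)), a = 6.283185307179586 * u2;
    spare = r * std::sin(a); have_spare = true;
    return r * std::cos(a);
  }
};

// ---------------------------------------------------------------------------
// natural cubic spline with linear extrapolation of the boundary slope
// ---------------------------------------------------------------------------
struct Spline {
  std::vector<double> x, y, y2;
  int n = 0;
  bool uniform = false;
  double dx = 0.0;

  void build(const NumericVector& xs, const NumericVector& ys) {
    n = xs.size();
    x.assign(xs.begin(), xs.end());
    y.assign(ys.begin(), ys.end());
    y2.assign(n, 0.0);
    if (n < 3) return;
    std::vector<double> u(n, 0.0);
    for (int i = 1; i < n - 1; ++i) {
      double sig = (x[i] - x[i - 1]) / (x[i + 1] - x[i - 1]);
      double p = sig * y2[i - 1] + 2.0;
      y2[i] = (sig - 1.0) / p;
      u[i] = (y[i + 1] - y[i]) / (x[i + 1] - x[i]) -
             (y[i] - y[i - 1]) / (x[i] - x[i - 1]);
      u[i] = (6.0 * u[i] / (x[i + 1] - x[i - 1]) - sig * u[i - 1]) / p;
    }
    for (int k = n - 2; k >= 0; --k) y2[k] = y2[k] * y2[k + 1] + u[k];
    dx = (x[n - 1] - x[0]) / (n - 1);
    uniform = true;
    for (int i = 1; i < n; ++i)
      if (std::fabs(x[i] - x[i - 1] - dx) > 1e-9 * dx) { uniform = false; break; }
  }

  // value and derivative; linear beyond the sampled range
  double eval(double t, double* dy) const {
    if (n == 1) { *dy = 0.0; return y[0]; }
    if (t <= x[0]) {
      double s = slope_at(0);
      *dy = s; return y[0] + s * (t - x[0]);
    }
    if (t >= x[n - 1]) {
      double s = slope_at(n - 1);
      *dy = s; return y[n - 1] + s * (t - x[n - 1]);
    }
    int k;
    if (uniform) {
      k = (int)((t - x[0]) / dx);
      if (k > n - 2) k = n - 2;
    } else {
      int lo = 0, hi = n - 1;
      while (hi - lo > 1) { int m = (lo + hi) / 2; if (x[m] > t) hi = m; else lo = m; }
      k = lo;
    }
    double h = x[k + 1] - x[k];
    double a = (x[k + 1] - t) / h, b = (t - x[k]) / h;
    double val = a * y[k] + b * y[k + 1] +
      ((a * a * a - a) * y2[k] + (b * b * b - b) * y2[k + 1]) * (h * h) / 6.0;
    *dy = (y[k + 1] - y[k]) / h +
      ((3.0 * b * b - 1.0) * y2[k + 1] - (3.0 * a * a - 1.0) * y2[k]) * h / 6.0;
    return val;
  }

  double slope_at(int k) const {
    if (n < 2) return 0.0;
    int j = (k == 0) ? 0 : n - 2;
    double h = x[j + 1] - x[j];
    double b0 = (y[j + 1] - y[j]) / h;
    if (k == 0) return b0 - h * (2.0 * y2[j] + y2[j + 1]) / 6.0;
    return b0 + h * (y2[j] + 2.0 * y2[j + 1]) / 6.0;
  }
};

static inline double mini(double d, double L) { return d - L * std::nearbyint(d / L); }

// ---------------------------------------------------------------------------
// system container
// ---------------------------------------------------------------------------
struct System {
  int n = 0, n_chains = 0;
  std::vector<double> px, py, pz, vx, vy, vz, mass;
  double box[3];
  std::vector<int> chain, mono;   // chain id, index within chain (0-based)
  // bonded tuples (linear chains)
  std::vector<int> b1, b2, a1, a2, a3, d1, d2, d3, d4;
  int excl_bonds = 3;

  bool has_bond = false, has_angle = false, has_dih = false, has_nb = false;
  Spline sp_bond, sp_angle, sp_dih, sp_nb;
  double rcut = 1.5;

  // neighbor list
  double skin = 0.3;
  std::vector<int> nl_i, nl_j;
  std::vector<double> ref_x, ref_y, ref_z;

  void build_tuples() {
    b1.clear(); b2.clear(); a1.clear(); a2.clear(); a3.clear();
    d1.clear(); d2.clear(); d3.clear(); d4.clear();
    for (int i = 0; i + 1 < n; ++i) {
      if (chain[i] != chain[i + 1]) continue;
      b1.push_back(i); b2.push_back(i + 1);
      if (i + 2 < n && chain[i] == chain[i + 2]) {
        a1.push_back(i); a2.push_back(i + 1); a3.push_back(i + 2);
        if (i + 3 < n && chain[i] == chain[i + 3]) {
          d1.push_back(i); d2.push_back(i + 1); d3.push_back(i + 2); d4.push_back(i + 3);
        }
      }
    }
  }

  bool excluded(int i, int j) const {
    return chain[i] == chain[j] && std::abs(mono[i] - mono[j]) <= excl_bonds;
  }

  void build_neighbors() {
    nl_i.clear(); nl_j.clear();
    double rl = rcut + skin, rl2 = rl * rl;
    // cell list
    int cx = std::max(1, (int)(box[0] / rl));
    int cy = std::max(1, (int)(box[1] / rl));
    int cz = std::max(1, (int)(box[2] / rl));
    if ((long)cx * cy * cz < 27 || n < 200) {
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j) {
          if (excluded(i, j)) continue;
          double dx = mini(px[i] - px[j], box[0]);
          double dy = mini(py[i] - py[j], box[1]);
          double dz = mini(pz[i] - pz[j], box[2]);
          if (dx * dx + dy * dy + dz * dz < rl2) { nl_i.push_back(i); nl_j.push_back(j); }
        }
    } else {
      std::vector<std::vector<int> > cells((size_t)cx * cy * cz);
      std::vector<int> ci(n), cj(n), ck(n);
      for (int i = 0; i < n; ++i) {
        double wx = px[i] - box[0] * std::floor(px[i] / box[0]);
        double wy = py[i] - box[1] * std::floor(py[i] / box[1]);
        double wz = pz[i] - box[2] * std::floor(pz[i] / box[2]);
        int a = std::min(cx - 1, (int)(wx / box[0] * cx));
        int b = std::min(cy - 1, (int)(wy / box[1] * cy));
        int c = std::min(cz - 1, (int)(wz / box[2] * cz));
        ci[i] = a; cj[i] = b; ck[i] = c;
        cells[(size_t)(a * cy + b) * cz + c].push_back(i);
      }
      for (int i = 0; i < n; ++i) {
        for (int da = -1; da <= 1; ++da)
          for (int db = -1; db <= 1; ++db)
            for (int dc = -1; dc <= 1; ++dc) {
              int a = (ci[i] + da + cx) % cx, b = (cj[i] + db + cy) % cy,
                  c = (ck[i] + dc + cz) % cz;
              const std::vector<int>& cell = cells[(size_t)(a * cy + b) * cz + c];
              for (size_t q = 0; q < cell.size(); ++q) {
                int j = cell[q];
                if (j <= i || excluded(i, j)) continue;
                double dx = mini(px[i] - px[j], box[0]);
                double dy = mini(py[i] - py[j], box[1]);
                double dz = mini(pz[i] - pz[j], box[2]);
                if (dx * dx + dy * dy + dz * dz < rl2) { nl_i.push_back(i); nl_j.push_back(j); }
              }
            }
      }
    }
    ref_x = px; ref_y = py; ref_z = pz;
  }

  bool need_rebuild() const {
    double half = 0.5 * skin, h2 = half * half;
    for (int i = 0; i < n; ++i) {
      double dx = px[i] - ref_x[i], dy = py[i] - ref_y[i], dz = pz[i] - ref_z[i];
      if (dx * dx + dy * dy + dz * dz > h2) return true;
    }
    return false;
  }

  // forces; returns potential energy, fills fx..fz and virial
  double forces(std::vector<double>& fx, std::vector<double>& fy,
                std::vector<double>& fz, double* virial) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    double pe = 0.0, W = 0.0;

    if (has_nb) {
      double rc2 = rcut * rcut;
      for (size_t p = 0; p < nl_i.size(); ++p) {
        int i = nl_i[p], j = nl_j[p];
        double dx = mini(px[i] - px[j], box[0]);
        double dy = mini(py[i] - py[j], box[1]);
        double dz = mini(pz[i] - pz[j], box[2]);
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 >= rc2) continue;
        double r = std::sqrt(r2), du;
        double u = sp_nb.eval(r, &du);
        pe += u;
        double fr = -du / r;
        fx[i] += fr * dx; fy[i] += fr * dy; fz[i] += fr * dz;
        fx[j] -= fr * dx; fy[j] -= fr * dy; fz[j] -= fr * dz;
        W += -du * r;
      }
    }
    if (has_bond) {
      for (size_t p = 0; p < b1.size(); ++p) {
        int i = b1[p], j = b2[p];
        double dx = mini(px[i] - px[j], box[0]);
        double dy = mini(py[i] - py[j], box[1]);
        double dz = mini(pz[i] - pz[j], box[2]);
        double r = std::sqrt(dx * dx + dy * dy + dz * dz), du;
        pe += sp_bond.eval(r, &du);
        double fr = -du / r;
        fx[i] += fr * dx; fy[i] += fr * dy; fz[i] += fr * dz;
        fx[j] -= fr * dx; fy[j] -= fr * dy; fz[j] -= fr * dz;
        W += -du * r;
      }
    }
    if (has_angle) {
      for (size_t p = 0; p < a1.size(); ++p) {
        int i = a1[p], j = a2[p], k = a3[p];
        double ax = mini(px[i] - px[j], box[0]);
        double ay = mini(py[i] - py[j], box[1]);
        double az = mini(pz[i] - pz[j], box[2]);
        double bx = mini(px[k] - px[j], box[0]);
        double by = mini(py[k] - py[j], box[1]);
        double bz = mini(pz[k] - pz[j], box[2]);
        double la = std::sqrt(ax * ax + ay * ay + az * az);
        double lb = std::sqrt(bx * bx + by * by + bz * bz);
        double cost = (ax * bx + ay * by + az * bz) / (la * lb);
        if (cost > 1.0) cost = 1.0; if (cost < -1.0) cost = -1.0;
        double du_dc;
        pe += sp_angle.eval(cost, &du_dc);     // spline in cos(theta)
        // F = -dU/dcos * grad(cos); regular at collinear configurations
        double c = -du_dc;
        // d cos/d a = b/(la lb) - cost a/la^2, similarly for b
        double fia = c * (bx / (la * lb) - cost * ax / (la * la));
        double fib = c * (by / (la * lb) - cost * ay / (la * la));
        double fic = c * (bz / (la * lb) - cost * az / (la * la));
        double fka = c * (ax / (la * lb) - cost * bx / (lb * lb));
        double fkb = c * (ay / (la * lb) - cost * by / (lb * lb));
        double fkc = c * (az / (la * lb) - cost * bz / (lb * lb));
        fx[i] += fia; fy[i] += fib; fz[i] += fic;
        fx[k] += fka; fy[k] += fkb; fz[k] += fkc;
        fx[j] -= fia + fka; fy[j] -= fib + fkb; fz[j] -= fic + fkc;
        W += fia * ax + fib * ay + fic * az + fka * bx + fkb * by + fkc * bz;
      }
    }
    if (has_dih) {
      // combined bending-torsion form U = T(phi) sin^3(theta1) sin^3(theta2):
      // the sin^3 factors remove the collinear-triple singularity of plain
      // torsions, keeping forces finite and the field exactly conservative
      for (size_t p = 0; p < d1.size(); ++p) {
        int i = d1[p], j = d2[p], k = d3[p], l = d4[p];
        double b1x = mini(px[j] - px[i], box[0]);
        double b1y = mini(py[j] - py[i], box[1]);
        double b1z = mini(pz[j] - pz[i], box[2]);
        double b2x = mini(px[k] - px[j], box[0]);
        double b2y = mini(py[k] - py[j], box[1]);
        double b2z = mini(pz[k] - pz[j], box[2]);
        double b3x = mini(px[l] - px[k], box[0]);
        double b3y = mini(py[l] - py[k], box[1]);
        double b3z = mini(pz[l] - pz[k], box[2]);
        double la = std::sqrt(b1x * b1x + b1y * b1y + b1z * b1z);
        double lb = std::sqrt(b2x * b2x + b2y * b2y + b2z * b2z);
        double lc = std::sqrt(b3x * b3x + b3y * b3y + b3z * b3z);
        double c1 = -(b1x * b2x + b1y * b2y + b1z * b2z) / (la * lb);
        double c2 = -(b2x * b3x + b2y * b3y + b2z * b3z) / (lb * lc);
        if (c1 > 1.0) c1 = 1.0; if (c1 < -1.0) c1 = -1.0;
        if (c2 > 1.0) c2 = 1.0; if (c2 < -1.0) c2 = -1.0;
        double s1sq = 1.0 - c1 * c1, s2sq = 1.0 - c2 * c2;
        if (s1sq < 1e-12 || s2sq < 1e-12) continue;  // S ~ s^3 -> 0 anyway
        double s1 = std::sqrt(s1sq), s2 = std::sqrt(s2sq);
        double S1 = s1sq * s1, S2 = s2sq * s2;       // sin^3

        double mx = b1y * b2z - b1z * b2y, my = b1z * b2x - b1x * b2z,
               mz = b1x * b2y - b1y * b2x;
        double nx = b2y * b3z - b2z * b3y, ny = b2z * b3x - b2x * b3z,
               nz = b2x * b3y - b2y * b3x;
        double m2 = mx * mx + my * my + mz * mz;
        double n2 = nx * nx + ny * ny + nz * nz;
        double cx = my * nz - mz * ny, cy = mz * nx - mx * nz, cz2 = mx * ny - my * nx;
        double sinp = (cx * b2x + cy * b2y + cz2 * b2z) / lb;
        double cosp = mx * nx + my * ny + mz * nz;
        double phi = std::atan2(sinp, cosp);         // radians, (-pi, pi]
        double dT_deg;
        double Tval = sp_dih.eval(phi * DEG, &dT_deg);
        double dT = dT_deg * DEG;                    // dT/dphi per radian
        pe += Tval * S1 * S2;

        // phi gradients
        double gix = -(lb / m2) * mx, giy = -(lb / m2) * my, giz = -(lb / m2) * mz;
        double glx = (lb / n2) * nx, gly = (lb / n2) * ny, glz = (lb / n2) * nz;
        double t = (b1x * b2x + b1y * b2y + b1z * b2z) / (lb * lb);
        double s = (b3x * b2x + b3y * b2y + b3z * b2z) / (lb * lb);
        double gjx = -(1.0 + t) * gix + s * glx;
        double gjy = -(1.0 + t) * giy + s * gly;
        double gjz = -(1.0 + t) * giz + s * glz;
        double gkx = t * gix - (1.0 + s) * glx;
        double gky = t * giy - (1.0 + s) * gly;
        double gkz = t * giz - (1.0 + s) * glz;

        // cos(theta1) gradients; theta1 at j between (i-j) = -b1 and (k-j) = b2
        double a1x = -b1x, a1y = -b1y, a1z = -b1z;
        double d1ix = b2x / (la * lb) - c1 * a1x / (la * la);
        double d1iy = b2y / (la * lb) - c1 * a1y / (la * la);
        double d1iz = b2z / (la * lb) - c1 * a1z / (la * la);
        double d1kx = a1x / (la * lb) - c1 * b2x / (lb * lb);
        double d1ky = a1y / (la * lb) - c1 * b2y / (lb * lb);
        double d1kz = a1z / (la * lb) - c1 * b2z / (lb * lb);
        double d1jx = -(d1ix + d1kx), d1jy = -(d1iy + d1ky), d1jz = -(d1iz + d1kz);

        // cos(theta2) gradients; theta2 at k between (j-k) = -b2 and (l-k) = b3
        double a2x = -b2x, a2y = -b2y, a2z = -b2z;
        double d2jx = b3x / (lb * lc) - c2 * a2x / (lb * lb);
        double d2jy = b3y / (lb * lc) - c2 * a2y / (lb * lb);
        double d2jz = b3z / (lb * lc) - c2 * a2z / (lb * lb);
        double d2lx = a2x / (lb * lc) - c2 * b3x / (lc * lc);
        double d2ly = a2y / (lb * lc) - c2 * b3y / (lc * lc);
        double d2lz = a2z / (lb * lc) - c2 * b3z / (lc * lc);
        double d2kx = -(d2jx + d2lx), d2ky = -(d2jy + d2ly), d2kz = -(d2jz + d2lz);

        // F_x = -[S1 S2 dT g_x + T S2 (-3 s1 c1) dc1_x + T S1 (-3 s2 c2) dc2_x]
        double w_phi = S1 * S2 * dT;
        double w_c1 = -3.0 * Tval * S2 * s1 * c1;
        double w_c2 = -3.0 * Tval * S1 * s2 * c2;
        double fix = -(w_phi * gix + w_c1 * d1ix);
        double fiy = -(w_phi * giy + w_c1 * d1iy);
        double fiz = -(w_phi * giz + w_c1 * d1iz);
        double fjx = -(w_phi * gjx + w_c1 * d1jx + w_c2 * d2jx);
        double fjy = -(w_phi * gjy + w_c1 * d1jy + w_c2 * d2jy);
        double fjz = -(w_phi * gjz + w_c1 * d1jz + w_c2 * d2jz);
        double fkx = -(w_phi * gkx + w_c1 * d1kx + w_c2 * d2kx);
        double fky = -(w_phi * gky + w_c1 * d1ky + w_c2 * d2ky);
        double fkz = -(w_phi * gkz + w_c1 * d1kz + w_c2 * d2kz);
        double flx = -(w_phi * glx + w_c2 * d2lx);
        double fly = -(w_phi * gly + w_c2 * d2ly);
        double flz = -(w_phi * glz + w_c2 * d2lz);
        fx[i] += fix; fy[i] += fiy; fz[i] += fiz;
        fx[j] += fjx; fy[j] += fjy; fz[j] += fjz;
        fx[k] += fkx; fy[k] += fky; fz[k] += fkz;
        fx[l] += flx; fy[l] += fly; fz[l] += flz;
        // atomic virial with positions taken relative to atom i
        double rjx = b1x, rjy = b1y, rjz = b1z;
        double rkx = b1x + b2x, rky = b1y + b2y, rkz = b1z + b2z;
        double rlx = rkx + b3x, rly = rky + b3y, rlz = rkz + b3z;
        W += fjx * rjx + fjy * rjy + fjz * rjz +
             fkx * rkx + fky * rky + fkz * rkz +
             flx * rlx + fly * rly + flz * rlz;
      }
    }
    *virial = W;
    return pe;
  }
};

static void setup_system(System& sys, const NumericMatrix& pos,
                         const NumericMatrix& vel, const NumericVector& mass,
                         const NumericVector& box, const IntegerVector& chain,
                         const IntegerVector& mono, const List& tables,
                         double rcut, int excl_bonds, double skin) {
  sys.n = pos.nrow();
  sys.px.resize(sys.n); sys.py.resize(sys.n); sys.pz.resize(sys.n);
  sys.vx.assign(sys.n, 0.0); sys.vy.assign(sys.n, 0.0); sys.vz.assign(sys.n, 0.0);
  for (int i = 0; i < sys.n; ++i) {
    sys.px[i] = pos(i, 0); sys.py[i] = pos(i, 1); sys.pz[i] = pos(i, 2);
  }
  if (vel.nrow() == sys.n)
    for (int i = 0; i < sys.n; ++i) {
      sys.vx[i] = vel(i, 0); sys.vy[i] = vel(i, 1); sys.vz[i] = vel(i, 2);
    }
  sys.mass.assign(mass.begin(), mass.end());
  for (int d = 0; d < 3; ++d) sys.box[d] = box[d];
  sys.chain.assign(chain.begin(), chain.end());
  sys.mono.assign(mono.begin(), mono.end());
  sys.excl_bonds = excl_bonds;
  sys.rcut = rcut;
  sys.skin = skin;
  sys.build_tuples();

  SEXP tb = tables["bond"], ta = tables["angle"], td = tables["dihedral"],
       tn = tables["nonbonded"];
  if (!Rf_isNull(tb)) {
    List t(tb); sys.sp_bond.build(t["x"], t["U"]); sys.has_bond = true;
  }
  if (!Rf_isNull(ta)) {
    // the angle table arrives in degrees; the engine interpolates U(cos
    // theta), which makes the bending force regular at 0 and 180 degrees
    List t(ta);
    NumericVector th = t["x"], U = t["U"];
    int na = th.size();
    NumericVector cx(na), cu(na);
    for (int i = 0; i < na; ++i) {
      cx[i] = std::cos(th[na - 1 - i] / DEG);   // reversed: increasing in cos
      cu[i] = U[na - 1 - i];
    }
    sys.sp_angle.build(cx, cu);
    sys.has_angle = true;
  }
  if (!Rf_isNull(td)) {
    List t(td); sys.sp_dih.build(t["x"], t["U"]); sys.has_dih = true;
  }
  if (!Rf_isNull(tn)) {
    List t(tn); sys.sp_nb.build(t["x"], t["U"]); sys.has_nb = true;
  }
}

// [[Rcpp::export]]
List cpp_compute_forces(NumericMatrix pos, NumericVector box,
                        IntegerVector chain, IntegerVector mono, List tables,
                        double rcut, int excl_bonds) {
  System sys;
  NumericMatrix novel(0, 3);
  NumericVector mass(pos.nrow(), 1.0);
  setup_system(sys, pos, novel, mass, box, chain, mono, tables, rcut, excl_bonds, 0.0);
  sys.build_neighbors();
  std::vector<double> fx(sys.n), fy(sys.n), fz(sys.n);
  double W;
  double pe = sys.forces(fx, fy, fz, &W);
  if (!std::isfinite(pe))
    stop("non-finite potential energy: configuration outside table support");
  NumericMatrix F(sys.n, 3);
  for (int i = 0; i < sys.n; ++i) { F(i, 0) = fx[i]; F(i, 1) = fy[i]; F(i, 2) = fz[i]; }
  return List::create(_["forces"] = F, _["energy"] = pe, _["virial"] = W);
}

// [[Rcpp::export]]
List cpp_run_md(NumericMatrix pos, NumericMatrix vel, NumericVector mass,
                NumericVector box, IntegerVector chain, IntegerVector mono,
                List tables, List params) {
  System sys;
  setup_system(sys, pos, vel, mass, box, chain, mono, tables,
               as<double>(params["rcut"]), as<int>(params["excl_bonds"]),
               as<double>(params["skin"]));
  double dt = as<double>(params["dt"]);
  int n_steps = as<int>(params["n_steps"]);
  double Ttarget = as<double>(params["temperature"]);   // <= 0: thermostat off
  double friction = as<double>(params["friction"]);     // 1/ps
  double Ptarget = as<double>(params["pressure"]);      // NA: barostat off
  bool use_baro = std::isfinite(Ptarget);
  double tau_p = as<double>(params["tau_p"]);
  double kappa = as<double>(params["kappa"]);           // 1/bar
  int obs_stride = as<int>(params["obs_stride"]);
  int traj_stride = as<int>(params["traj_stride"]);
  int min_steps = as<int>(params["min_steps"]);
  uint64_t seed = (uint64_t)as<double>(params["seed"]);
  double t0 = as<double>(params["time0"]);
  Rng rng(seed * 6364136223846793005ULL + 1442695040888963407ULL);

  int n = sys.n;
  std::vector<double> fx(n), fy(n), fz(n);
  double W = 0.0, pe = 0.0;

  // optional steepest-descent minimization (displacement-capped)
  if (min_steps > 0) {
    double dmax = 0.02;
    for (int it = 0; it < min_steps; ++it) {
      sys.build_neighbors();
      pe = sys.forces(fx, fy, fz, &W);
      double fmax = 0.0;
      for (int i = 0; i < n; ++i) {
        double f = std::sqrt(fx[i] * fx[i] + fy[i] * fy[i] + fz[i] * fz[i]);
        if (f > fmax) fmax = f;
      }
      if (fmax < 10.0) break;
      double scale = dmax / fmax;
      for (int i = 0; i < n; ++i) {
        sys.px[i] += fx[i] * scale; sys.py[i] += fy[i] * scale; sys.pz[i] += fz[i] * scale;
      }
    }
  }

  bool langevin = (Ttarget > 0.0 && friction > 0.0);
  double c1 = langevin ? std::exp(-friction * dt) : 1.0;
  double c2 = langevin ? std::sqrt(1.0 - c1 * c1) : 0.0;

  sys.build_neighbors();
  pe = sys.forces(fx, fy, fz, &W);
  if (!std::isfinite(pe)) stop("engine divergence: non-finite energy at start");

  int n_obs = n_steps / obs_stride + 1;
  NumericMatrix obs(n_obs, 7);  // time KE PE T P density + box edge
  int n_fr = (traj_stride > 0) ? n_steps / traj_stride + 1 : 0;
  List frames(n_fr);
  NumericVector frame_time(n_fr);
  NumericMatrix frame_box(n_fr, 3);
  int io = 0, ifr = 0;

  double half_dt = 0.5 * dt;

  for (int step = 0; step <= n_steps; ++step) {
    double time = t0 + step * dt;
    // observables
    if (step % obs_stride == 0 && io < n_obs) {
      double ke = 0.0;
      for (int i = 0; i < n; ++i)
        ke += 0.5 * sys.mass[i] *
              (sys.vx[i] * sys.vx[i] + sys.vy[i] * sys.vy[i] + sys.vz[i] * sys.vz[i]);
      double V = sys.box[0] * sys.box[1] * sys.box[2];
      double T = 2.0 * ke / (3.0 * n * KB);
      double P = (2.0 * ke / 3.0 + W / 3.0) / V * PRESS_UNIT;
      double mtot = 0.0;
      for (int i = 0; i < n; ++i) mtot += sys.mass[i];
      obs(io, 0) = time; obs(io, 1) = ke; obs(io, 2) = pe; obs(io, 3) = T;
      obs(io, 4) = P; obs(io, 5) = mtot / V * 1.66053906892;  // kg/m^3
      obs(io, 6) = sys.box[0];
      ++io;
    }
    if (traj_stride > 0 && step % traj_stride == 0 && ifr < n_fr) {
      NumericMatrix fr(n, 3);
      for (int i = 0; i < n; ++i) {
        fr(i, 0) = sys.px[i]; fr(i, 1) = sys.py[i]; fr(i, 2) = sys.pz[i];
      }
      frames[ifr] = fr;
      frame_time[ifr] = time;
      frame_box(ifr, 0) = sys.box[0]; frame_box(ifr, 1) = sys.box[1];
      frame_box(ifr, 2) = sys.box[2];
      ++ifr;
    }
    if (step == n_steps) break;

    // B: half kick
    for (int i = 0; i < n; ++i) {
      double s = half_dt / sys.mass[i];
      sys.vx[i] += fx[i] * s; sys.vy[i] += fy[i] * s; sys.vz[i] += fz[i] * s;
    }
    // A: half drift
    for (int i = 0; i < n; ++i) {
      sys.px[i] += sys.vx[i] * half_dt; sys.py[i] += sys.vy[i] * half_dt;
      sys.pz[i] += sys.vz[i] * half_dt;
    }
    // O: Ornstein-Uhlenbeck velocity update (Langevin)
    if (langevin) {
      for (int i = 0; i < n; ++i) {
        double sig = std::sqrt(KB * Ttarget / sys.mass[i]);
        sys.vx[i] = c1 * sys.vx[i] + c2 * sig * rng.gauss();
        sys.vy[i] = c1 * sys.vy[i] + c2 * sig * rng.gauss();
        sys.vz[i] = c1 * sys.vz[i] + c2 * sig * rng.gauss();
      }
    }
    // A: half drift
    double max_v2 = 0.0;
    for (int i = 0; i < n; ++i) {
      sys.px[i] += sys.vx[i] * half_dt; sys.py[i] += sys.vy[i] * half_dt;
      sys.pz[i] += sys.vz[i] * half_dt;
      double d = sys.vx[i] * sys.vx[i] + sys.vy[i] * sys.vy[i] + sys.vz[i] * sys.vz[i];
      if (d > max_v2) max_v2 = d;
    }
    if (sys.has_nb && sys.skin > 0 && std::sqrt(max_v2) * dt > sys.skin)
      stop("integration unstable: per-step displacement exceeds the neighbor-list skin at step %d",
           step + 1);
    if (sys.has_nb && sys.need_rebuild()) sys.build_neighbors();

    pe = sys.forces(fx, fy, fz, &W);
    if (!std::isfinite(pe))
      stop("engine divergence: non-finite energy at step %d", step + 1);
    // B: half kick
    for (int i = 0; i < n; ++i) {
      double s = half_dt / sys.mass[i];
      sys.vx[i] += fx[i] * s; sys.vy[i] += fy[i] * s; sys.vz[i] += fz[i] * s;
    }

    // isotropic weak-coupling barostat
    if (use_baro) {
      double ke = 0.0;
      for (int i = 0; i < n; ++i)
        ke += 0.5 * sys.mass[i] *
              (sys.vx[i] * sys.vx[i] + sys.vy[i] * sys.vy[i] + sys.vz[i] * sys.vz[i]);
      double V = sys.box[0] * sys.box[1] * sys.box[2];
      double P = (2.0 * ke / 3.0 + W / 3.0) / V * PRESS_UNIT;
      double mu = std::cbrt(1.0 - kappa * dt / tau_p * (Ptarget - P));
      if (mu < 0.98) mu = 0.98; if (mu > 1.02) mu = 1.02;
      for (int d = 0; d < 3; ++d) sys.box[d] *= mu;
      for (int i = 0; i < n; ++i) { sys.px[i] *= mu; sys.py[i] *= mu; sys.pz[i] *= mu; }
      if (std::fabs(mu - 1.0) > 1e-6) sys.build_neighbors();
    }
  }

  NumericMatrix outp(n, 3), outv(n, 3);
  for (int i = 0; i < n; ++i) {
    outp(i, 0) = sys.px[i]; outp(i, 1) = sys.py[i]; outp(i, 2) = sys.pz[i];
    outv(i, 0) = sys.vx[i]; outv(i, 1) = sys.vy[i]; outv(i, 2) = sys.vz[i];
  }
  NumericVector outb(3);
  for (int d = 0; d < 3; ++d) outb[d] = sys.box[d];
  return List::create(_["positions"] = outp, _["velocities"] = outv,
                      _["box"] = outb, _["time"] = t0 + n_steps * dt,
                      _["observables"] = obs, _["frames"] = frames,
                      _["frame_time"] = frame_time, _["frame_box"] = frame_box);
}

// ---------------------------------------------------------------------------
// analysis kernels
// ---------------------------------------------------------------------------

// pair-distance histogram for the monomeric RDF (counts only; the R side
// normalizes by ideal-gas shell counts)
// [[Rcpp::export]]
NumericVector cpp_rdf_count(NumericMatrix pos, NumericVector box,
                            IntegerVector chain, IntegerVector mono,
                            int excl_bonds, double r_max, int n_bins) {
  int n = pos.nrow();
  NumericVector counts(n_bins);
  double dr = r_max / n_bins, r2max = r_max * r_max;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      if (chain[i] == chain[j] && std::abs(mono[i] - mono[j]) <= excl_bonds) continue;
      double dx = mini(pos(i, 0) - pos(j, 0), box[0]);
      double dy = mini(pos(i, 1) - pos(j, 1), box[1]);
      double dz = mini(pos(i, 2) - pos(j, 2), box[2]);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= r2max) continue;
      int b = (int)(std::sqrt(r2) / dr);
      if (b >= 0 && b < n_bins) counts[b] += 2.0;   // both orderings
    }
  return counts;
}

// mean squared internal distance per index separation, one frame;
// positions must be ordered chain-by-chain, npc particles per chain
// [[Rcpp::export]]
List cpp_internal_profile(NumericMatrix pos, int n_chains, int npc) {
  NumericVector sumsq(npc - 1);
  NumericVector cnt(npc - 1);
  for (int c = 0; c < n_chains; ++c) {
    int off = c * npc;
    for (int i = 0; i < npc; ++i)
      for (int j = i + 1; j < npc; ++j) {
        double dx = pos(off + j, 0) - pos(off + i, 0);
        double dy = pos(off + j, 1) - pos(off + i, 1);
        double dz = pos(off + j, 2) - pos(off + i, 2);
        sumsq[j - i - 1] += dx * dx + dy * dy + dz * dz;
        cnt[j - i - 1] += 1.0;
      }
  }
  return List::create(_["sumsq"] = sumsq, _["count"] = cnt);
}

// isotropic single-chain form factor (Debye sum), averaged over chains
// [[Rcpp::export]]
NumericVector cpp_debye(NumericMatrix pos, int n_chains, int npc, NumericVector q) {
  int nq = q.size();
  NumericVector W(nq);
  for (int c = 0; c < n_chains; ++c) {
    int off = c * npc;
    for (int i = 0; i < npc; ++i)
      for (int j = i + 1; j < npc; ++j) {
        double dx = pos(off + j, 0) - pos(off + i, 0);
        double dy = pos(off + j, 1) - pos(off + i, 1);
        double dz = pos(off + j, 2) - pos(off + i, 2);
        double r = std::sqrt(dx * dx + dy * dy + dz * dz);
        for (int m = 0; m < nq; ++m) {
          double x = q[m] * r;
          W[m] += 2.0 * std::sin(x) / x;
        }
      }
  }
  // add self terms (npc per chain), normalize per chain and per particle
  for (int m = 0; m < nq; ++m)
    W[m] = (W[m] / n_chains + npc) / ((double)npc * npc);
  return W;
}

// bending angles (degrees) for index triples; minimum-image bonded vectors
// [[Rcpp::export]]
NumericVector cpp_angles(NumericMatrix pos, NumericVector box,
                         IntegerMatrix triples) {
  int m = triples.nrow();
  NumericVector out(m);
  for (int p = 0; p < m; ++p) {
    int i = triples(p, 0), j = triples(p, 1), k = triples(p, 2);
    double ax = mini(pos(i, 0) - pos(j, 0), box[0]);
    double ay = mini(pos(i, 1) - pos(j, 1), box[1]);
    double az = mini(pos(i, 2) - pos(j, 2), box[2]);
    double bx = mini(pos(k, 0) - pos(j, 0), box[0]);
    double by = mini(pos(k, 1) - pos(j, 1), box[1]);
    double bz = mini(pos(k, 2) - pos(j, 2), box[2]);
    double la = std::sqrt(ax * ax + ay * ay + az * az);
    double lb = std::sqrt(bx * bx + by * by + bz * bz);
    if (la < 1e-12 || lb < 1e-12) { out[p] = NA_REAL; continue; }
    double cost = (ax * bx + ay * by + az * bz) / (la * lb);
    if (cost > 1.0) cost = 1.0; if (cost < -1.0) cost = -1.0;
    out[p] = std::acos(cost) * DEG;
  }
  return out;
}

// signed dihedrals (degrees, IUPAC: cis = 0, trans = 180) for index quadruples
// [[Rcpp::export]]
NumericVector cpp_dihedrals(NumericMatrix pos, NumericVector box,
                            IntegerMatrix quads) {
  int m = quads.nrow();
  NumericVector out(m);
  for (int p = 0; p < m; ++p) {
    int i = quads(p, 0), j = quads(p, 1), k = quads(p, 2), l = quads(p, 3);
    double b1x = mini(pos(j, 0) - pos(i, 0), box[0]);
    double b1y = mini(pos(j, 1) - pos(i, 1), box[1]);
    double b1z = mini(pos(j, 2) - pos(i, 2), box[2]);
    double b2x = mini(pos(k, 0) - pos(j, 0), box[0]);
    double b2y = mini(pos(k, 1) - pos(j, 1), box[1]);
    double b2z = mini(pos(k, 2) - pos(j, 2), box[2]);
    double b3x = mini(pos(l, 0) - pos(k, 0), box[0]);
    double b3y = mini(pos(l, 1) - pos(k, 1), box[1]);
    double b3z = mini(pos(l, 2) - pos(k, 2), box[2]);
    double mx = b1y * b2z - b1z * b2y, my = b1z * b2x - b1x * b2z,
           mz = b1x * b2y - b1y * b2x;
    double nx = b2y * b3z - b2z * b3y, ny = b2z * b3x - b2x * b3z,
           nz = b2x * b3y - b2y * b3x;
    double m2 = mx * mx + my * my + mz * mz;
    double n2 = nx * nx + ny * ny + nz * nz;
    if (m2 < 1e-18 || n2 < 1e-18) { out[p] = NA_REAL; continue; }
    double lb2 = std::sqrt(b2x * b2x + b2y * b2y + b2z * b2z);
    double cx = my * nz - mz * ny, cy = mz * nx - mx * nz, cz = mx * ny - my * nx;
    double sinp = (cx * b2x + cy * b2y + cz * b2z) / lb2;
    double cosp = mx * nx + my * ny + mz * nz;
    out[p] = std::atan2(sinp, cosp) * DEG;
  }
  return out;
}
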