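// Coarse-grained bead-spring engine: species-resolved truncated LJ, FENE
// bonds, Coulomb electrostatics (Ewald, direct lattice sum, damped
// shifted-force), Verlet/cell neighbor lists, BAOAB Langevin and overdamped
// Brownian integrators. Reduced units: sigma = m = kBT(ref) = 1.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <random>
#include <cstdint>

using namespace Rcpp;

static const double TWO_PI = 6.283185307179586476925286766559;
static const double SQRT_PI = 1.7724538509055160272981674833411;

struct FF {
  double eps_poly, eps_ci, rcut_poly, rcut_ci;
  bool lj_shift;
  double fene_k, fene_R0;
  double lB;
  int coul_method;      // 0 none, 1 dsf, 2 ewald
  double coul_rcut, dsf_alpha, ewald_accuracy;
  double cap;           // max pair force magnitude; 0 = off
  // precomputed
  double shift_poly, shift_ci, rc2_poly, rc2_ci, R02;
  double dsf_eshift, dsf_fshift, rc2_coul;
  // species-pair lookup (index = sp_i | sp_j: 0 monomer-monomer, 1 counterion)
  double t_eps[2], t_rc2[2], t_shift[2];
};

static FF parse_ff(const List& ff) {
  FF p;
  p.eps_poly = as<double>(ff["eps_poly"]);
  p.eps_ci = as<double>(ff["eps_ci"]);
  p.rcut_poly = as<double>(ff["rcut_poly"]);
  p.rcut_ci = as<double>(ff["rcut_ci"]);
  p.lj_shift = as<bool>(ff["lj_shift"]);
  p.fene_k = as<double>(ff["fene_k"]);
  p.fene_R0 = as<double>(ff["fene_R0"]);
  p.lB = as<double>(ff["lB"]);
  p.coul_method = as<int>(ff["coul_method"]);
  p.coul_rcut = as<double>(ff["coul_rcut"]);
  p.dsf_alpha = as<double>(ff["dsf_alpha"]);
  p.ewald_accuracy = as<double>(ff["ewald_accuracy"]);
  p.cap = as<double>(ff["cap"]);
  auto ulj = [](double eps, double r2) {
    double inv6 = 1.0 / (r2 * r2 * r2);
    return 4.0 * eps * (inv6 * inv6 - inv6);
  };
  p.rc2_poly = p.rcut_poly * p.rcut_poly;
  p.rc2_ci = p.rcut_ci * p.rcut_ci;
  p.shift_poly = p.lj_shift ? ulj(p.eps_poly, p.rc2_poly) : 0.0;
  p.shift_ci = p.lj_shift ? ulj(p.eps_ci, p.rc2_ci) : 0.0;
  p.R02 = p.fene_R0 * p.fene_R0;
  double a = p.dsf_alpha, rc = p.coul_rcut;
  p.rc2_coul = rc * rc;
  p.dsf_fshift = std::erfc(a * rc) / (rc * rc) +
                 2.0 * a / SQRT_PI * std::exp(-a * a * rc * rc) / rc;
  p.dsf_eshift = std::erfc(a * rc) / rc;
  p.t_eps[0] = p.eps_poly; p.t_eps[1] = p.eps_ci;
  p.t_rc2[0] = p.rc2_poly; p.t_rc2[1] = p.rc2_ci;
  p.t_shift[0] = p.shift_poly; p.t_shift[1] = p.shift_ci;
  return p;
}

// finite boxes only (callers substitute a huge box for open boundaries)
static inline void mi3(double* d, const double* box, const double* inv) {
  d[0] -= box[0] * std::nearbyint(d[0] * inv[0]);
  d[1] -= box[1] * std::nearbyint(d[1] * inv[1]);
  d[2] -= box[2] * std::nearbyint(d[2] * inv[2]);
}

static inline void sanitize_box(double* b) {
  for (int k = 0; k < 3; ++k) if (!std::isfinite(b[k])) b[k] = 1e12;
}

// rational erfc approximation (Abramowitz & Stegun 7.1.26, |err| < 1.5e-7)
// given x >= 0 and ex = exp(-x^2); avoids a second transcendental per pair
static inline double erfc_fast(double x, double ex) {
  double t = 1.0 / (1.0 + 0.3275911 * x);
  return t * (0.254829592 + t * (-0.284496736 + t * (1.421413741 +
         t * (-1.453152027 + t * 1.061405429)))) * ex;
}

static inline void min_image(double* d, const double* box) {
  for (int k = 0; k < 3; ++k) {
    if (std::isfinite(box[k])) d[k] -= box[k] * std::round(d[k] / box[k]);
  }
}

// ---------------------------------------------------------------------------
// Neighbor lists (half pair lists over an index subset, built by cell binning
// with brute-force fallback when the box holds fewer than 3 cells per axis)

struct PairList {
  std::vector<int> ii, jj;       // global particle indices, half list
  std::vector<double> ref;       // subset positions at build time
  std::vector<int> subset;
  double rlist;

  void build(const std::vector<double>& pos, const double* box) {
    ii.clear(); jj.clear();
    const int n = (int)subset.size();
    ref.resize(3 * n);
    for (int a = 0; a < n; ++a)
      for (int k = 0; k < 3; ++k) ref[3 * a + k] = pos[3 * subset[a] + k];

    int nc[3]; bool cells_ok = true;
    for (int k = 0; k < 3; ++k) {
      nc[k] = std::isfinite(box[k]) ? (int)std::floor(box[k] / rlist) : 0;
      if (nc[k] < 3) cells_ok = false;
    }
    const double rl2 = rlist * rlist;
    if (!cells_ok || n < 64) {
      for (int a = 0; a < n; ++a) {
        for (int b = a + 1; b < n; ++b) {
          double d[3];
          for (int k = 0; k < 3; ++k) d[k] = ref[3 * a + k] - ref[3 * b + k];
          min_image(d, box);
          if (d[0] * d[0] + d[1] * d[1] + d[2] * d[2] < rl2) {
            ii.push_back(subset[a]); jj.push_back(subset[b]);
          }
        }
      }
      return;
    }
    int ncell = nc[0] * nc[1] * nc[2];
    std::vector<int> head(ncell, -1), nxt(n, -1), cell_of(n);
    auto cidx = [&](double x, double L, int m) {
      double w = x / L;
      w -= std::floor(w);            // wrap to [0,1)
      int c = (int)(w * m); if (c >= m) c = m - 1; if (c < 0) c = 0;
      return c;
    };
    for (int a = 0; a < n; ++a) {
      int cx = cidx(ref[3 * a], box[0], nc[0]);
      int cy = cidx(ref[3 * a + 1], box[1], nc[1]);
      int cz = cidx(ref[3 * a + 2], box[2], nc[2]);
      int c = (cx * nc[1] + cy) * nc[2] + cz;
      cell_of[a] = c; nxt[a] = head[c]; head[c] = a;
    }
    // half stencil: self cell (a<b) + 13 neighbor cells
    static const int st[13][3] = {
      {1,0,0},{0,1,0},{0,0,1},{1,1,0},{1,-1,0},{1,0,1},{1,0,-1},
      {0,1,1},{0,1,-1},{1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}};
    for (int cx = 0; cx < nc[0]; ++cx)
    for (int cy = 0; cy < nc[1]; ++cy)
    for (int cz = 0; cz < nc[2]; ++cz) {
      int c = (cx * nc[1] + cy) * nc[2] + cz;
      for (int a = head[c]; a != -1; a = nxt[a]) {
        for (int b = nxt[a]; b != -1; b = nxt[b]) {
          double d[3];
          for (int k = 0; k < 3; ++k) d[k] = ref[3 * a + k] - ref[3 * b + k];
          min_image(d, box);
          if (d[0] * d[0] + d[1] * d[1] + d[2] * d[2] < rl2) {
            ii.push_back(subset[a]); jj.push_back(subset[b]);
          }
        }
      }
      for (int s = 0; s < 13; ++s) {
        int dx = (cx + st[s][0] + nc[0]) % nc[0];
        int dy = (cy + st[s][1] + nc[1]) % nc[1];
        int dz = (cz + st[s][2] + nc[2]) % nc[2];
        int c2 = (dx * nc[1] + dy) * nc[2] + dz;
        for (int a = head[c]; a != -1; a = nxt[a]) {
          for (int b = head[c2]; b != -1; b = nxt[b]) {
            double d[3];
            for (int k = 0; k < 3; ++k) d[k] = ref[3 * a + k] - ref[3 * b + k];
            min_image(d, box);
            if (d[0] * d[0] + d[1] * d[1] + d[2] * d[2] < rl2) {
              ii.push_back(subset[a]); jj.push_back(subset[b]);
            }
          }
        }
      }
    }
  }

  bool stale(const std::vector<double>& pos, double skin) const {
    const double lim2 = 0.25 * skin * skin;
    for (size_t a = 0; a < subset.size(); ++a) {
      double s = 0;
      for (int k = 0; k < 3; ++k) {
        double d = pos[3 * subset[a] + k] - ref[3 * a + k];
        s += d * d;
      }
      if (s > lim2) return true;
    }
    return false;
  }
};

// ---------------------------------------------------------------------------
// Ewald summation (tinfoil boundary conditions), energy and forces

struct EwaldPlan {
  double alpha, rcut;
  int nmax[3];
};

static EwaldPlan ewald_plan(const double* box, double accuracy, double rcut) {
  EwaldPlan pl;
  double minL = std::min(box[0], std::min(box[1], box[2]));
  pl.rcut = (rcut > 0) ? rcut : 0.49 * minL;
  if (pl.rcut > 0.5 * minL) pl.rcut = 0.49 * minL;
  // erfc(s)/rcut ~ accuracy  =>  s from erfc(s) ~ exp(-s^2)/(s sqrt(pi))
  double s = 3.0;
  for (int it = 0; it < 20; ++it)
    s = std::sqrt(std::max(1.0, -std::log(accuracy * SQRT_PI * std::max(s, 1.0))));
  pl.alpha = s / pl.rcut;
  double kcut = 2.0 * pl.alpha * s;
  for (int k = 0; k < 3; ++k)
    pl.nmax[k] = std::max(1, (int)std::ceil(kcut * box[k] / TWO_PI));
  return pl;
}

// accumulate Ewald energy and (optionally) forces; q in e, lengths in sigma
static double ewald_full(const std::vector<double>& pos, const std::vector<double>& q,
                         const double* box, double lB, double accuracy, double rcut,
                         std::vector<double>* force) {
  const int n = (int)pos.size() / 3;
  EwaldPlan pl = ewald_plan(box, accuracy, rcut);
  const double a = pl.alpha;
  double e_real = 0.0, e_self = 0.0, qtot = 0.0;
  for (int i = 0; i < n; ++i) { e_self -= a / SQRT_PI * q[i] * q[i]; qtot += q[i]; }
  if (std::fabs(qtot) > 1e-9)
    stop("Ewald summation requires a charge-neutral system (net charge %f e)", qtot);
  const double rc2 = pl.rcut * pl.rcut;
  for (int i = 0; i < n; ++i) {
    if (q[i] == 0) continue;
    for (int j = i + 1; j < n; ++j) {
      if (q[j] == 0) continue;
      double d[3];
      for (int k = 0; k < 3; ++k) d[k] = pos[3 * i + k] - pos[3 * j + k];
      min_image(d, box);
      double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
      if (r2 >= rc2) continue;
      double r = std::sqrt(r2);
      double qq = q[i] * q[j];
      e_real += qq * std::erfc(a * r) / r;
      if (force) {
        double fr = qq * (std::erfc(a * r) / r2 +
                          2.0 * a / SQRT_PI * std::exp(-a * a * r2) / r) / r;
        for (int k = 0; k < 3; ++k) {
          (*force)[3 * i + k] += lB * fr * d[k];
          (*force)[3 * j + k] -= lB * fr * d[k];
        }
      }
    }
  }
  // reciprocal space
  double V = box[0] * box[1] * box[2];
  double e_rec = 0.0;
  std::vector<double> kr(n);
  for (int nx = -pl.nmax[0]; nx <= pl.nmax[0]; ++nx)
  for (int ny = -pl.nmax[1]; ny <= pl.nmax[1]; ++ny)
  for (int nz = -pl.nmax[2]; nz <= pl.nmax[2]; ++nz) {
    if (nx == 0 && ny == 0 && nz == 0) continue;
    double kx = TWO_PI * nx / box[0], ky = TWO_PI * ny / box[1], kz = TWO_PI * nz / box[2];
    double k2 = kx * kx + ky * ky + kz * kz;
    double Ak = std::exp(-k2 / (4.0 * a * a)) / k2;
    if (Ak < 1e-16) continue;
    double sre = 0.0, sim = 0.0;
    for (int i = 0; i < n; ++i) {
      if (q[i] == 0) { kr[i] = 0; continue; }
      kr[i] = kx * pos[3 * i] + ky * pos[3 * i + 1] + kz * pos[3 * i + 2];
      sre += q[i] * std::cos(kr[i]);
      sim += q[i] * std::sin(kr[i]);
    }
    e_rec += Ak * (sre * sre + sim * sim);
    if (force) {
      double pref = lB * (4.0 * M_PI / V) * Ak;
      for (int i = 0; i < n; ++i) {
        if (q[i] == 0) continue;
        double g = pref * q[i] * (std::sin(kr[i]) * sre - std::cos(kr[i]) * sim);
        (*force)[3 * i] += g * kx;
        (*force)[3 * i + 1] += g * ky;
        (*force)[3 * i + 2] += g * kz;
      }
    }
  }
  e_rec *= TWO_PI / V;
  return lB * (e_real + e_rec + e_self);
}

// [[Rcpp::export]]
double cpp_coulomb_ewald(NumericMatrix pos, NumericVector q, NumericVector box,
                         double lB, double accuracy, double rcut = 0.0) {
  const int n = pos.nrow();
  std::vector<double> p(3 * n), qq(n);
  for (int i = 0; i < n; ++i) {
    p[3 * i] = pos(i, 0); p[3 * i + 1] = pos(i, 1); p[3 * i + 2] = pos(i, 2);
    qq[i] = q[i];
  }
  double b[3] = {box[0], box[1], box[2]};
  return ewald_full(p, qq, b, lB, accuracy, rcut, nullptr);
}

// Brute-force lattice sum over cubic image shells |n_k| <= nshells
// (independent oracle; converges for neutral, zero-dipole configurations).
// nshells = 0 with an infinite box gives the plain open-boundary pair sum.
// [[Rcpp::export]]
double cpp_coulomb_direct(NumericMatrix pos, NumericVector q, NumericVector box,
                          double lB, int nshells = 0) {
  const int n = pos.nrow();
  double e = 0.0;
  for (int nx = -nshells; nx <= nshells; ++nx)
  for (int ny = -nshells; ny <= nshells; ++ny)
  for (int nz = -nshells; nz <= nshells; ++nz) {
    // guard 0 * Inf for open-boundary (infinite box) pair sums
    double sh[3] = {nx == 0 ? 0.0 : nx * box[0],
                    ny == 0 ? 0.0 : ny * box[1],
                    nz == 0 ? 0.0 : nz * box[2]};
    bool origin = (nx == 0 && ny == 0 && nz == 0);
    for (int i = 0; i < n; ++i) {
      if (q[i] == 0) continue;
      for (int j = 0; j < n; ++j) {
        if (origin && j <= i) continue;
        if (!origin && j < 0) continue;
        if (q[j] == 0) continue;
        double dx = pos(i, 0) - pos(j, 0) + sh[0];
        double dy = pos(i, 1) - pos(j, 1) + sh[1];
        double dz = pos(i, 2) - pos(j, 2) + sh[2];
        double r = std::sqrt(dx * dx + dy * dy + dz * dz);
        double w = origin ? 1.0 : 0.5;   // image pairs counted twice
        e += w * q[i] * q[j] / r;
      }
    }
  }
  return lB * e;
}

// ---------------------------------------------------------------------------
// Force evaluation

struct Energies { double lj, fene, coul; };

static void compute_forces(const std::vector<double>& pos,
                           const std::vector<int>& species,
                           const std::vector<double>& q,
                           const std::vector<int>& bond_i,
                           const std::vector<int>& bond_j,
                           const double* box, const FF& p,
                           const PairList& lj_list, const PairList& coul_list,
                           bool use_lists,
                           std::vector<double>& force, Energies& en) {
  const int n = (int)pos.size() / 3;
  std::fill(force.begin(), force.end(), 0.0);
  en.lj = en.fene = en.coul = 0.0;
  const double inv[3] = {1.0 / box[0], 1.0 / box[1], 1.0 / box[2]};

  auto lj_pair = [&](int i, int j) {
    double d[3] = {pos[3 * i] - pos[3 * j],
                   pos[3 * i + 1] - pos[3 * j + 1],
                   pos[3 * i + 2] - pos[3 * j + 2]};
    mi3(d, box, inv);
    double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
    int t = species[i] | species[j];
    if (r2 >= p.t_rc2[t]) return;
    if (r2 < 1e-12) {
      if (p.cap <= 0) stop("overlapping beads %d and %d (r < 1e-6 sigma)", i + 1, j + 1);
      r2 = 1e-12;
    }
    double eps = p.t_eps[t];
    double inv2 = 1.0 / r2;
    double inv6 = inv2 * inv2 * inv2;
    en.lj += 4.0 * eps * (inv6 * inv6 - inv6) - p.t_shift[t];
    double fr = 24.0 * eps * (2.0 * inv6 * inv6 - inv6) * inv2;
    if (p.cap > 0) {
      double fmag = std::fabs(fr) * std::sqrt(r2);
      if (fmag > p.cap) fr *= p.cap / fmag;
    }
    force[3 * i] += fr * d[0]; force[3 * j] -= fr * d[0];
    force[3 * i + 1] += fr * d[1]; force[3 * j + 1] -= fr * d[1];
    force[3 * i + 2] += fr * d[2]; force[3 * j + 2] -= fr * d[2];
  };

  auto dsf_pair = [&](int i, int j) {
    double d[3] = {pos[3 * i] - pos[3 * j],
                   pos[3 * i + 1] - pos[3 * j + 1],
                   pos[3 * i + 2] - pos[3 * j + 2]};
    mi3(d, box, inv);
    double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
    if (r2 >= p.rc2_coul) return;
    double r = std::sqrt(r2);
    double qq = q[i] * q[j];
    double a = p.dsf_alpha;
    double ex = std::exp(-a * a * r2);
    double ec = erfc_fast(a * r, ex);
    en.coul += p.lB * qq * (ec / r - p.dsf_eshift +
                            p.dsf_fshift * (r - p.coul_rcut));
    double fr = p.lB * qq * (ec / r2 + 2.0 * a / SQRT_PI * ex / r -
                             p.dsf_fshift) / r;
    force[3 * i] += fr * d[0]; force[3 * j] -= fr * d[0];
    force[3 * i + 1] += fr * d[1]; force[3 * j + 1] -= fr * d[1];
    force[3 * i + 2] += fr * d[2]; force[3 * j + 2] -= fr * d[2];
  };

  if (use_lists) {
    for (size_t m = 0; m < lj_list.ii.size(); ++m) lj_pair(lj_list.ii[m], lj_list.jj[m]);
  } else {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) lj_pair(i, j);
  }

  // FENE bonds
  for (size_t m = 0; m < bond_i.size(); ++m) {
    int i = bond_i[m], j = bond_j[m];
    double d[3];
    for (int k = 0; k < 3; ++k) d[k] = pos[3 * i + k] - pos[3 * j + k];
    mi3(d, box, inv);
    double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
    if (r2 >= p.R02) {
      stop("FENE bond %d-%d broken: r = %.4f sigma >= R0 = %.2f sigma",
           i + 1, j + 1, std::sqrt(r2), p.fene_R0);
    }
    double w = 1.0 - r2 / p.R02;
    en.fene += -0.5 * p.fene_k * p.R02 * std::log(w);
    double fr = -p.fene_k / w;
    for (int k = 0; k < 3; ++k) {
      force[3 * i + k] += fr * d[k];
      force[3 * j + k] -= fr * d[k];
    }
  }

  if (p.coul_method == 1) {
    if (use_lists) {
      for (size_t m = 0; m < coul_list.ii.size(); ++m)
        dsf_pair(coul_list.ii[m], coul_list.jj[m]);
    } else {
      for (int i = 0; i < n; ++i) {
        if (q[i] == 0) continue;
        for (int j = i + 1; j < n; ++j) {
          if (q[j] == 0) continue;
          dsf_pair(i, j);
        }
      }
    }
  } else if (p.coul_method == 2) {
    en.coul = ewald_full(pos, q, box, p.lB, p.ewald_accuracy, p.coul_rcut, &force);
  }
}

static void fill_state(const NumericMatrix& pos, const IntegerVector& species,
                       const NumericVector& q, const IntegerMatrix& bonds,
                       std::vector<double>& p, std::vector<int>& sp,
                       std::vector<double>& qq,
                       std::vector<int>& bi, std::vector<int>& bj) {
  const int n = pos.nrow();
  p.resize(3 * n); sp.resize(n); qq.resize(n);
  for (int i = 0; i < n; ++i) {
    p[3 * i] = pos(i, 0); p[3 * i + 1] = pos(i, 1); p[3 * i + 2] = pos(i, 2);
    sp[i] = species[i]; qq[i] = q[i];
  }
  const int nb = bonds.nrow();
  bi.resize(nb); bj.resize(nb);
  for (int m = 0; m < nb; ++m) { bi[m] = bonds(m, 0) - 1; bj[m] = bonds(m, 1) - 1; }
}

// [[Rcpp::export]]
List cpp_forces(NumericMatrix pos, IntegerVector species, NumericVector q,
                IntegerMatrix bonds, NumericVector box, List ff,
                bool use_neighbor_lists = true) {
  FF p = parse_ff(ff);
  std::vector<double> P, Q; std::vector<int> S, BI, BJ;
  fill_state(pos, species, q, bonds, P, S, Q, BI, BJ);
  const int n = pos.nrow();
  double b[3] = {box[0], box[1], box[2]};
  sanitize_box(b);
  PairList ljl, cl;
  if (use_neighbor_lists) {
    ljl.rlist = std::max(p.rcut_poly, p.rcut_ci);
    ljl.subset.resize(n);
    for (int i = 0; i < n; ++i) ljl.subset[i] = i;
    ljl.build(P, b);
    if (p.coul_method == 1) {
      cl.rlist = p.coul_rcut;
      for (int i = 0; i < n; ++i) if (Q[i] != 0) cl.subset.push_back(i);
      cl.build(P, b);
    }
  }
  std::vector<double> F(3 * n);
  Energies en;
  compute_forces(P, S, Q, BI, BJ, b, p, ljl, cl, use_neighbor_lists, F, en);
  NumericMatrix Fm(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) Fm(i, k) = F[3 * i + k];
  return List::create(_["force"] = Fm,
                      _["e_lj"] = en.lj, _["e_fene"] = en.fene,
                      _["e_coul"] = en.coul,
                      _["e_pot"] = en.lj + en.fene + en.coul);
}

// ---------------------------------------------------------------------------
// Langevin / Brownian dynamics

// [[Rcpp::export]]
List cpp_run_langevin(NumericMatrix pos, NumericMatrix vel, IntegerVector species,
                      NumericVector q, IntegerMatrix bonds, NumericVector box,
                      List ff, int nsteps, double dt, double gamma, double kT,
                      double mass, int seed, int frame_every = 0,
                      int log_every = 0, double tether_k = 0.0,
                      int integrator = 0) {
  FF p = parse_ff(ff);
  std::vector<double> P, Q; std::vector<int> S, BI, BJ;
  const int n = pos.nrow();
  P.resize(3 * n); S.resize(n); Q.resize(n);
  std::vector<double> V(3 * n), anchor;
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < 3; ++k) {
      P[3 * i + k] = pos(i, k);
      V[3 * i + k] = vel(i, k);
    }
    S[i] = species[i]; Q[i] = q[i];
  }
  const int nbnd = bonds.nrow();
  BI.resize(nbnd); BJ.resize(nbnd);
  for (int m = 0; m < nbnd; ++m) { BI[m] = bonds(m, 0) - 1; BJ[m] = bonds(m, 1) - 1; }
  if (tether_k > 0) anchor = P;

  double b[3] = {box[0], box[1], box[2]};
  sanitize_box(b);
  const double skin_lj = 0.7, skin_coul = 1.4;
  PairList ljl, cl;
  ljl.rlist = std::max(p.rcut_poly, p.rcut_ci) + skin_lj;
  ljl.subset.resize(n);
  for (int i = 0; i < n; ++i) ljl.subset[i] = i;
  ljl.build(P, b);
  bool have_coul = (p.coul_method == 1);
  if (have_coul) {
    cl.rlist = p.coul_rcut + skin_coul;
    for (int i = 0; i < n; ++i) if (Q[i] != 0) cl.subset.push_back(i);
    if (cl.subset.empty()) have_coul = false;
    else cl.build(P, b);
  }

  std::mt19937_64 rng((uint64_t)seed);
  std::normal_distribution<double> gauss(0.0, 1.0);
  std::vector<double> F(3 * n);
  Energies en;
  compute_forces(P, S, Q, BI, BJ, b, p, ljl, cl, true, F, en);
  auto add_tether = [&]() {
    if (tether_k <= 0) return;
    for (int i = 0; i < 3 * n; ++i) {
      F[i] += -tether_k * (P[i] - anchor[i]);
    }
  };
  add_tether();

  const double c1 = std::exp(-gamma * dt);
  const double c2 = std::sqrt(std::max(0.0, (1.0 - c1 * c1)) * kT / mass);
  const double bd_mob = dt / (gamma * mass);
  const double bd_noise = std::sqrt(2.0 * kT * dt / (gamma * mass));

  std::vector<NumericMatrix> frames;
  std::vector<int> frame_steps;
  std::vector<double> log_step, log_lj, log_fene, log_coul, log_kin;
  auto log_now = [&](int step) {
    double ekin = 0;
    for (int i = 0; i < 3 * n; ++i) ekin += 0.5 * mass * V[i] * V[i];
    log_step.push_back(step); log_lj.push_back(en.lj); log_fene.push_back(en.fene);
    log_coul.push_back(en.coul); log_kin.push_back(ekin);
  };
  if (log_every > 0) log_now(0);

  for (int step = 1; step <= nsteps; ++step) {
    if (integrator == 0) {
      // BAOAB splitting: one force evaluation per step
      for (int i = 0; i < 3 * n; ++i) V[i] += 0.5 * dt * F[i] / mass;
      for (int i = 0; i < 3 * n; ++i) P[i] += 0.5 * dt * V[i];
      for (int i = 0; i < 3 * n; ++i) V[i] = c1 * V[i] + c2 * gauss(rng);
      for (int i = 0; i < 3 * n; ++i) P[i] += 0.5 * dt * V[i];
      if (ljl.stale(P, skin_lj) || (have_coul && cl.stale(P, skin_coul))) {
        ljl.build(P, b);
        if (have_coul) cl.build(P, b);
      }
      compute_forces(P, S, Q, BI, BJ, b, p, ljl, cl, true, F, en);
      add_tether();
      for (int i = 0; i < 3 * n; ++i) V[i] += 0.5 * dt * F[i] / mass;
    } else {
      // overdamped (inertialess) Brownian step
      for (int i = 0; i < 3 * n; ++i) P[i] += bd_mob * F[i] + bd_noise * gauss(rng);
      if (ljl.stale(P, skin_lj) || (have_coul && cl.stale(P, skin_coul))) {
        ljl.build(P, b);
        if (have_coul) cl.build(P, b);
      }
      compute_forces(P, S, Q, BI, BJ, b, p, ljl, cl, true, F, en);
      add_tether();
    }
    if (frame_every > 0 && step % frame_every == 0) {
      NumericMatrix fr(n, 3);
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k) fr(i, k) = P[3 * i + k];
      frames.push_back(fr);
      frame_steps.push_back(step);
    }
    if (log_every > 0 && step % log_every == 0) log_now(step);
    if (step % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix Pm(n, 3), Vm(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) { Pm(i, k) = P[3 * i + k]; Vm(i, k) = V[3 * i + k]; }
  List fl(frames.size());
  for (size_t m = 0; m < frames.size(); ++m) fl[m] = frames[m];
  return List::create(
    _["pos"] = Pm, _["vel"] = Vm, _["frames"] = fl,
    _["frame_steps"] = wrap(frame_steps),
    _["log"] = DataFrame::create(_["step"] = wrap(log_step), _["e_lj"] = wrap(log_lj),
                                 _["e_fene"] = wrap(log_fene), _["e_coul"] = wrap(log_coul),
                                 _["e_kin"] = wrap(log_kin)));
}

// ---------------------------------------------------------------------------
// Small geometry helpers

// minimum-image distance from each row of `a` to the nearest row of `b`
// [[Rcpp::export]]
NumericVector cpp_min_dist_to_set(NumericMatrix a, NumericMatrix b, NumericVector box) {
  const int na = a.nrow(), nb = b.nrow();
  double bx[3] = {box[0], box[1], box[2]};
  NumericVector out(na);
  for (int i = 0; i < na; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < nb; ++j) {
      double d[3] = {a(i, 0) - b(j, 0), a(i, 1) - b(j, 1), a(i, 2) - b(j, 2)};
      min_image(d, bx);
      double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
      if (r2 < best) best = r2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// connectivity-based unwrapping: BFS over bonds, each bead placed at the
// minimum image relative to its parent; beads beyond n_net are left alone
// [[Rcpp::export]]
NumericMatrix cpp_unwrap(NumericMatrix pos, IntegerMatrix bonds, NumericVector box,
                         int n_net) {
  const int n = pos.nrow(), nb = bonds.nrow();
  double bx[3] = {box[0], box[1], box[2]};
  NumericMatrix out = clone(pos);
  std::vector<std::vector<int>> adj(n_net);
  for (int m = 0; m < nb; ++m) {
    int i = bonds(m, 0) - 1, j = bonds(m, 1) - 1;
    if (i < n_net && j < n_net) { adj[i].push_back(j); adj[j].push_back(i); }
  }
  std::vector<char> seen(n_net, 0);
  std::vector<int> queue;
  for (int root = 0; root < n_net; ++root) {
    if (seen[root]) continue;
    seen[root] = 1;
    queue.clear(); queue.push_back(root);
    size_t h = 0;
    while (h < queue.size()) {
      int i = queue[h++];
      for (int j : adj[i]) {
        if (seen[j]) continue;
        seen[j] = 1;
        double d[3] = {out(j, 0) - out(i, 0), out(j, 1) - out(i, 1), out(j, 2) - out(i, 2)};
        min_image(d, bx);
        for (int k = 0; k < 3; ++k) out(j, k) = out(i, k) + d[k];
        queue.push_back(j);
      }
    }
  }
  return out;
}
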