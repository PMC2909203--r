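#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double DEG = M_PI / 180.0;

// Ideal backbone geometry (Angstrom / degrees); mirrors R/constants.R GEOM.
static const double B_N_CA = 1.458, B_CA_C = 1.525, B_C_N = 1.329;
static const double B_C_O = 1.231, B_CA_CB = 1.521;
static const double A_N_CA_C = 111.2, A_CA_C_N = 116.2, A_C_N_CA = 121.7;
static const double A_CA_C_O = 120.5, A_C_CA_CB = 110.5;
static const double T_N_C_CA_CB = -122.6; // improper fixing CB chirality (L)
static const double OMEGA = 180.0;

static inline void cross3(const double *a, const double *b, double *o) {
  o[0] = a[1] * b[2] - a[2] * b[1];
  o[1] = a[2] * b[0] - a[0] * b[2];
  o[2] = a[0] * b[1] - a[1] * b[0];
}

static inline void norm3(double *v) {
  double n = std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
  v[0] /= n; v[1] /= n; v[2] /= n;
}

// Place atom D bonded to C such that |CD| = bond, angle(B,C,D) = ang and
// dihedral(A,B,C,D) = tor (degrees). Standard NeRF construction.
static void place_atom(const double *A, const double *B, const double *C,
                       double bond, double ang, double tor, double *D) {
  double a = ang * DEG, t = -tor * DEG; // sign: IUPAC dihedral(A,B,C,D) = tor
  double d2[3] = {-bond * std::cos(a),
                  bond * std::sin(a) * std::cos(t),
                  bond * std::sin(a) * std::sin(t)};
  double bc[3] = {C[0] - B[0], C[1] - B[1], C[2] - B[2]};
  norm3(bc);
  double ab[3] = {B[0] - A[0], B[1] - A[1], B[2] - A[2]};
  double n[3];
  cross3(ab, bc, n);
  norm3(n);
  double m[3];
  cross3(n, bc, m);
  for (int k = 0; k < 3; ++k)
    D[k] = C[k] + bc[k] * d2[0] + m[k] * d2[1] + n[k] * d2[2];
}

// Atom layout per residue: N, CA, C, O, then CB when has_cb.
static int chain_natoms(const LogicalVector &has_cb) {
  int n = 0;
  for (int i = 0; i < has_cb.size(); ++i) n += has_cb[i] ? 5 : 4;
  return n;
}

static void residue_offsets(const LogicalVector &has_cb,
                            std::vector<int> &off) {
  int n = has_cb.size(), at = 0;
  off.resize(n);
  for (int i = 0; i < n; ++i) { off[i] = at; at += has_cb[i] ? 5 : 4; }
}

static void build_chain(const double *phi, const double *psi, int n,
                        const LogicalVector &has_cb, double *xyz) {
  std::vector<int> off;
  residue_offsets(has_cb, off);
  double *N0 = xyz + 3 * off[0];
  double *CA0 = N0 + 3, *C0 = N0 + 6;
  N0[0] = 0; N0[1] = 0; N0[2] = 0;
  CA0[0] = B_N_CA; CA0[1] = 0; CA0[2] = 0;
  double a = A_N_CA_C * DEG;
  C0[0] = CA0[0] - B_CA_C * std::cos(a);
  C0[1] = B_CA_C * std::sin(a);
  C0[2] = 0;
  for (int i = 0; i < n; ++i) {
    double *N = xyz + 3 * off[i];
    double *CA = N + 3, *C = N + 6, *O = N + 9;
    if (i > 0) {
      double *Np = xyz + 3 * off[i - 1];
      double *CAp = Np + 3, *Cp = Np + 6;
      place_atom(Np, CAp, Cp, B_C_N, A_CA_C_N, psi[i - 1], N);
      place_atom(CAp, Cp, N, B_N_CA, A_C_N_CA, OMEGA, CA);
      place_atom(Cp, N, CA, B_CA_C, A_N_CA_C, phi[i], C);
    }
    place_atom(N, CA, C, B_C_O, A_CA_C_O, psi[i] + 180.0, O);
    if (has_cb[i]) place_atom(N, C, CA, B_CA_CB, A_C_CA_CB, T_N_C_CA_CB, O + 3);
  }
}

// [[Rcpp::export(name = ".nerf_chain")]]
NumericMatrix nerf_chain(NumericVector phi, NumericVector psi,
                         LogicalVector has_cb) {
  int n = phi.size();
  if (psi.size() != n || has_cb.size() != n)
    stop("phi, psi, has_cb must have equal length");
  int na = chain_natoms(has_cb);
  std::vector<double> xyz(3 * na);
  build_chain(phi.begin(), psi.begin(), n, has_cb, xyz.data());
  NumericMatrix out(na, 3);
  for (int i = 0; i < na; ++i)
    for (int k = 0; k < 3; ++k) out(i, k) = xyz[3 * i + k];
  return out;
}

// Soft-sphere clash penalty via a cell list (cell edge > largest contact
// distance, 0.9 * (1.8 + 1.8) = 3.24 A). Optionally collects the active
// (overlapping) pairs and their dE/dd / d coefficients for the gradient.
static double soft_vdw_xyz(const double *xyz, int na,
                           const NumericVector &radii,
                           const IntegerVector &resno,
                           std::vector<int> *pa = 0, std::vector<int> *pb = 0,
                           std::vector<double> *pref = 0) {
  const double CELL = 3.4;
  if (na == 0) return 0.0;
  double mn[3] = {1e30, 1e30, 1e30}, mx[3] = {-1e30, -1e30, -1e30};
  for (int i = 0; i < na; ++i) {
    for (int k = 0; k < 3; ++k) {
      double v = xyz[3 * i + k];
      if (v < mn[k]) mn[k] = v;
      if (v > mx[k]) mx[k] = v;
    }
  }
  int ncell[3];
  for (int k = 0; k < 3; ++k) {
    ncell[k] = (int)((mx[k] - mn[k]) / CELL) + 1;
    if (ncell[k] < 1) ncell[k] = 1;
  }
  int ntot = ncell[0] * ncell[1] * ncell[2];
  std::vector<int> head(ntot, -1), nxt(na);
  std::vector<int> ci(na), cj(na), ck(na);
  for (int i = 0; i < na; ++i) {
    ci[i] = (int)((xyz[3 * i] - mn[0]) / CELL);
    cj[i] = (int)((xyz[3 * i + 1] - mn[1]) / CELL);
    ck[i] = (int)((xyz[3 * i + 2] - mn[2]) / CELL);
    int c = (ci[i] * ncell[1] + cj[i]) * ncell[2] + ck[i];
    nxt[i] = head[c];
    head[c] = i;
  }
  double e = 0;
  for (int i = 0; i < na; ++i) {
    for (int dx = -1; dx <= 1; ++dx) {
      int x = ci[i] + dx;
      if (x < 0 || x >= ncell[0]) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        int y = cj[i] + dy;
        if (y < 0 || y >= ncell[1]) continue;
        for (int dz = -1; dz <= 1; ++dz) {
          int z = ck[i] + dz;
          if (z < 0 || z >= ncell[2]) continue;
          int c = (x * ncell[1] + y) * ncell[2] + z;
          for (int j = head[c]; j != -1; j = nxt[j]) {
            if (j <= i) continue;
            int sep = resno[j] - resno[i];
            if (sep < 0) sep = -sep;
            if (sep < 2) continue;
            double s = 0.9 * (radii[i] + radii[j]);
            double ddx = xyz[3 * i] - xyz[3 * j];
            double ddy = xyz[3 * i + 1] - xyz[3 * j + 1];
            double ddz = xyz[3 * i + 2] - xyz[3 * j + 2];
            double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
            if (d2 >= s * s || d2 < 1e-18) continue;
            double d = std::sqrt(d2);
            double v = s - d;
            e += v * v;
            if (pa) {
              pa->push_back(i);
              pb->push_back(j);
              pref->push_back(-2.0 * v / d);
            }
          }
        }
      }
    }
  }
  return e;
}

// [[Rcpp::export(name = ".soft_vdw")]]
double soft_vdw(NumericMatrix coords, NumericVector radii,
                IntegerVector resno) {
  int na = coords.nrow();
  std::vector<double> xyz(3 * na);
  for (int i = 0; i < na; ++i)
    for (int k = 0; k < 3; ++k) xyz[3 * i + k] = coords(i, k);
  return soft_vdw_xyz(xyz.data(), na, radii, resno);
}

static double constraint_energy(const double *xyz, const IntegerVector &ai,
                                const IntegerVector &aj,
                                const NumericVector &target,
                                const NumericVector &weight) {
  double e = 0;
  for (int c = 0; c < ai.size(); ++c) {
    int i = ai[c], j = aj[c];
    double dx = xyz[3 * i] - xyz[3 * j];
    double dy = xyz[3 * i + 1] - xyz[3 * j + 1];
    double dz = xyz[3 * i + 2] - xyz[3 * j + 2];
    double d = std::sqrt(dx * dx + dy * dy + dz * dz) - target[c];
    e += weight[c] * d * d;
  }
  return e;
}

// [[Rcpp::export(name = ".restraint_energy")]]
double restraint_energy(NumericMatrix coords, IntegerVector ai,
                        IntegerVector aj, NumericVector target,
                        NumericVector weight) {
  int na = coords.nrow();
  std::vector<double> xyz(3 * na);
  for (int i = 0; i < na; ++i)
    for (int k = 0; k < 3; ++k) xyz[3 * i + k] = coords(i, k);
  return constraint_energy(xyz.data(), ai, aj, target, weight);
}

// Draw a (phi, psi) pair from the cumulative bin distribution of one class.
static void draw_torsion(const double *cum, int nbin2, int nb, double binw,
                         double *phi, double *psi) {
  double u = unif_rand();
  int lo = 0, hi = nbin2 - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (cum[mid] < u) lo = mid + 1; else hi = mid;
  }
  int pb = lo / nb, sb = lo % nb;
  *phi = -180.0 + binw * (pb + unif_rand());
  *psi = -180.0 + binw * (sb + unif_rand());
}

// Objective shared by the annealer and the minimizer.
struct Objective {
  const LogicalVector &has_cb;
  const NumericVector &radii;
  const IntegerVector &resno;
  const IntegerVector &ai, &aj;
  const NumericVector &target, &weight;
  int n, na;
  std::vector<int> off;
  std::vector<int> atom_res;
  std::vector<double> xyz;
  Objective(const LogicalVector &hcb, const NumericVector &rad,
            const IntegerVector &rn, const IntegerVector &a,
            const IntegerVector &b, const NumericVector &t,
            const NumericVector &w)
      : has_cb(hcb), radii(rad), resno(rn), ai(a), aj(b), target(t),
        weight(w) {
    n = hcb.size();
    residue_offsets(hcb, off);
    na = chain_natoms(hcb);
    atom_res.resize(na);
    for (int i = 0; i < n; ++i)
      for (int k = off[i]; k < (i + 1 < n ? off[i + 1] : na); ++k)
        atom_res[k] = i;
    xyz.resize(3 * na);
  }
  double eval(const double *phi, const double *psi) {
    build_chain(phi, psi, n, has_cb, xyz.data());
    return soft_vdw_xyz(xyz.data(), na, radii, resno) +
           constraint_energy(xyz.data(), ai, aj, target, weight);
  }
};

// Analytic gradient of the restraint+clash objective with respect to the
// torsions, exploiting that a torsion only changes distances that cross
// its rotation axis. Assumes obj.xyz holds the current geometry.
static void torsion_gradient(Objective &obj, double *gphi, double *gpsi) {
  int n = obj.n;
  const double *xyz = obj.xyz.data();
  for (int i = 0; i < n; ++i) { gphi[i] = 0; gpsi[i] = 0; }
  std::vector<int> pa, pb;
  std::vector<double> pref; // dE/dd / d coefficients
  for (int c = 0; c < obj.ai.size(); ++c) {
    int a = obj.ai[c], b = obj.aj[c];
    double dx = xyz[3 * a] - xyz[3 * b];
    double dy = xyz[3 * a + 1] - xyz[3 * b + 1];
    double dz = xyz[3 * a + 2] - xyz[3 * b + 2];
    double d = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (d < 1e-9) continue;
    pa.push_back(a);
    pb.push_back(b);
    pref.push_back(2.0 * obj.weight[c] * (d - obj.target[c]) / d);
  }
  soft_vdw_xyz(xyz, obj.na, obj.radii, obj.resno, &pa, &pb, &pref);
  // note: stored torsions are IUPAC dihedrals, which place_atom applies
  // with a negated rotation sense; the right-hand derivative below is
  // therefore negated at the end
  for (size_t c = 0; c < pa.size(); ++c) {
    int a = pa[c], b = pb[c];
    if (obj.atom_res[a] > obj.atom_res[b]) { int t = a; a = b; b = t; }
    int ra = obj.atom_res[a], rb = obj.atom_res[b];
    const double *xa = xyz + 3 * a, *xb = xyz + 3 * b;
    double rab[3] = {xb[0] - xa[0], xb[1] - xa[1], xb[2] - xa[2]};
    for (int i = ra; i <= rb && i < n; ++i) {
      int base = obj.off[i];
      int ca_idx = base + 1, c_idx = base + 2, o_idx = base + 3;
      // phi_i moves atoms k > ca_idx; psi_i moves O_i and k >= off[i+1]
      bool a_phi = a > ca_idx, b_phi = b > ca_idx;
      if (a_phi != b_phi) {
        const double *pN = xyz + 3 * base, *pCA = xyz + 3 * ca_idx;
        double ax[3] = {pCA[0] - pN[0], pCA[1] - pN[1], pCA[2] - pN[2]};
        norm3(ax);
        const double *mv = b_phi ? xb : xa;
        double r[3] = {mv[0] - pCA[0], mv[1] - pCA[1], mv[2] - pCA[2]};
        double cr[3];
        cross3(ax, r, cr);
        double dd = cr[0] * rab[0] + cr[1] * rab[1] + cr[2] * rab[2];
        if (!b_phi) dd = -dd;
        gphi[i] += pref[c] * dd;
      }
      bool a_psi = (a == o_idx) || (i + 1 < n && a >= obj.off[i + 1]);
      bool b_psi = (b == o_idx) || (i + 1 < n && b >= obj.off[i + 1]);
      if (a_psi != b_psi) {
        const double *pCA = xyz + 3 * ca_idx, *pC = xyz + 3 * c_idx;
        double ax[3] = {pC[0] - pCA[0], pC[1] - pCA[1], pC[2] - pCA[2]};
        norm3(ax);
        const double *mv = b_psi ? xb : xa;
        double r[3] = {mv[0] - pC[0], mv[1] - pC[1], mv[2] - pC[2]};
        double cr[3];
        cross3(ax, r, cr);
        double dd = cr[0] * rab[0] + cr[1] * rab[1] + cr[2] * rab[2];
        if (!b_psi) dd = -dd;
        gpsi[i] += pref[c] * dd;
      }
    }
  }
  for (int i = 0; i < n; ++i) { gphi[i] = -gphi[i]; gpsi[i] = -gpsi[i]; }
}

// L-BFGS (two-loop recursion, Armijo backtracking line search) on the
// 2n torsion variables (degrees); the objective never increases.
static double minimize_inner(std::vector<double> &phi,
                             std::vector<double> &psi, Objective &obj,
                             int iters) {
  int n = obj.n;
  int dim = 2 * n;
  const int M = 8;
  const double D2R = M_PI / 180.0;
  std::vector<double> x(dim), g(dim), gphi(n), gpsi(n);
  for (int i = 0; i < n; ++i) { x[i] = phi[i]; x[n + i] = psi[i]; }
  auto fval = [&](const std::vector<double> &v) {
    return obj.eval(v.data(), v.data() + n);
  };
  auto grad = [&](std::vector<double> &go) {
    // obj.xyz must correspond to the current point
    torsion_gradient(obj, gphi.data(), gpsi.data());
    for (int i = 0; i < n; ++i) {
      go[i] = gphi[i] * D2R;     // per-degree derivatives
      go[n + i] = gpsi[i] * D2R;
    }
  };
  double u = fval(x);
  grad(g);
  std::vector<std::vector<double> > sk(M, std::vector<double>(dim)),
      yk(M, std::vector<double>(dim));
  std::vector<double> rho(M);
  int mem = 0, head = 0;
  std::vector<double> d(dim), xnew(dim), gnew(dim), alpha(M);
  for (int it = 0; it < iters; ++it) {
    double gn = 0;
    for (int i = 0; i < dim; ++i) gn += g[i] * g[i];
    if (gn < 1e-14) break;
    // two-loop recursion
    for (int i = 0; i < dim; ++i) d[i] = -g[i];
    double gamma = 1.0;
    for (int q = 0; q < mem; ++q) {
      int idx = (head - 1 - q + M * 2) % M;
      double a = 0;
      for (int i = 0; i < dim; ++i) a += sk[idx][i] * d[i];
      a *= rho[idx];
      alpha[q] = a;
      for (int i = 0; i < dim; ++i) d[i] -= a * yk[idx][i];
    }
    if (mem > 0) {
      int idx = (head - 1 + M) % M;
      double sy = 0, yy = 0;
      for (int i = 0; i < dim; ++i) {
        sy += sk[idx][i] * yk[idx][i];
        yy += yk[idx][i] * yk[idx][i];
      }
      if (yy > 1e-16) gamma = sy / yy;
    }
    for (int i = 0; i < dim; ++i) d[i] *= gamma;
    for (int q = mem - 1; q >= 0; --q) {
      int idx = (head - 1 - q + M * 2) % M;
      double bq = 0;
      for (int i = 0; i < dim; ++i) bq += yk[idx][i] * d[i];
      bq *= rho[idx];
      for (int i = 0; i < dim; ++i) d[i] += (alpha[q] - bq) * sk[idx][i];
    }
    double gd = 0;
    for (int i = 0; i < dim; ++i) gd += g[i] * d[i];
    if (gd > -1e-14) { // not a descent direction: restart from -g
      mem = 0;
      for (int i = 0; i < dim; ++i) d[i] = -g[i];
      gd = -gn;
    }
    // cap the step so no torsion jumps more than ~25 degrees at once
    double dmax = 0;
    for (int i = 0; i < dim; ++i) dmax = std::max(dmax, std::fabs(d[i]));
    double cap = dmax > 25.0 ? 25.0 / dmax : 1.0;
    double t = cap;
    bool moved = false;
    for (int ls = 0; ls < 30; ++ls) {
      for (int i = 0; i < dim; ++i) xnew[i] = x[i] + t * d[i];
      double ut = fval(xnew);
      if (ut <= u + 1e-4 * t * gd) {
        grad(gnew);
        int idx = head % M;
        double sy = 0;
        for (int i = 0; i < dim; ++i) {
          sk[idx][i] = xnew[i] - x[i];
          yk[idx][i] = gnew[i] - g[i];
          sy += sk[idx][i] * yk[idx][i];
        }
        if (sy > 1e-12) {
          rho[idx] = 1.0 / sy;
          head = (head + 1) % M;
          if (mem < M) ++mem;
        }
        x.swap(xnew);
        g.swap(gnew);
        u = ut;
        moved = true;
        break;
      }
      t *= 0.5;
    }
    if (!moved) break;
  }
  for (int i = 0; i < n; ++i) { phi[i] = x[i]; psi[i] = x[n + i]; }
  obj.eval(phi.data(), psi.data()); // leave obj.xyz in sync
  return u;
}

// [[Rcpp::export(name = ".torsion_minimize")]]
List torsion_minimize(NumericVector phi0, NumericVector psi0,
                      LogicalVector has_cb, NumericVector radii,
                      IntegerVector resno, IntegerVector ai,
                      IntegerVector aj, NumericVector target,
                      NumericVector weight, int iters) {
  Objective obj(has_cb, radii, resno, ai, aj, target, weight);
  std::vector<double> phi(phi0.begin(), phi0.end());
  std::vector<double> psi(psi0.begin(), psi0.end());
  double u_init = obj.eval(phi.data(), psi.data());
  double u = minimize_inner(phi, psi, obj, iters);
  return List::create(_["phi"] = NumericVector(phi.begin(), phi.end()),
                      _["psi"] = NumericVector(psi.begin(), psi.end()),
                      _["u_init"] = u_init, _["u_final"] = u);
}

// Metropolis simulated annealing in (phi, psi) space: proposal replaces
// one residue's torsions with a prior draw (or, with probability
// jitter_prob, a small Gaussian nudge). Uses R's RNG.
// [[Rcpp::export(name = ".anneal_torsions")]]
List anneal_torsions(NumericVector phi0, NumericVector psi0,
                     LogicalVector has_cb, IntegerVector resclass,
                     NumericMatrix prior_cum, NumericVector radii,
                     IntegerVector resno, IntegerVector ai, IntegerVector aj,
                     NumericVector target, NumericVector weight,
                     int steps, double t_start, double t_end,
                     double jitter_prob = 0.0, double jitter_sd = 8.0) {
  int n = phi0.size();
  int nbin2 = prior_cum.nrow();
  int nb = (int)std::lround(std::sqrt((double)nbin2));
  double binw = 360.0 / nb;
  Objective obj(has_cb, radii, resno, ai, aj, target, weight);
  std::vector<double> phi(phi0.begin(), phi0.end());
  std::vector<double> psi(psi0.begin(), psi0.end());
  double u_cur = obj.eval(phi.data(), psi.data());
  double u_init = u_cur;
  std::vector<double> best_phi(phi), best_psi(psi);
  double u_best = u_cur;
  long accepted = 0;
  for (int step = 0; step < steps; ++step) {
    double frac = steps > 1 ? (double)step / (steps - 1) : 1.0;
    double T = t_start * std::pow(t_end / t_start, frac);
    int r = (int)(unif_rand() * n);
    if (r >= n) r = n - 1;
    double old_phi = phi[r], old_psi = psi[r];
    if (unif_rand() < jitter_prob) {
      phi[r] = old_phi + norm_rand() * jitter_sd;
      psi[r] = old_psi + norm_rand() * jitter_sd;
    } else {
      double np_, ns_;
      const double *cum = &prior_cum(0, resclass[r]);
      draw_torsion(cum, nbin2, nb, binw, &np_, &ns_);
      phi[r] = np_;
      psi[r] = ns_;
    }
    double u_trial = obj.eval(phi.data(), psi.data());
    bool accept = u_trial <= u_cur ||
                  unif_rand() < std::exp(-(u_trial - u_cur) / T);
    if (accept) {
      u_cur = u_trial;
      ++accepted;
      if (u_cur < u_best) {
        u_best = u_cur;
        best_phi.assign(phi.begin(), phi.end());
        best_psi.assign(psi.begin(), psi.end());
      }
    } else {
      phi[r] = old_phi;
      psi[r] = old_psi;
    }
  }
  return List::create(_["phi"] = NumericVector(best_phi.begin(), best_phi.end()),
                      _["psi"] = NumericVector(best_psi.begin(), best_psi.end()),
                      _["u_init"] = u_init, _["u_final"] = u_best,
                      _["accepted"] = (double)accepted);
}

// One full model search: extended chain -> one Metropolis sweep of
// prior-drawn torsions per residue (infinite-temperature limit) ->
// gradient minimization -> basin hopping (prior-redraw of 1-2 residues,
// re-minimize, Metropolis accept on a geometric temperature ladder) ->
// deep final polish. Deterministic under R's RNG.
// [[Rcpp::export(name = ".build_model_search")]]
List build_model_search(LogicalVector has_cb, IntegerVector resclass,
                        NumericMatrix prior_cum, NumericVector radii,
                        IntegerVector resno, IntegerVector ai,
                        IntegerVector aj, NumericVector target,
                        NumericVector weight, int n_hops, int iters_hop,
                        int iters_final, double t_hop_start,
                        double t_hop_end) {
  int n = has_cb.size();
  int nbin2 = prior_cum.nrow();
  int nb = (int)std::lround(std::sqrt((double)nbin2));
  double binw = 360.0 / nb;
  Objective obj(has_cb, radii, resno, ai, aj, target, weight);
  std::vector<double> phi(n, 180.0), psi(n, 180.0);
  double u_init = obj.eval(phi.data(), psi.data());
  // move every residue to its class's modal torsion bin (jittered within
  // the bin): the locally most probable conformation under the prior,
  // from which the basin hops explore
  for (int r = 0; r < n; ++r) {
    const double *cum = &prior_cum(0, resclass[r]);
    int bestb = 0;
    double bestp = cum[0];
    for (int bq = 1; bq < nbin2; ++bq) {
      double pq = cum[bq] - cum[bq - 1];
      if (pq > bestp) { bestp = pq; bestb = bq; }
    }
    int pb = bestb / nb, sb = bestb % nb;
    phi[r] = -180.0 + binw * (pb + unif_rand());
    psi[r] = -180.0 + binw * (sb + unif_rand());
  }
  double u_cur = minimize_inner(phi, psi, obj, iters_hop);
  std::vector<double> best_phi(phi), best_psi(psi);
  double u_best = u_cur;
  for (int hop = 0; hop < n_hops; ++hop) {
    double frac = n_hops > 1 ? (double)hop / (n_hops - 1) : 1.0;
    double T = t_hop_start * std::pow(t_hop_end / t_hop_start, frac);
    std::vector<double> tp(phi), ts(psi);
    int nmove = unif_rand() < 0.5 ? 1 : 2;
    for (int q = 0; q < nmove; ++q) {
      int r = (int)(unif_rand() * n);
      if (r >= n) r = n - 1;
      const double *cum = &prior_cum(0, resclass[r]);
      draw_torsion(cum, nbin2, nb, binw, &tp[r], &ts[r]);
    }
    double u_trial = minimize_inner(tp, ts, obj, iters_hop);
    if (u_trial <= u_cur ||
        unif_rand() < std::exp(-(u_trial - u_cur) / T)) {
      phi.swap(tp);
      psi.swap(ts);
      u_cur = u_trial;
      if (u_cur < u_best) {
        u_best = u_cur;
        best_phi = phi;
        best_psi = psi;
      }
    }
  }
  double u_final = minimize_inner(best_phi, best_psi, obj, iters_final);
  return List::create(
      _["phi"] = NumericVector(best_phi.begin(), best_phi.end()),
      _["psi"] = NumericVector(best_psi.begin(), best_psi.end()),
      _["u_init"] = u_init, _["u_final"] = u_final);
}
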