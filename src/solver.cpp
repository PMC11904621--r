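// 1D pulse-wave propagation solver: nonlinear hyperbolic system
//   dA/dt + dq/dx = 0
//   dq/dt + d/dx( phi q^2/A + B(A) ) = -CF q/A
// with B(A) the pressure-flux potential of the wall law (per-vessel constant
// stiffness, so the A/rho dp/dx term is conservative). Explicit Richtmyer
// two-step Lax-Wendroff on node-centred grids, characteristic closures at
// inlet/outlets, damped-Newton junction coupling. All quantities in CGS
// internally; the R interface converts mmHg <-> dyn/cm^2.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double MMHG = 1333.223874;

// positive-argument modulo (times are nonnegative here)
static inline double pmod(double x, double y) {
  return x - std::floor(x / y) * y;
}

struct WallLaw {
  // law 0: p = pref + s (sqrt(A/A0) - 1)   (default)
  // law 1: p = pref + s (A/A0 - 1)
  int law;
  double s, A0, pref, rho;
  double pres(double A) const {
    return law == 0 ? pref + s * (std::sqrt(A / A0) - 1.0)
                    : pref + s * (A / A0 - 1.0);
  }
  double dpdA(double A) const {
    return law == 0 ? s / (2.0 * std::sqrt(A * A0)) : s / A0;
  }
  double Bflux(double A) const {
    return law == 0 ? s * A0 / (3.0 * rho) * std::pow(A / A0, 1.5)
                    : s * A * A / (2.0 * rho * A0);
  }
  double c(double A) const { return std::sqrt(A / rho * dpdA(A)); }
  double dcdA(double A) const {
    return law == 0 ? c(A) / (4.0 * A) : c(A) / (2.0 * A);
  }
  double Cw() const { return law == 0 ? 4.0 : 2.0; }
};

struct Vessel {
  int N;             // cells; N+1 nodes
  double dx;
  WallLaw wall;
  std::vector<double> A, q;
  int parent, d1, d2;   // indices, -1 if none
  int term_idx;         // index into terminal BC arrays, -1 if not terminal
};

// ---- Richtmyer interior update -------------------------------------------
// Computes half-step states and updates interior nodes 1..N-1 in place.
// Returns mass fluxes at half nodes (q at j+1/2) if requested.
static void step_interior(Vessel& V, double dt, double phi, double CF,
                          std::vector<double>* mass_flux) {
  const int N = V.N;
  const WallLaw& w = V.wall;
  std::vector<double> Ah(N), qh(N), F2(N + 1), S2(N + 1);
  for (int j = 0; j <= N; ++j) {
    F2[j] = phi * V.q[j] * V.q[j] / V.A[j] + w.Bflux(V.A[j]);
    S2[j] = -CF * V.q[j] / V.A[j];
  }
  const double r = dt / (2.0 * V.dx);
  for (int j = 0; j < N; ++j) {
    Ah[j] = 0.5 * (V.A[j] + V.A[j + 1]) - r * (V.q[j + 1] - V.q[j]);
    qh[j] = 0.5 * (V.q[j] + V.q[j + 1]) - r * (F2[j + 1] - F2[j])
            + 0.25 * dt * (S2[j] + S2[j + 1]);
    if (Ah[j] <= 0.0) stop("pulse-wave solver: negative area at half step");
  }
  std::vector<double> F2h(N), S2h(N);
  for (int j = 0; j < N; ++j) {
    F2h[j] = phi * qh[j] * qh[j] / Ah[j] + w.Bflux(Ah[j]);
    S2h[j] = -CF * qh[j] / Ah[j];
  }
  const double rr = dt / V.dx;
  std::vector<double> Anew(V.A), qnew(V.q);
  for (int j = 1; j < N; ++j) {
    Anew[j] = V.A[j] - rr * (qh[j] - qh[j - 1]);
    qnew[j] = V.q[j] - rr * (F2h[j] - F2h[j - 1])
              + 0.5 * dt * (S2h[j] + S2h[j - 1]);
    if (Anew[j] <= 0.0) stop("pulse-wave solver: negative area");
  }
  if (mass_flux) *mass_flux = qh;
  V.A.swap(Anew);
  V.q.swap(qnew);
}

// Riemann-invariant extrapolation from the time-n state to the boundary foot
// point. side = +1: outgoing W+ = u + Cw c at the distal node (foot upstream);
// side = -1: outgoing W- = u - Cw c at the proximal node (foot downstream).
static double extrapolate_W(const std::vector<double>& A,
                            const std::vector<double>& q,
                            const WallLaw& w, int N, double dx, double dt,
                            int side) {
  int j0 = (side > 0) ? N : 0;
  int j1 = (side > 0) ? N - 1 : 1;
  double u0 = q[j0] / A[j0], c0 = w.c(A[j0]);
  double f = (side > 0 ? (u0 + c0) : (c0 - u0)) * dt / dx;
  if (f < 0.0) f = 0.0;
  if (f > 1.0) f = 1.0;
  double Af = (1.0 - f) * A[j0] + f * A[j1];
  double qf = (1.0 - f) * q[j0] + f * q[j1];
  double uf = qf / Af, cf = w.c(Af);
  return side > 0 ? uf + w.Cw() * cf : uf - w.Cw() * cf;
}

// ---- inlet: prescribed flow, incoming characteristic ---------------------
static void inlet_bc(Vessel& V, double qin, double Wm) {
  const WallLaw& w = V.wall;
  double A = V.A[0];
  for (int it = 0; it < 60; ++it) {
    double g = qin / A - w.Cw() * w.c(A) - Wm;
    double dg = -qin / (A * A) - w.Cw() * w.dcdA(A);
    double dA = -g / dg;
    if (A + dA <= 0.1 * A) dA = -0.9 * A;
    A += dA;
    if (std::fabs(dA) < 1e-14 * A) break;
  }
  if (!(A > 0.0)) stop("pulse-wave solver: inlet closure failed");
  V.A[0] = A;
  V.q[0] = qin;
}

// ---- terminal outlet: p = a + b q (affine BC), outgoing characteristic ---
static void outlet_bc(Vessel& V, double Wp, double a, double b) {
  const WallLaw& w = V.wall;
  double A = V.A[V.N];
  if (b > 1e-12 * MMHG) {
    for (int it = 0; it < 80; ++it) {
      double u = Wp - w.Cw() * w.c(A);
      double g = A * u - (w.pres(A) - a) / b;
      double dg = u - A * w.Cw() * w.dcdA(A) - w.dpdA(A) / b;
      double dA = -g / dg;
      if (A + dA <= 0.1 * A) dA = -0.9 * A;
      A += dA;
      if (std::fabs(dA) < 1e-14 * A) break;
    }
  } else {
    // resistance-free limit: pressure prescribed directly
    double p = a;
    A = (w.law == 0)
      ? w.A0 * std::pow((p - w.pref) / w.s + 1.0, 2.0)
      : w.A0 * ((p - w.pref) / w.s + 1.0);
  }
  if (!(A > 0.0)) stop("pulse-wave solver: outlet closure failed");
  V.A[V.N] = A;
  V.q[V.N] = A * (Wp - w.Cw() * w.c(A));
}

// ---- junction: conservation of flow, continuity of pressure --------------
// Unknowns x = (Ap, up, A1, u1, A2, u2); residuals: parent outgoing W+,
// daughters outgoing W-, mass, two pressure continuities. Damped Newton with
// analytic Jacobian and scaled residuals.
struct JuncResult { double Ap, up, A1, u1, A2, u2, resid; int iters; };

static JuncResult solve_junction(const WallLaw& wp, const WallLaw& w1,
                                 const WallLaw& w2, double Wp, double Wm1,
                                 double Wm2, double x0[6]) {
  double x[6];
  for (int i = 0; i < 6; ++i) x[i] = x0[i];
  const double cref = wp.c(wp.A0);
  const double sc[6] = {cref, cref, cref, wp.A0 * cref,
                        wp.rho * cref * cref, wp.rho * cref * cref};
  auto resid = [&](const double* y, double* r) {
    r[0] = y[1] + wp.Cw() * wp.c(y[0]) - Wp;
    r[1] = y[3] - w1.Cw() * w1.c(y[2]) - Wm1;
    r[2] = y[5] - w2.Cw() * w2.c(y[4]) - Wm2;
    r[3] = y[0] * y[1] - y[2] * y[3] - y[4] * y[5];
    r[4] = wp.pres(y[0]) - w1.pres(y[2]);
    r[5] = wp.pres(y[0]) - w2.pres(y[4]);
  };
  auto norm2 = [&](const double* r) {
    double s = 0.0;
    for (int i = 0; i < 6; ++i) { double t = r[i] / sc[i]; s += t * t; }
    return std::sqrt(s);
  };
  double r[6];
  resid(x, r);
  double rn = norm2(r);
  int it = 0;
  for (; it < 50 && rn > 1e-12; ++it) {
    double J[6][6] = {{0}};
    J[0][0] = wp.Cw() * wp.dcdA(x[0]); J[0][1] = 1.0;
    J[1][2] = -w1.Cw() * w1.dcdA(x[2]); J[1][3] = 1.0;
    J[2][4] = -w2.Cw() * w2.dcdA(x[4]); J[2][5] = 1.0;
    J[3][0] = x[1]; J[3][1] = x[0];
    J[3][2] = -x[3]; J[3][3] = -x[2];
    J[3][4] = -x[5]; J[3][5] = -x[4];
    J[4][0] = wp.dpdA(x[0]); J[4][2] = -w1.dpdA(x[2]);
    J[5][0] = wp.dpdA(x[0]); J[5][4] = -w2.dpdA(x[4]);
    // solve J dx = -r (Gaussian elimination, partial pivoting)
    double M[6][7];
    for (int i = 0; i < 6; ++i) {
      for (int j = 0; j < 6; ++j) M[i][j] = J[i][j];
      M[i][6] = -r[i];
    }
    for (int col = 0; col < 6; ++col) {
      int piv = col;
      for (int i = col + 1; i < 6; ++i)
        if (std::fabs(M[i][col]) > std::fabs(M[piv][col])) piv = i;
      if (std::fabs(M[piv][col]) < 1e-300)
        stop("pulse-wave solver: singular junction Jacobian");
      if (piv != col) for (int j = col; j < 7; ++j) std::swap(M[piv][j], M[col][j]);
      for (int i = col + 1; i < 6; ++i) {
        double f = M[i][col] / M[col][col];
        for (int j = col; j < 7; ++j) M[i][j] -= f * M[col][j];
      }
    }
    double dx[6];
    for (int i = 5; i >= 0; --i) {
      double s = M[i][6];
      for (int j = i + 1; j < 6; ++j) s -= M[i][j] * dx[j];
      dx[i] = s / M[i][i];
    }
    double lam = 1.0;
    for (int half = 0; half < 12; ++half) {
      double xn[6], rnw[6];
      bool ok = true;
      for (int i = 0; i < 6; ++i) {
        xn[i] = x[i] + lam * dx[i];
        if ((i % 2 == 0) && xn[i] <= 0.0) ok = false;   // areas positive
      }
      if (ok) {
        resid(xn, rnw);
        double rn2 = norm2(rnw);
        if (rn2 < rn || rn2 < 1e-12) {
          for (int i = 0; i < 6; ++i) { x[i] = xn[i]; r[i] = rnw[i]; }
          rn = rn2;
          break;
        }
      }
      lam *= 0.5;
      if (half == 11) { // accept damped step anyway
        for (int i = 0; i < 6; ++i) if (i % 2 || x[i] + lam * dx[i] > 0)
          x[i] += lam * dx[i];
        resid(x, r);
        rn = norm2(r);
      }
    }
  }
  if (rn > 1e-10)
    stop("pulse-wave solver: junction Newton failed (scaled residual %g)", rn);
  JuncResult out{x[0], x[1], x[2], x[3], x[4], x[5], rn, it};
  return out;
}

// ---- exported single-vessel step (for verification) ----------------------
// [[Rcpp::export(name = ".pw_step_vessel")]]
List pw_step_vessel(NumericVector A, NumericVector q, double dt, double dx,
                    double rho, double phi, double CF, double s_cgs,
                    double pref_cgs, double A0, int law) {
  Vessel V;
  V.N = A.size() - 1;
  V.dx = dx;
  V.wall = WallLaw{law, s_cgs, A0, pref_cgs, rho};
  V.A = as<std::vector<double>>(A);
  V.q = as<std::vector<double>>(q);
  // CFL check
  for (int j = 0; j <= V.N; ++j) {
    double sp = std::fabs(V.q[j] / V.A[j]) * phi + V.wall.c(V.A[j]);
    if (sp * dt > dx)
      stop("pulse-wave solver: CFL violation (max wave speed %g cm/s)", sp);
  }
  std::vector<double> mf;
  step_interior(V, dt, phi, CF, &mf);
  return List::create(_["A"] = wrap(V.A), _["q"] = wrap(V.q),
                      _["mass_flux_half"] = wrap(mf));
}

// ---- exported junction solve (for verification) --------------------------
// [[Rcpp::export(name = ".pw_couple_junction")]]
List pw_couple_junction(double Wp, double Wm1, double Wm2,
                        NumericVector s_cgs, NumericVector A0,
                        NumericVector pref_cgs, double rho, int law,
                        NumericVector guess) {
  WallLaw wp{law, s_cgs[0], A0[0], pref_cgs[0], rho};
  WallLaw w1{law, s_cgs[1], A0[1], pref_cgs[1], rho};
  WallLaw w2{law, s_cgs[2], A0[2], pref_cgs[2], rho};
  double x0[6];
  for (int i = 0; i < 6; ++i) x0[i] = guess[i];
  JuncResult jr = solve_junction(wp, w1, w2, Wp, Wm1, Wm2, x0);
  return List::create(_["A_p"] = jr.Ap, _["u_p"] = jr.up,
                      _["A_d1"] = jr.A1, _["u_d1"] = jr.u1,
                      _["A_d2"] = jr.A2, _["u_d2"] = jr.u2,
                      _["residual"] = jr.resid, _["iterations"] = jr.iters);
}

// ---- full network simulation ---------------------------------------------
// [[Rcpp::export(name = ".pw_run_simulation")]]
List pw_run_simulation(NumericVector length_cm, NumericVector r0_cm,
                       IntegerVector parent, IntegerMatrix daughters,
                       IntegerVector term_idx, NumericVector stiff_mmHg,
                       double p_ref_mmHg, int law, double rho, double nu,
                       double gamma_prof, double cycle_T, int m_out,
                       int cells_per_vessel, double cfl, double tol_mmHg,
                       int n_cycles_max, int inflow_shape, double Q_max,
                       double systole_fraction, int bc_kind,
                       NumericVector wk_Rp_mmHg, NumericVector wk_Rd_mmHg,
                       NumericVector wk_C_mmHg, NumericMatrix st_kernel_mmHg,
                       NumericVector pd0_mmHg, NumericVector qbuf0,
                       IntegerMatrix probes) {
  const int V = length_cm.size();
  const double phi = (gamma_prof + 2.0) / (gamma_prof + 1.0);
  const double CF = 2.0 * M_PI * nu * (gamma_prof + 2.0);
  const double pref = p_ref_mmHg * MMHG;
  const double tol = tol_mmHg * MMHG;

  std::vector<Vessel> ves(V);
  double dxmin = 1e300;
  for (int v = 0; v < V; ++v) {
    Vessel& Vv = ves[v];
    Vv.N = cells_per_vessel;
    Vv.dx = length_cm[v] / cells_per_vessel;
    dxmin = std::min(dxmin, Vv.dx);
    double A0 = M_PI * r0_cm[v] * r0_cm[v];
    Vv.wall = WallLaw{law, stiff_mmHg[v] * MMHG, A0, pref, rho};
    Vv.A.assign(Vv.N + 1, A0);
    Vv.q.assign(Vv.N + 1, 0.0);
    Vv.parent = parent[v];
    Vv.d1 = daughters(v, 0);
    Vv.d2 = daughters(v, 1);
    Vv.term_idx = term_idx[v];
  }
  int root = -1;
  for (int v = 0; v < V; ++v) if (ves[v].parent < 0) root = v;

  // terminal BC state
  int nterm = 0;
  for (int v = 0; v < V; ++v) if (ves[v].term_idx >= 0) ++nterm;
  std::vector<double> Rp(nterm), Rd(nterm), Cap(nterm), pd(nterm, 0.0),
      qterm(nterm, 0.0);
  if (bc_kind == 0) {
    for (int i = 0; i < nterm; ++i) {
      Rp[i] = wk_Rp_mmHg[i] * MMHG;
      Rd[i] = wk_Rd_mmHg[i] * MMHG;
      Cap[i] = wk_C_mmHg[i] / MMHG;
      pd[i] = pd0_mmHg[i] * MMHG;   // warm start near the periodic state
      if (!(Rp[i] > 0) || !(Rd[i] > 0) || !(Cap[i] > 0))
        stop("pulse-wave solver: nonpositive Windkessel element");
    }
  }
  const int Mk = (bc_kind == 1) ? st_kernel_mmHg.nrow() : 0;
  std::vector<std::vector<double>> zker(nterm), qbuf(nterm);
  if (bc_kind == 1) {
    for (int i = 0; i < nterm; ++i) {
      zker[i].resize(Mk);
      for (int k = 0; k < Mk; ++k) zker[i][k] = st_kernel_mmHg(k, i) * MMHG;
      qbuf[i].assign(Mk, qbuf0[i]);   // warm start with the mean flow split
    }
  }

  auto qin_of = [&](double t) {
    double tc = pmod(t, cycle_T);
    if (inflow_shape == 1) return Q_max;                 // constant
    double ts = systole_fraction * cycle_T;
    if (tc >= ts) return 0.0;
    double s = std::sin(M_PI * tc / ts);
    return Q_max * s * s;                                // sine^2 systole
  };

  const int n_probe = probes.nrow();
  std::vector<std::vector<double>> probe_p(n_probe);
  std::vector<double> probe_t;

  NumericVector p_prev(m_out, NA_REAL), p_cur(m_out);
  NumericVector cycle_delta(n_cycles_max, NA_REAL);
  bool converged = false;
  int cycles_used = 0;
  double t = 0.0;

  for (int cyc = 0; cyc < n_cycles_max && !converged; ++cyc) {
    // time step for this cycle from the current maximum wave speed
    double smax = 0.0;
    for (int v = 0; v < V; ++v)
      for (int j = 0; j <= ves[v].N; ++j) {
        double sp = phi * std::fabs(ves[v].q[j] / ves[v].A[j])
                    + ves[v].wall.c(ves[v].A[j]);
        smax = std::max(smax, sp);
      }
    double dtmax = cfl * dxmin / smax;
    int spc = m_out * (int)std::ceil(cycle_T / (m_out * dtmax));
    double dt = cycle_T / spc;
    int per_sample = spc / m_out;

    for (int s = 0; s < spc; ++s) {
      if (s % per_sample == 0) {
        int k = s / per_sample;
        p_cur[k] = ves[root].wall.pres(ves[root].A[0]) / MMHG;
      }
      if (n_probe) {
        probe_t.push_back(t);
        for (int ip = 0; ip < n_probe; ++ip)
          probe_p[ip].push_back(
            ves[probes(ip, 0)].wall.pres(ves[probes(ip, 0)].A[probes(ip, 1)])
            / MMHG);
      }
      // CFL guard against intra-cycle speed-up
      for (int v = 0; v < V; ++v)
        for (int j = 0; j <= ves[v].N; ++j) {
          double sp = phi * std::fabs(ves[v].q[j] / ves[v].A[j])
                      + ves[v].wall.c(ves[v].A[j]);
          if (sp * dt > ves[v].dx)
            stop("pulse-wave solver: CFL violation (max wave speed %g cm/s)",
                 sp);
        }
      // save time-n states for boundary extrapolation
      std::vector<std::vector<double>> Aold(V), qold(V);
      for (int v = 0; v < V; ++v) { Aold[v] = ves[v].A; qold[v] = ves[v].q; }

      for (int v = 0; v < V; ++v) step_interior(ves[v], dt, phi, CF, nullptr);

      double tn1 = t + dt;
      // inlet
      {
        double Wm = extrapolate_W(Aold[root], qold[root], ves[root].wall,
                                  ves[root].N, ves[root].dx, dt, -1);
        inlet_bc(ves[root], qin_of(tn1), Wm);
      }
      // junctions
      for (int v = 0; v < V; ++v) {
        if (ves[v].d1 < 0) continue;
        Vessel& P = ves[v];
        Vessel& D1 = ves[P.d1];
        Vessel& D2 = ves[P.d2];
        double Wp = extrapolate_W(Aold[v], qold[v], P.wall, P.N, P.dx, dt, 1);
        double W1 = extrapolate_W(Aold[P.d1], qold[P.d1], D1.wall, D1.N,
                                  D1.dx, dt, -1);
        double W2 = extrapolate_W(Aold[P.d2], qold[P.d2], D2.wall, D2.N,
                                  D2.dx, dt, -1);
        double g0[6] = {P.A[P.N], P.q[P.N] / P.A[P.N],
                        D1.A[0], D1.q[0] / D1.A[0],
                        D2.A[0], D2.q[0] / D2.A[0]};
        JuncResult jr = solve_junction(P.wall, D1.wall, D2.wall, Wp, W1, W2,
                                       g0);
        P.A[P.N] = jr.Ap; P.q[P.N] = jr.Ap * jr.up;
        D1.A[0] = jr.A1; D1.q[0] = jr.A1 * jr.u1;
        D2.A[0] = jr.A2; D2.q[0] = jr.A2 * jr.u2;
      }
      // terminal outlets
      for (int v = 0; v < V; ++v) {
        int ti = ves[v].term_idx;
        if (ti < 0) continue;
        Vessel& Vv = ves[v];
        double Wp = extrapolate_W(Aold[v], qold[v], Vv.wall, Vv.N, Vv.dx, dt,
                                  1);
        double a, b;
        if (bc_kind == 0) {
          double a1 = dt / (2.0 * Cap[ti]);
          double den = 1.0 + a1 / Rd[ti];
          double P0 = (pd[ti] * (1.0 - a1 / Rd[ti]) + a1 * qterm[ti]) / den;
          double P1 = a1 / den;
          a = pref + P0;
          b = Rp[ti] + P1;
        } else {
          double dT = cycle_T / Mk;
          int ib = (int)std::floor(pmod(tn1, cycle_T) / dT) % Mk;
          double conv = 0.0;
          for (int k = 1; k < Mk; ++k)
            conv += zker[ti][k] * qbuf[ti][(ib - k + 2 * Mk) % Mk];
          a = pref + dT * conv;
          b = dT * zker[ti][0];
        }
        outlet_bc(Vv, Wp, a, b);
        double qn1 = Vv.q[Vv.N];
        if (bc_kind == 0) {
          double a1 = dt / (2.0 * Cap[ti]);
          pd[ti] = (pd[ti] * (1.0 - a1 / Rd[ti]) + a1 * (qterm[ti] + qn1))
                   / (1.0 + a1 / Rd[ti]);
        } else {
          double dT = cycle_T / Mk;
          int ib = (int)std::floor(pmod(tn1, cycle_T) / dT) % Mk;
          qbuf[ti][ib] = qn1;
        }
        qterm[ti] = qn1;
      }
      t = tn1;
    }
    cycles_used = cyc + 1;
    double dmax = 0.0;
    bool have_prev = !NumericVector::is_na(p_prev[0]);
    for (int k = 0; k < m_out; ++k) {
      if (have_prev) dmax = std::max(dmax, std::fabs(p_cur[k] - p_prev[k]));
      p_prev[k] = p_cur[k];
    }
    if (have_prev) {
      cycle_delta[cyc] = dmax;
      if (dmax <= tol_mmHg) converged = true;
    }
  }

  NumericVector tout(m_out);
  for (int k = 0; k < m_out; ++k) tout[k] = k * cycle_T / m_out;
  List probe_list(n_probe);
  for (int ip = 0; ip < n_probe; ++ip) probe_list[ip] = wrap(probe_p[ip]);
  return List::create(_["t"] = tout, _["p"] = p_cur,
                      _["converged"] = converged,
                      _["cycles_used"] = cycles_used,
                      _["cycle_delta"] = cycle_delta,
                      _["probe_t"] = wrap(probe_t),
                      _["probe_p"] = probe_list);
}
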