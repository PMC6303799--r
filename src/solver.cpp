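// Explicit MacCormack stepper for 1D pulse-wave propagation on an arterial
// network, with characteristic-based coupling at junctions, stenosis
// pressure-loss junctions and Windkessel (WK3 / coronary) outlets.
//
// The R side discretizes the network and drives the stepper one cardiac
// cycle at a time; this file advances nsteps time steps of size dt and
// records P, Q, A at requested sites.
//
// Units are CGS throughout (cm, g, s, dyn).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <string>

using namespace Rcpp;

struct Segment {
  std::vector<double> P, Q, Ad, beta, Pdia, sqAd, cd;
  double dx;
  int n; // number of nodes
};

static inline double area_of_P(const Segment& s, int i, double P) {
  double root = s.sqAd[i] + (P - s.Pdia[i]) * s.Ad[i] / s.beta[i];
  if (root <= 0.0) return -1.0; // collapse flag
  return root * root;
}

static inline double P_of_area(const Segment& s, int i, double A) {
  return s.Pdia[i] + (s.beta[i] / s.Ad[i]) * (std::sqrt(A) - s.sqAd[i]);
}

static inline double wave_c(const Segment& s, int i, double A, double rho) {
  return std::sqrt(s.beta[i] * std::sqrt(A) / (2.0 * rho * s.Ad[i]));
}

// dA/dP at pressure P
static inline double dAdP(const Segment& s, int i, double A) {
  return 2.0 * s.Ad[i] * std::sqrt(A) / s.beta[i];
}

struct WkAttach {
  int type;                  // 0 = wk3, 1 = coronary
  // wk3: R1 C R2 Pout ; cor: Ra Ca Rm Cm Rv gamma Pout
  std::vector<double> par;
  std::vector<double> state; // wk3: Pc Qw ; cor: P1 P2 Qw
  std::vector<double> plv;   // coronary only, values at step times (nsteps+1)
};

struct Coupling {
  int type;                        // 0 junction, 1 inflow_Q, 2 inflow_P
  std::vector<int> seg, end;       // end: 0 prox, 1 dist
  std::vector<double> kv, ke;      // extra pressure-loss coeffs (per end, [0] unused)
  std::vector<double> inflow;      // prescribed values at step times
  std::vector<WkAttach> wk;
  std::string label;
};

// WK pressure seen by the vessel face for trial flow Q, plus dP/dQ, using an
// implicit-Euler update of the internal states (not committed).
static void wk_pressure(const WkAttach& w, double dt, double Q,
                        double plv0, double plv1,
                        double& Pw, double& dPdQ) {
  if (w.type == 0) {
    double R1 = w.par[0], C = w.par[1], R2 = w.par[2], Pout = w.par[3];
    double a = dt / C, b = dt / (R2 * C);
    double Pc1 = (w.state[0] + a * Q + b * Pout) / (1.0 + b);
    Pw = Pc1 + R1 * Q;
    dPdQ = a / (1.0 + b) + R1;
  } else {
    double Ra = w.par[0], Ca = w.par[1], Rm = w.par[2], Cm = w.par[3],
           Rv = w.par[4], g = w.par[5], Pout = w.par[6];
    double a11 = Ca / dt + 1.0 / Rm, a12 = -1.0 / Rm;
    double a21 = -1.0 / Rm, a22 = Cm / dt + 1.0 / Rm + 1.0 / Rv;
    double det = a11 * a22 - a12 * a21;
    // rhs: b1 = Ca*P1/dt + Q ; b2 = Cm*(P2 - g*plv0 + g*plv1)/dt + Pout/Rv
    double b1c = Ca * w.state[0] / dt;           // constant part of b1
    double b2 = Cm * (w.state[1] - g * plv0 + g * plv1) / dt + Pout / Rv;
    // P1' = (a22*(b1c+Q) - a12*b2)/det
    double P1 = (a22 * (b1c + Q) - a12 * b2) / det;
    Pw = P1 + Ra * Q;
    dPdQ = a22 / det + Ra;
  }
}

// Commit the WK internal state for the accepted flow Q.
static void wk_commit(WkAttach& w, double dt, double Q,
                      double plv0, double plv1) {
  if (w.type == 0) {
    double C = w.par[1], R2 = w.par[2], Pout = w.par[3];
    double a = dt / C, b = dt / (R2 * C);
    w.state[0] = (w.state[0] + a * Q + b * Pout) / (1.0 + b);
    w.state[1] = Q;
  } else {
    double Ca = w.par[1], Rm = w.par[2], Cm = w.par[3], Rv = w.par[4],
           g = w.par[5], Pout = w.par[6];
    double a11 = Ca / dt + 1.0 / Rm, a12 = -1.0 / Rm;
    double a21 = -1.0 / Rm, a22 = Cm / dt + 1.0 / Rm + 1.0 / Rv;
    double det = a11 * a22 - a12 * a21;
    double b1 = Ca * w.state[0] / dt + Q;
    double b2 = Cm * (w.state[1] - g * plv0 + g * plv1) / dt + Pout / Rv;
    double P1 = (a22 * b1 - a12 * b2) / det;
    double P2 = (a11 * b2 - a21 * b1) / det;
    w.state[0] = P1; w.state[1] = P2; w.state[2] = Q;
  }
}

// Dense Gaussian elimination with partial pivoting; solves J x = rhs in place.
static bool gauss_solve(std::vector<double>& J, std::vector<double>& rhs, int n) {
  for (int col = 0; col < n; ++col) {
    int piv = col;
    double best = std::fabs(J[col * n + col]);
    for (int r = col + 1; r < n; ++r) {
      double v = std::fabs(J[r * n + col]);
      if (v > best) { best = v; piv = r; }
    }
    if (best < 1e-300) return false;
    if (piv != col) {
      for (int c = 0; c < n; ++c) std::swap(J[col * n + c], J[piv * n + c]);
      std::swap(rhs[col], rhs[piv]);
    }
    double d = J[col * n + col];
    for (int r = col + 1; r < n; ++r) {
      double f = J[r * n + col] / d;
      if (f == 0.0) continue;
      for (int c = col; c < n; ++c) J[r * n + c] -= f * J[col * n + c];
      rhs[r] -= f * rhs[col];
    }
  }
  for (int r = n - 1; r >= 0; --r) {
    double acc = rhs[r];
    for (int c = r + 1; c < n; ++c) acc -= J[r * n + c] * rhs[c];
    rhs[r] = acc / J[r * n + r];
  }
  return true;
}

struct BoundaryUpdate {
  std::vector<double> A, U;      // per vessel end
  std::vector<double> Qw;        // per WK attachment
  double mass_defect;
};

// Solve the nonlinear coupling system at one junction/boundary for the
// states at t^{n+1}. W[] are the extrapolated characteristic values.
static BoundaryUpdate solve_coupling(const Coupling& cp,
                                     const std::vector<Segment>& segs,
                                     const std::vector<double>& W,
                                     double rho, double dt, int step,
                                     double tol_scale) {
  int n = cp.seg.size();
  int m = cp.wk.size();
  int dim = 2 * n + m;
  std::vector<double> z(dim);
  std::vector<int> bnode(n);
  std::vector<double> sgn(n);
  for (int i = 0; i < n; ++i) {
    const Segment& s = segs[cp.seg[i]];
    bnode[i] = (cp.end[i] == 0) ? 0 : (s.n - 1);
    sgn[i] = (cp.end[i] == 1) ? 1.0 : -1.0;
    double A = area_of_P(s, bnode[i], s.P[bnode[i]]);
    z[i] = A;
    z[n + i] = s.Q[bnode[i]] / A;
  }
  for (int j = 0; j < m; ++j)
    z[2 * n + j] = cp.wk[j].state.back(); // warm start from previous Qw

  const Segment& s0 = segs[cp.seg[0]];
  double cref = s0.cd[bnode[0]];
  double Aref = s0.Ad[bnode[0]];
  double pref = rho * cref * cref;

  std::vector<double> F(dim), J;
  double plv0 = 0, plv1 = 0;

  for (int iter = 0; iter < 100; ++iter) {
    J.assign(dim * dim, 0.0);
    // characteristic equations
    for (int i = 0; i < n; ++i) {
      const Segment& s = segs[cp.seg[i]];
      double A = z[i], U = z[n + i];
      double c = wave_c(s, bnode[i], A, rho);
      F[i] = U + sgn[i] * 4.0 * (c - s.cd[bnode[i]]) - W[i];
      J[i * dim + i] = sgn[i] * c / A;       // 4*dc/dA = c/A
      J[i * dim + n + i] = 1.0;
    }
    // mass balance
    double mass = 0.0;
    int rm = n;
    for (int i = 0; i < n; ++i) mass += sgn[i] * z[i] * z[n + i];
    if (cp.type == 1) {
      // prescribed inflow: A*U = Qin (single prox end)
      F[rm] = z[0] * z[n] - cp.inflow[step + 1];
      J[rm * dim + 0] = z[n];
      J[rm * dim + n] = z[0];
    } else if (cp.type == 2) {
      // prescribed pressure
      const Segment& s = segs[cp.seg[0]];
      F[rm] = P_of_area(s, bnode[0], z[0]) - cp.inflow[step + 1];
      J[rm * dim + 0] = s.beta[bnode[0]] / (2.0 * s.Ad[bnode[0]] * std::sqrt(z[0]));
    } else {
      for (int j = 0; j < m; ++j) mass -= z[2 * n + j];
      F[rm] = mass;
      for (int i = 0; i < n; ++i) {
        J[rm * dim + i] = sgn[i] * z[n + i];
        J[rm * dim + n + i] = sgn[i] * z[i];
      }
      for (int j = 0; j < m; ++j) J[rm * dim + 2 * n + j] = -1.0;
    }
    // total-pressure continuity between vessel ends (with optional dP loss)
    double A0 = z[0], U0 = z[n];
    double P0 = P_of_area(s0, bnode[0], A0);
    double pt0 = P0 + 0.5 * rho * U0 * U0;
    double dP0dA = s0.beta[bnode[0]] / (2.0 * s0.Ad[bnode[0]] * std::sqrt(A0));
    double Qtr = sgn[0] * A0 * U0;
    for (int i = 1; i < n; ++i) {
      int r = n + 1 + (i - 1);
      const Segment& s = segs[cp.seg[i]];
      double A = z[i], U = z[n + i];
      double P = P_of_area(s, bnode[i], A);
      double dPdA = s.beta[bnode[i]] / (2.0 * s.Ad[bnode[i]] * std::sqrt(A));
      double dP = cp.kv[i] * Qtr + cp.ke[i] * Qtr * std::fabs(Qtr);
      F[r] = pt0 - (P + 0.5 * rho * U * U) - dP;
      J[r * dim + 0] = dP0dA;
      J[r * dim + n] = rho * U0;
      J[r * dim + i] = -dPdA;
      J[r * dim + n + i] = -rho * U;
      double ddPdQ = cp.kv[i] + 2.0 * cp.ke[i] * std::fabs(Qtr);
      J[r * dim + 0] -= ddPdQ * sgn[0] * U0;
      J[r * dim + n] -= ddPdQ * sgn[0] * A0;
    }
    // WK attachments: static pressure of end 0 equals WK face pressure
    for (int j = 0; j < m; ++j) {
      int r = 2 * n + j;
      const WkAttach& w = cp.wk[j];
      if (w.type == 1) { plv0 = w.plv[step]; plv1 = w.plv[step + 1]; }
      double Pw, dPdQ;
      wk_pressure(w, dt, z[2 * n + j], plv0, plv1, Pw, dPdQ);
      F[r] = P0 - Pw;
      J[r * dim + 0] = dP0dA;
      J[r * dim + 2 * n + j] = -dPdQ;
    }

    // convergence check on scaled residual
    double nrm = 0.0;
    for (int i = 0; i < n; ++i) nrm = std::max(nrm, std::fabs(F[i]) / cref);
    nrm = std::max(nrm, std::fabs(F[n]) / (Aref * cref));
    for (int r = n + 1; r < dim; ++r) nrm = std::max(nrm, std::fabs(F[r]) / pref);
    if (nrm < tol_scale) break;
    if (iter == 99)
      stop("junction solve failed to converge at coupling '%s'", cp.label);

    std::vector<double> rhs(dim);
    for (int r = 0; r < dim; ++r) rhs[r] = -F[r];
    std::vector<double> Jc = J;
    if (!gauss_solve(Jc, rhs, dim))
      stop("singular junction system at coupling '%s'", cp.label);
    // damped update keeping areas positive
    double lam = 1.0;
    for (int tr = 0; tr < 40; ++tr) {
      bool ok = true;
      for (int i = 0; i < n; ++i)
        if (z[i] + lam * rhs[i] <= 0.0) { ok = false; break; }
      if (ok) break;
      lam *= 0.5;
    }
    for (int r = 0; r < dim; ++r) z[r] += lam * rhs[r];
  }

  BoundaryUpdate out;
  out.A.assign(z.begin(), z.begin() + n);
  out.U.assign(z.begin() + n, z.begin() + 2 * n);
  out.Qw.assign(z.begin() + 2 * n, z.end());
  double mass = 0.0;
  for (int i = 0; i < n; ++i) mass += sgn[i] * out.A[i] * out.U[i];
  for (int j = 0; j < m; ++j) mass -= out.Qw[j];
  if (cp.type == 1) mass = out.A[0] * out.U[0] - cp.inflow[step + 1];
  if (cp.type == 2) mass = 0.0;
  out.mass_defect = std::fabs(mass);
  return out;
}

// Extrapolate the outgoing characteristic value for each coupling end from
// the interior solution at time t^n (first order along the characteristic).
static double char_extrapolate(const Segment& s, int endq, double rho, double dt) {
  int b = (endq == 0) ? 0 : (s.n - 1);
  int nb = (endq == 0) ? 1 : (s.n - 2);
  double sgn = (endq == 1) ? 1.0 : -1.0;
  double Ab = area_of_P(s, b, s.P[b]);
  double Anb = area_of_P(s, nb, s.P[nb]);
  if (Ab <= 0.0 || Anb <= 0.0) stop("vessel collapse at a boundary node");
  double Ub = s.Q[b] / Ab, Unb = s.Q[nb] / Anb;
  double cb = wave_c(s, b, Ab, rho);
  double lam = Ub + sgn * cb;           // signed characteristic speed
  double frac = std::fabs(lam) * dt / s.dx;
  if (frac > 1.0) frac = 1.0;
  if (sgn * lam < 0.0) frac = 0.0;      // characteristic not outgoing; use node value
  double Uf = (1.0 - frac) * Ub + frac * Unb;
  double cnb = wave_c(s, nb, Anb, rho);
  double cf = (1.0 - frac) * cb + frac * cnb;
  double cdf = (1.0 - frac) * s.cd[b] + frac * s.cd[nb];
  return Uf + sgn * 4.0 * (cf - cdf);
}

// [[Rcpp::export(name = ".mac_cycle")]]
List mac_cycle(List segs_in, List coups_in, double rho, double kf,
               double dt, int nsteps, IntegerMatrix sites) {
  int nseg = segs_in.size();
  std::vector<Segment> segs(nseg);
  for (int k = 0; k < nseg; ++k) {
    List sl = segs_in[k];
    Segment& s = segs[k];
    s.P = as<std::vector<double> >(sl["P"]);
    s.Q = as<std::vector<double> >(sl["Q"]);
    s.Ad = as<std::vector<double> >(sl["Ad"]);
    s.beta = as<std::vector<double> >(sl["beta"]);
    s.Pdia = as<std::vector<double> >(sl["Pdia"]);
    s.dx = as<double>(sl["dx"]);
    s.n = s.P.size();
    s.sqAd.resize(s.n); s.cd.resize(s.n);
    for (int i = 0; i < s.n; ++i) {
      s.sqAd[i] = std::sqrt(s.Ad[i]);
      s.cd[i] = std::sqrt(s.beta[i] * s.sqAd[i] / (2.0 * rho * s.Ad[i]));
    }
  }

  int ncp = coups_in.size();
  std::vector<Coupling> cps(ncp);
  for (int k = 0; k < ncp; ++k) {
    List cl = coups_in[k];
    Coupling& cp = cps[k];
    cp.type = as<int>(cl["type"]);
    IntegerMatrix ends = cl["ends"];
    int n = ends.nrow();
    cp.seg.resize(n); cp.end.resize(n);
    for (int i = 0; i < n; ++i) {
      cp.seg[i] = ends(i, 0) - 1;
      cp.end[i] = ends(i, 1);
    }
    cp.kv = as<std::vector<double> >(cl["kv"]);
    cp.ke = as<std::vector<double> >(cl["ke"]);
    cp.label = as<std::string>(cl["label"]);
    if (cl.containsElementNamed("inflow") && !Rf_isNull(cl["inflow"]))
      cp.inflow = as<std::vector<double> >(cl["inflow"]);
    if (cl.containsElementNamed("wk") && !Rf_isNull(cl["wk"])) {
      List wl = cl["wk"];
      for (int j = 0; j < wl.size(); ++j) {
        List wj = wl[j];
        WkAttach w;
        w.type = as<int>(wj["type"]);
        w.par = as<std::vector<double> >(wj["par"]);
        w.state = as<std::vector<double> >(wj["state"]);
        if (wj.containsElementNamed("plv") && !Rf_isNull(wj["plv"]))
          w.plv = as<std::vector<double> >(wj["plv"]);
        cp.wk.push_back(w);
      }
    }
  }

  int nsites = sites.nrow();
  NumericMatrix siteP(nsteps + 1, nsites), siteQ(nsteps + 1, nsites),
                siteA(nsteps + 1, nsites);
  auto record = [&](int row) {
    for (int j = 0; j < nsites; ++j) {
      const Segment& s = segs[sites(j, 0) - 1];
      int node = sites(j, 1) - 1;
      double A = area_of_P(s, node, s.P[node]);
      siteP(row, j) = s.P[node];
      siteQ(row, j) = s.Q[node];
      siteA(row, j) = A;
    }
  };
  record(0);

  double max_cfl = 0.0, mass_defect = 0.0, maxQ = 0.0;
  std::vector<std::vector<double> > Ps(nseg), Qs(nseg);
  for (int k = 0; k < nseg; ++k) { Ps[k].resize(segs[k].n); Qs[k].resize(segs[k].n); }

  const double newton_tol = 1e-11;

  for (int step = 0; step < nsteps; ++step) {
    // 1. boundary/junction updates from the time-n fields
    std::vector<BoundaryUpdate> upd(ncp);
    for (int k = 0; k < ncp; ++k) {
      Coupling& cp = cps[k];
      int n = cp.seg.size();
      std::vector<double> W(n);
      for (int i = 0; i < n; ++i)
        W[i] = char_extrapolate(segs[cp.seg[i]], cp.end[i], rho, dt);
      upd[k] = solve_coupling(cp, segs, W, rho, dt, step, newton_tol);
      if (cp.type == 0 && upd[k].mass_defect > mass_defect)
        mass_defect = upd[k].mass_defect;
    }

    // 2. MacCormack predictor/corrector on segment interiors
    for (int k = 0; k < nseg; ++k) {
      Segment& s = segs[k];
      int M = s.n - 1;
      double r = dt / s.dx;
      // predictor (forward differences) for interior nodes
      for (int i = 1; i < M; ++i) {
        double A = area_of_P(s, i, s.P[i]);
        double A1 = area_of_P(s, i + 1, s.P[i + 1]);
        if (A <= 0.0 || A1 <= 0.0)
          stop("negative area during predictor in solver segment %d", k + 1);
        double Fi = s.Q[i] * s.Q[i] / A;
        double Fi1 = s.Q[i + 1] * s.Q[i + 1] / A1;
        double comp = dAdP(s, i, A);
        Ps[k][i] = s.P[i] - (r / comp) * (s.Q[i + 1] - s.Q[i]);
        Qs[k][i] = s.Q[i] - r * (Fi1 - Fi)
                 - r * (A / rho) * (s.P[i + 1] - s.P[i])
                 - dt * kf * s.Q[i] / (rho * A);
        double c = wave_c(s, i, A, rho);
        double cfl = (std::fabs(s.Q[i] / A) + c) * dt / s.dx;
        if (cfl > max_cfl) max_cfl = cfl;
        if (std::fabs(s.Q[i]) > maxQ) maxQ = std::fabs(s.Q[i]);
      }
    }
    // boundary starred values = the new (t^{n+1}) boundary solution
    for (int k = 0; k < ncp; ++k) {
      const Coupling& cp = cps[k];
      for (size_t i = 0; i < cp.seg.size(); ++i) {
        Segment& s = segs[cp.seg[i]];
        int b = (cp.end[i] == 0) ? 0 : (s.n - 1);
        Ps[cp.seg[i]][b] = P_of_area(s, b, upd[k].A[i]);
        Qs[cp.seg[i]][b] = upd[k].A[i] * upd[k].U[i];
      }
    }
    // corrector (backward differences on starred fields)
    for (int k = 0; k < nseg; ++k) {
      Segment& s = segs[k];
      int M = s.n - 1;
      double r = dt / s.dx;
      std::vector<double> Pn(s.n), Qn(s.n);
      for (int i = 1; i < M; ++i) {
        double As = area_of_P(s, i, Ps[k][i]);
        double Asm = area_of_P(s, i - 1, Ps[k][i - 1]);
        if (As <= 0.0 || Asm <= 0.0)
          stop("negative area during corrector in solver segment %d", k + 1);
        double Fs = Qs[k][i] * Qs[k][i] / As;
        double Fsm = Qs[k][i - 1] * Qs[k][i - 1] / Asm;
        double comp = dAdP(s, i, As);
        Pn[i] = 0.5 * (s.P[i] + Ps[k][i] - (r / comp) * (Qs[k][i] - Qs[k][i - 1]));
        Qn[i] = 0.5 * (s.Q[i] + Qs[k][i]
                        - r * (Fs - Fsm)
                        - r * (As / rho) * (Ps[k][i] - Ps[k][i - 1])
                        - dt * kf * Qs[k][i] / (rho * As));
      }
      for (int i = 1; i < M; ++i) { s.P[i] = Pn[i]; s.Q[i] = Qn[i]; }
    }
    // commit boundary values and WK states
    for (int k = 0; k < ncp; ++k) {
      Coupling& cp = cps[k];
      for (size_t i = 0; i < cp.seg.size(); ++i) {
        Segment& s = segs[cp.seg[i]];
        int b = (cp.end[i] == 0) ? 0 : (s.n - 1);
        s.P[b] = P_of_area(s, b, upd[k].A[i]);
        s.Q[b] = upd[k].A[i] * upd[k].U[i];
        if (std::fabs(s.Q[b]) > maxQ) maxQ = std::fabs(s.Q[b]);
      }
      for (size_t j = 0; j < cp.wk.size(); ++j) {
        WkAttach& w = cp.wk[j];
        double plv0 = 0, plv1 = 0;
        if (w.type == 1) { plv0 = w.plv[step]; plv1 = w.plv[step + 1]; }
        wk_commit(w, dt, upd[k].Qw[j], plv0, plv1);
      }
    }
    record(step + 1);
    if (max_cfl > 1.0)
      stop("CFL condition violated (max Courant number %.3f)", max_cfl);
  }

  List segs_out(nseg);
  for (int k = 0; k < nseg; ++k)
    segs_out[k] = List::create(_["P"] = wrap(segs[k].P), _["Q"] = wrap(segs[k].Q));
  List wk_out(ncp);
  for (int k = 0; k < ncp; ++k) {
    List st(cps[k].wk.size());
    for (size_t j = 0; j < cps[k].wk.size(); ++j)
      st[j] = wrap(cps[k].wk[j].state);
    wk_out[k] = st;
  }
  return List::create(_["segs"] = segs_out, _["wk"] = wk_out,
                      _["siteP"] = siteP, _["siteQ"] = siteQ, _["siteA"] = siteA,
                      _["max_cfl"] = max_cfl, _["mass_defect"] = mass_defect,
                      _["maxQ"] = maxQ);
}
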