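// One-dimensional arterial pulse-wave solver.
//
// Governing equations (per segment, CGS units):
//   A_t + Q_x = 0
//   Q_t + (Q^2/A)_x + (A/rho) P_x = -Kf Q / A
// with the tube law P = Pext + beta (sqrt(A) - sqrt(A0)) / A0, where beta and
// A0 may vary along the vessel (linear taper). Discretisation is the
// two-step (Richtmyer) Lax-Wendroff scheme in conservative form with
// geometric source terms. Boundaries are coupled through Riemann invariants
// W+- = u +- 4 (c - c0): a time-varying-elastance heart (or prescribed flow)
// at the root inlet, conservation of flow and continuity of static pressure
// at junctions, and RCR windkessel (or closed / pure-resistance) terminals.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct Segment {
  int n;
  double dx;
  std::vector<double> A, Q, Aold, Qold;
  std::vector<double> A0, beta, c0n;   // per node
  std::vector<double> db, da0;         // d(beta)/dx, d(A0)/dx at nodes
  std::vector<int> children;
  // terminal: 0 none, 1 RCR, 2 pure resistance, 3 closed end
  int term_type = 0;
  double Zc = 0, Rp = 0, Cp = 0, Pout = 0, Pc = 0;
  double out_vol = 0;  // cumulative terminal outflow
};

static inline double pressure(double A, double beta, double A0, double Pext) {
  return Pext + beta * (std::sqrt(A) - std::sqrt(A0)) / A0;
}
static inline double dPdA(double A, double beta, double A0) {
  return beta / (2.0 * A0 * std::sqrt(A));
}
static inline double wave_c(double A, double A0, double c0n) {
  return c0n * std::pow(A / A0, 0.25);
}

// Momentum source: friction plus the geometric terms that keep a tapered
// vessel in equilibrium at rest.
static inline double source2(double A, double Q, double beta, double A0,
                             double db, double da0, double rho, double Kf) {
  double sA = std::sqrt(A), sA0 = std::sqrt(A0);
  double t1 = db * (std::pow(A, 1.5) / (3.0 * rho * A0) -
                    A * (sA - sA0) / (rho * A0));
  double t2 = da0 * (-beta * std::pow(A, 1.5) / (3.0 * rho * A0 * A0) +
                     (A / rho) * beta *
                         (1.0 / (2.0 * std::pow(A0, 1.5)) +
                          (sA - sA0) / (A0 * A0)));
  return -Kf * Q / A + t1 + t2;
}

// Safeguarded Newton for scalar residual f(A) on [lo, hi].
template <typename F, typename DF>
static double newton_solve(F f, DF df, double x0, double lo, double hi) {
  double x = std::min(std::max(x0, lo), hi);
  for (int it = 0; it < 60; ++it) {
    double fx = f(x);
    if (std::fabs(fx) < 1e-10 * (1.0 + std::fabs(x))) return x;
    double d = df(x);
    double step = (d != 0.0) ? fx / d : 0.0;
    double xn = x - step;
    if (!(xn > lo && xn < hi) || std::fabs(step) > 0.5 * (hi - lo)) {
      // bisection fallback using sign of f at bounds
      double flo = f(lo), fx2 = fx;
      if (flo * fx2 < 0) hi = x; else lo = x;
      xn = 0.5 * (lo + hi);
    }
    if (std::fabs(xn - x) < 1e-14 * (1.0 + std::fabs(x))) return xn;
    x = xn;
  }
  return x;
}

// Backward invariant W- = u - 4(c - c0) interpolated at the foot of the
// incoming characteristic at the left boundary (from old state).
static double foot_Wminus(const Segment& s, double dt) {
  auto Wm = [&](int i) {
    double u = s.Qold[i] / s.Aold[i];
    return u - 4.0 * (wave_c(s.Aold[i], s.A0[i], s.c0n[i]) - s.c0n[i]);
  };
  double u0 = s.Qold[0] / s.Aold[0];
  double lam = u0 - wave_c(s.Aold[0], s.A0[0], s.c0n[0]);
  double xi = std::min(std::max(-lam * dt / s.dx, 0.0), 1.0);
  return (1.0 - xi) * Wm(0) + xi * Wm(1);
}

// Forward invariant at the foot of the characteristic entering the right
// boundary.
static double foot_Wplus(const Segment& s, double dt) {
  int n = s.n;
  auto Wp = [&](int i) {
    double u = s.Qold[i] / s.Aold[i];
    return u + 4.0 * (wave_c(s.Aold[i], s.A0[i], s.c0n[i]) - s.c0n[i]);
  };
  double un = s.Qold[n - 1] / s.Aold[n - 1];
  double lam = un + wave_c(s.Aold[n - 1], s.A0[n - 1], s.c0n[n - 1]);
  double xi = std::min(std::max(lam * dt / s.dx, 0.0), 1.0);
  return (1.0 - xi) * Wp(n - 1) + xi * Wp(n - 2);
}

// Solve a junction: parent distal node + children proximal nodes.
// Unknowns A_p, A_c1..A_ck; equations: flow conservation and static
// pressure continuity. Newton with analytic Jacobian, Gaussian elimination.
static void solve_junction(Segment& par, std::vector<Segment*>& kids,
                           double dt, double rho, double Pext) {
  int k = (int)kids.size();
  int m = k + 1;
  double Wp = foot_Wplus(par, dt);
  std::vector<double> Wm(k);
  for (int j = 0; j < k; ++j) Wm[j] = foot_Wminus(*kids[j], dt);

  std::vector<double> A(m);
  A[0] = par.A[par.n - 1];
  for (int j = 0; j < k; ++j) A[j + 1] = kids[j]->A[0];

  int np = par.n - 1;
  for (int it = 0; it < 50; ++it) {
    double cp = wave_c(A[0], par.A0[np], par.c0n[np]);
    double up = Wp - 4.0 * (cp - par.c0n[np]);
    double Pp = pressure(A[0], par.beta[np], par.A0[np], Pext);
    std::vector<double> uc(k), Pc(k), cc(k);
    for (int j = 0; j < k; ++j) {
      Segment* ch = kids[j];
      cc[j] = wave_c(A[j + 1], ch->A0[0], ch->c0n[0]);
      uc[j] = Wm[j] + 4.0 * (cc[j] - ch->c0n[0]);
      Pc[j] = pressure(A[j + 1], ch->beta[0], ch->A0[0], Pext);
    }
    // residuals
    std::vector<double> F(m, 0.0);
    F[0] = up * A[0];
    for (int j = 0; j < k; ++j) F[0] -= uc[j] * A[j + 1];
    for (int j = 0; j < k; ++j) F[j + 1] = Pp - Pc[j];
    double fn = 0;
    for (int j = 0; j < m; ++j) fn += std::fabs(F[j]);
    if (fn < 1e-9) break;
    // Jacobian
    std::vector<std::vector<double>> J(m, std::vector<double>(m, 0.0));
    J[0][0] = up - cp;
    for (int j = 0; j < k; ++j) J[0][j + 1] = -(uc[j] + cc[j]);
    double dPp = dPdA(A[0], par.beta[np], par.A0[np]);
    for (int j = 0; j < k; ++j) {
      J[j + 1][0] = dPp;
      J[j + 1][j + 1] = -dPdA(A[j + 1], kids[j]->beta[0], kids[j]->A0[0]);
    }
    // solve J dx = F (Gaussian elimination with partial pivoting)
    for (int col = 0; col < m; ++col) {
      int piv = col;
      for (int r = col + 1; r < m; ++r)
        if (std::fabs(J[r][col]) > std::fabs(J[piv][col])) piv = r;
      std::swap(J[col], J[piv]);
      std::swap(F[col], F[piv]);
      for (int r = col + 1; r < m; ++r) {
        double fac = J[r][col] / J[col][col];
        for (int cc2 = col; cc2 < m; ++cc2) J[r][cc2] -= fac * J[col][cc2];
        F[r] -= fac * F[col];
      }
    }
    std::vector<double> dxv(m);
    for (int r = m - 1; r >= 0; --r) {
      double sum = F[r];
      for (int cc2 = r + 1; cc2 < m; ++cc2) sum -= J[r][cc2] * dxv[cc2];
      dxv[r] = sum / J[r][r];
    }
    for (int j = 0; j < m; ++j) {
      A[j] -= dxv[j];
      if (A[j] <= 0) A[j] = 1e-6;
    }
  }
  double cp = wave_c(A[0], par.A0[np], par.c0n[np]);
  double up = Wp - 4.0 * (cp - par.c0n[np]);
  par.A[np] = A[0];
  par.Q[np] = up * A[0];
  for (int j = 0; j < k; ++j) {
    Segment* ch = kids[j];
    double ccj = wave_c(A[j + 1], ch->A0[0], ch->c0n[0]);
    double ucj = Wm[j] + 4.0 * (ccj - ch->c0n[0]);
    ch->A[0] = A[j + 1];
    ch->Q[0] = ucj * A[j + 1];
  }
}

// [[Rcpp::export]]
List solve_tree_1d(List seg_list, double rho, double Kf, double Pext,
                   double dt, int nsteps, int steps_per_beat,
                   int inlet_type, NumericVector inflow,
                   List heart, IntegerVector mon_seg, IntegerVector mon_node,
                   int mon_every) {
  int nseg = seg_list.size();
  std::vector<Segment> segs(nseg);
  for (int s = 0; s < nseg; ++s) {
    List sl = seg_list[s];
    Segment& sg = segs[s];
    NumericVector A0 = sl["A0"], beta = sl["beta"];
    sg.n = A0.size();
    sg.dx = as<double>(sl["dx"]);
    sg.A0.assign(A0.begin(), A0.end());
    sg.beta.assign(beta.begin(), beta.end());
    sg.A.assign(A0.begin(), A0.end());
    sg.Q.assign(sg.n, 0.0);
    sg.c0n.resize(sg.n);
    for (int i = 0; i < sg.n; ++i)
      sg.c0n[i] = std::sqrt(sg.beta[i] / (2.0 * rho * std::sqrt(sg.A0[i])));
    sg.db.assign(sg.n, 0.0);
    sg.da0.assign(sg.n, 0.0);
    for (int i = 1; i < sg.n - 1; ++i) {
      sg.db[i] = (sg.beta[i + 1] - sg.beta[i - 1]) / (2 * sg.dx);
      sg.da0[i] = (sg.A0[i + 1] - sg.A0[i - 1]) / (2 * sg.dx);
    }
    if (sg.n > 1) {
      sg.db[0] = (sg.beta[1] - sg.beta[0]) / sg.dx;
      sg.da0[0] = (sg.A0[1] - sg.A0[0]) / sg.dx;
      sg.db[sg.n - 1] = (sg.beta[sg.n - 1] - sg.beta[sg.n - 2]) / sg.dx;
      sg.da0[sg.n - 1] = (sg.A0[sg.n - 1] - sg.A0[sg.n - 2]) / sg.dx;
    }
    IntegerVector ch = sl["children"];
    sg.children.assign(ch.begin(), ch.end());
    sg.term_type = as<int>(sl["term_type"]);
    if (sg.term_type == 1 || sg.term_type == 2) {
      sg.Zc = as<double>(sl["Zc"]);
      sg.Rp = as<double>(sl["Rp"]);
      sg.Cp = as<double>(sl["Cp"]);
      sg.Pout = as<double>(sl["Pout"]);
      sg.Pc = Pext;
    }
  }

  // heart parameters
  NumericVector Evec;
  double V0 = 0, Vv = 0, Pfill = 0, Rmit = 1, Kv = 0;
  bool valve_open = false;
  if (inlet_type == 1) {
    Evec = as<NumericVector>(heart["E"]);
    V0 = as<double>(heart["V0"]);
    Vv = as<double>(heart["Vinit"]);
    Pfill = as<double>(heart["Pfill"]);
    Rmit = as<double>(heart["Rmit"]);
    Kv = as<double>(heart["Kv"]);
  }

  int nmon = mon_seg.size();
  int nrec = nsteps / mon_every + 1;
  NumericMatrix recP(nrec, nmon), recQ(nrec, nmon), recA(nrec, nmon);
  NumericVector rec_t(nrec);
  NumericVector heart_Pv(nrec), heart_V(nrec), heart_Qin(nrec);

  int nbeats = nsteps / steps_per_beat;
  NumericVector beat_pp(nbeats), inlet_vol_beat(nbeats),
      outlet_vol_beat(nbeats), stored_vol(nbeats + 1);
  double rootP_min = 1e300, rootP_max = -1e300;
  double inlet_vol = 0;

  auto domain_volume = [&]() {
    double v = 0;
    for (auto& sg : segs) {
      for (int i = 0; i < sg.n; ++i) {
        double w = (i == 0 || i == sg.n - 1) ? 0.5 : 1.0;
        v += w * sg.A[i] * sg.dx;
      }
    }
    return v;
  };
  stored_vol[0] = domain_volume();
  double out_acc_prev = 0;

  auto record = [&](int rec_idx, double t) {
    rec_t[rec_idx] = t;
    for (int m = 0; m < nmon; ++m) {
      Segment& sg = segs[mon_seg[m]];
      int i = mon_node[m];
      recP(rec_idx, m) = pressure(sg.A[i], sg.beta[i], sg.A0[i], Pext);
      recQ(rec_idx, m) = sg.Q[i];
      recA(rec_idx, m) = sg.A[i];
    }
    if (inlet_type == 1) {
      heart_Pv[rec_idx] = Evec[std::min((int)Evec.size() - 1,
                                        rec_idx * mon_every)] * (Vv - V0);
      heart_V[rec_idx] = Vv;
      heart_Qin[rec_idx] = segs[0].Q[0];
    }
  };
  record(0, 0.0);

  bool negative_area = false;
  bool cfl_violated = false;

  for (int step = 1; step <= nsteps; ++step) {
    double t_new = step * dt;
    // save old state
    for (auto& sg : segs) {
      sg.Aold = sg.A;
      sg.Qold = sg.Q;
    }
    // CFL check
    for (auto& sg : segs) {
      for (int i = 0; i < sg.n; ++i) {
        double u = std::fabs(sg.Q[i] / sg.A[i]);
        double c = wave_c(sg.A[i], sg.A0[i], sg.c0n[i]);
        if ((u + c) * dt / sg.dx > 1.0) { cfl_violated = true; }
      }
    }
    if (cfl_violated) break;

    // interior update, segment by segment; keep half-step fluxes adjacent
    // to the boundaries for the conservative boundary closure below
    std::vector<double> Qh_first(nseg), Qh_last(nseg);
    for (int sidx = 0; sidx < nseg; ++sidx) {
      Segment& sg = segs[sidx];
      int n = sg.n;
      std::vector<double> Ah(n - 1), Qh(n - 1), F2h(n - 1), S2h(n - 1);
      for (int i = 0; i < n - 1; ++i) {
        double bA = 0.5 * (sg.beta[i] + sg.beta[i + 1]);
        double A0h = 0.5 * (sg.A0[i] + sg.A0[i + 1]);
        double dbh = (sg.beta[i + 1] - sg.beta[i]) / sg.dx;
        double da0h = (sg.A0[i + 1] - sg.A0[i]) / sg.dx;
        double F2i = sg.Qold[i] * sg.Qold[i] / sg.Aold[i] +
                     sg.beta[i] * std::pow(sg.Aold[i], 1.5) /
                         (3.0 * rho * sg.A0[i]);
        double F2ip = sg.Qold[i + 1] * sg.Qold[i + 1] / sg.Aold[i + 1] +
                      sg.beta[i + 1] * std::pow(sg.Aold[i + 1], 1.5) /
                          (3.0 * rho * sg.A0[i + 1]);
        double S2i = source2(sg.Aold[i], sg.Qold[i], sg.beta[i], sg.A0[i],
                             sg.db[i], sg.da0[i], rho, Kf);
        double S2ip = source2(sg.Aold[i + 1], sg.Qold[i + 1], sg.beta[i + 1],
                              sg.A0[i + 1], sg.db[i + 1], sg.da0[i + 1], rho,
                              Kf);
        Ah[i] = 0.5 * (sg.Aold[i] + sg.Aold[i + 1]) -
                dt / (2 * sg.dx) * (sg.Qold[i + 1] - sg.Qold[i]);
        Qh[i] = 0.5 * (sg.Qold[i] + sg.Qold[i + 1]) -
                dt / (2 * sg.dx) * (F2ip - F2i) + dt / 4.0 * (S2i + S2ip);
        if (Ah[i] <= 0) { negative_area = true; Ah[i] = 1e-6; }
        F2h[i] = Qh[i] * Qh[i] / Ah[i] +
                 bA * std::pow(Ah[i], 1.5) / (3.0 * rho * A0h);
        S2h[i] = source2(Ah[i], Qh[i], bA, A0h, dbh, da0h, rho, Kf);
      }
      for (int i = 1; i < n - 1; ++i) {
        sg.A[i] = sg.Aold[i] - dt / sg.dx * (Qh[i] - Qh[i - 1]);
        sg.Q[i] = sg.Qold[i] - dt / sg.dx * (F2h[i] - F2h[i - 1]) +
                  dt * 0.5 * (S2h[i] + S2h[i - 1]);
        if (sg.A[i] <= 0) { negative_area = true; sg.A[i] = 1e-6; }
      }
      Qh_first[sidx] = Qh[0];
      Qh_last[sidx] = Qh[n - 2];
    }
    if (negative_area) break;

    // Conservative half-cell area update at a boundary node, given the
    // physical boundary flux Qb solved from the characteristic coupling:
    // guarantees machine-exact volume balance of the whole tree.
    auto close_left = [&](Segment& sg, int sidx, double Qb) {
      sg.A[0] = sg.Aold[0] - dt / (0.5 * sg.dx) * (Qh_first[sidx] - Qb);
      if (sg.A[0] <= 0) { negative_area = true; sg.A[0] = 1e-6; }
      sg.Q[0] = Qb;
    };
    auto close_right = [&](Segment& sg, int sidx, double Qb) {
      int nn = sg.n - 1;
      sg.A[nn] = sg.Aold[nn] - dt / (0.5 * sg.dx) * (Qb - Qh_last[sidx]);
      if (sg.A[nn] <= 0) { negative_area = true; sg.A[nn] = 1e-6; }
      sg.Q[nn] = Qb;
    };

    // ---- inlet boundary (root = segment 0) ----
    {
      Segment& rt = segs[0];
      double Wm = foot_Wminus(rt, dt);
      double A0n = rt.A0[0], c0n = rt.c0n[0], b0 = rt.beta[0];
      if (inlet_type == 0) {
        double Qt = inflow[std::min(step, (int)inflow.size() - 1)];
        auto f = [&](double A) {
          double u = Wm + 4.0 * (wave_c(A, A0n, c0n) - c0n);
          return u * A - Qt;
        };
        auto df = [&](double A) {
          double u = Wm + 4.0 * (wave_c(A, A0n, c0n) - c0n);
          return u + wave_c(A, A0n, c0n);
        };
        double A = newton_solve(f, df, rt.A[0], 0.05 * A0n, 20.0 * A0n);
        close_left(rt, 0, (Wm + 4.0 * (wave_c(A, A0n, c0n) - c0n)) * A);
      } else {
        double E = Evec[std::min(step, (int)Evec.size() - 1)];
        double Pv = E * (Vv - V0);
        double Qin = 0;
        // closed-valve boundary state (u = 0)
        double c_closed = std::max(c0n - Wm / 4.0, 0.1 * c0n);
        double A_closed = A0n * std::pow(c_closed / c0n, 4.0);
        double P_closed = pressure(A_closed, b0, A0n, Pext);
        if (!valve_open && Pv > P_closed) valve_open = true;
        if (valve_open) {
          auto uofA = [&](double A) {
            return Wm + 4.0 * (wave_c(A, A0n, c0n) - c0n);
          };
          auto f = [&](double A) {
            double u = uofA(A);
            double Q = u * A;
            double Pv_new = E * (Vv - dt * Q - V0);
            return Pv_new - pressure(A, b0, A0n, Pext) -
                   Kv * Q * std::fabs(Q);
          };
          auto df = [&](double A) {
            double u = uofA(A);
            double c = wave_c(A, A0n, c0n);
            double dQ = u + c;
            return -E * dt * dQ - dPdA(A, b0, A0n) -
                   2.0 * Kv * std::fabs(u * A) * dQ;
          };
          double A = newton_solve(f, df, rt.A[0], 0.05 * A0n, 20.0 * A0n);
          double u = uofA(A);
          Qin = u * A;
          if (Qin <= 0) {
            valve_open = false;
            Qin = 0;
          }
          close_left(rt, 0, Qin);
        } else {
          close_left(rt, 0, 0.0);
        }
        // ventricular volume update: ejection and mitral filling
        double Qmit = (Pfill > Pv && !valve_open)
                          ? (Pfill - Pv) / Rmit : 0.0;
        Vv += dt * (Qmit - Qin);
      }
      inlet_vol += rt.Q[0] * dt;
    }

    // ---- junctions ----
    for (int s = 0; s < nseg; ++s) {
      if (segs[s].children.empty()) continue;
      std::vector<Segment*> kids;
      for (int c : segs[s].children) kids.push_back(&segs[c]);
      solve_junction(segs[s], kids, dt, rho, Pext);
      close_right(segs[s], s, segs[s].Q[segs[s].n - 1]);
      for (int c : segs[s].children) close_left(segs[c], c, segs[c].Q[0]);
    }

    // ---- terminals ----
    for (int sidx = 0; sidx < nseg; ++sidx) {
      Segment& sg = segs[sidx];
      if (sg.term_type == 0) continue;
      int nn = sg.n - 1;
      double Wp = foot_Wplus(sg, dt);
      double A0n = sg.A0[nn], c0n = sg.c0n[nn], bn = sg.beta[nn];
      auto uofA = [&](double A) {
        return Wp - 4.0 * (wave_c(A, A0n, c0n) - c0n);
      };
      if (sg.term_type == 3) {  // closed end
        close_right(sg, sidx, 0.0);
      } else if (sg.term_type == 2) {  // pure resistance P = Pout + Rt Q
        double Rt = sg.Zc + sg.Rp;
        auto f = [&](double A) {
          return pressure(A, bn, A0n, Pext) - sg.Pout - Rt * uofA(A) * A;
        };
        auto df = [&](double A) {
          double u = uofA(A);
          return dPdA(A, bn, A0n) - Rt * (u - wave_c(A, A0n, c0n));
        };
        double A = newton_solve(f, df, sg.A[nn], 0.05 * A0n, 20.0 * A0n);
        close_right(sg, sidx, uofA(A) * A);
      } else {  // RCR: semi-implicit compliance update
        double fac = 1.0 + dt / (sg.Rp * sg.Cp);
        auto pc_new = [&](double Q) {
          return (sg.Pc + (dt / sg.Cp) * (Q + sg.Pout / sg.Rp)) / fac;
        };
        auto f = [&](double A) {
          double Q = uofA(A) * A;
          return pressure(A, bn, A0n, Pext) - sg.Zc * Q - pc_new(Q);
        };
        auto df = [&](double A) {
          double u = uofA(A);
          double dQ = u - wave_c(A, A0n, c0n);
          return dPdA(A, bn, A0n) - (sg.Zc + (dt / sg.Cp) / fac) * dQ;
        };
        double A = newton_solve(f, df, sg.A[nn], 0.05 * A0n, 20.0 * A0n);
        double Q = uofA(A) * A;
        close_right(sg, sidx, Q);
        sg.Pc = pc_new(Q);
      }
      sg.out_vol += sg.Q[nn] * dt;
    }

    if (negative_area) break;

    // root pressure extrema for per-beat pulse pressure
    {
      Segment& rt = segs[0];
      double p0 = pressure(rt.A[0], rt.beta[0], rt.A0[0], Pext);
      if (p0 < rootP_min) rootP_min = p0;
      if (p0 > rootP_max) rootP_max = p0;
    }
    if (step % steps_per_beat == 0) {
      int b = step / steps_per_beat - 1;
      if (b >= 0 && b < nbeats) {
        beat_pp[b] = rootP_max - rootP_min;
        rootP_min = 1e300; rootP_max = -1e300;
        inlet_vol_beat[b] = inlet_vol;
        inlet_vol = 0;
        double out_acc = 0;
        for (auto& sg : segs) out_acc += sg.out_vol;
        outlet_vol_beat[b] = out_acc - out_acc_prev;
        out_acc_prev = out_acc;
        stored_vol[b + 1] = domain_volume();
      }
    }
    if (step % mon_every == 0) record(step / mon_every, t_new);
  }

  if (cfl_violated) stop("CFL condition violated during the run");
  if (negative_area) stop("negative cross-sectional area: simulation aborted");

  return List::create(
      _["t"] = rec_t, _["P"] = recP, _["Q"] = recQ, _["A"] = recA,
      _["heart_Pv"] = heart_Pv, _["heart_V"] = heart_V,
      _["heart_Qin"] = heart_Qin,
      _["beat_pp"] = beat_pp, _["inlet_vol_beat"] = inlet_vol_beat,
      _["outlet_vol_beat"] = outlet_vol_beat, _["stored_vol"] = stored_vol);
}
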