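// Two-step (Richtmyer) Lax-Wendroff solver for the 1D cross-section-
// averaged blood flow equations on a bifurcating tree:
//   dA/dt + dQ/dx = 0
//   dQ/dt + d(Q^2/A + B(A))/dx = -(2 pi nu r / delta) (Q/A)
// with B(A) = (1/rho) int A dP/dA dA so that the pressure-gradient term
// is in conservation form (the tube law is uniform along a segment).
// Boundaries are closed with outgoing Riemann invariants
//   W+- = Q/A +- I(A),  I(A) = int c(a)/a da,  c = sqrt(A P'(A)/rho):
// prescribed inflow at the root, continuity of pressure and flow at
// junctions, and an implicit-Euler three-element Windkessel (RCR) at
// terminals. All quantities are SI.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <sstream>
using namespace Rcpp;

namespace {

struct Tables {
  // per-segment uniform-in-A lookup tables
  int m;
  std::vector<double> Amin, dA;          // per segment
  NumericMatrix P, dP, B, I;             // m x n_seg
};

inline double interp(const NumericMatrix& tab, const Tables& T, int s,
                     double a, bool* out_of_range) {
  double x = (a - T.Amin[s]) / T.dA[s];
  if (x < 0) { x = 0; *out_of_range = true; }
  if (x > T.m - 1) { x = T.m - 1; *out_of_range = true; }
  int i = (int)x;
  if (i > T.m - 2) i = T.m - 2;
  double f = x - i;
  return (1 - f) * tab(i, s) + f * tab(i + 1, s);
}

// invert the monotone P table: area with P(area) = p (clamped to range)
inline double inv_pressure(const Tables& T, int s, double p,
                           bool* out_of_range) {
  int lo = 0, hi = T.m - 1;
  if (p <= T.P(0, s)) { *out_of_range = true; return T.Amin[s]; }
  if (p >= T.P(hi, s)) { *out_of_range = true;
    return T.Amin[s] + T.dA[s] * (T.m - 1); }
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (T.P(mid, s) <= p) lo = mid; else hi = mid;
  }
  double f = (p - T.P(lo, s)) / (T.P(hi, s) - T.P(lo, s));
  return T.Amin[s] + T.dA[s] * (lo + f);
}

struct BoundaryFn {
  // residual of a scalar boundary closure in the boundary area
  virtual double operator()(double a) const = 0;
  virtual ~BoundaryFn() {}
};

// bisection + secant refinement on a decreasing-or-increasing residual
inline double solve_boundary(const BoundaryFn& f, double lo, double hi,
                             double* defect) {
  double flo = f(lo), fhi = f(hi);
  bool increasing = fhi > flo;
  if ((flo > 0) == (fhi > 0)) {
    // no sign change in range: take endpoint with smaller |residual|
    *defect = std::min(std::fabs(flo), std::fabs(fhi));
    return std::fabs(flo) < std::fabs(fhi) ? lo : hi;
  }
  for (int it = 0; it < 35; ++it) {
    double mid = 0.5 * (lo + hi), fm = f(mid);
    if ((fm > 0) == increasing) hi = mid; else lo = mid;
  }
  // secant polish, keeping the best iterate
  double x0 = lo, x1 = hi, f0 = f(lo), f1 = f(hi);
  double best = std::fabs(f0) < std::fabs(f1) ? x0 : x1;
  double bestf = std::min(std::fabs(f0), std::fabs(f1));
  for (int it = 0; it < 25; ++it) {
    double denom = f1 - f0;
    if (denom == 0) break;
    double x2 = x1 - f1 * (x1 - x0) / denom;
    if (!std::isfinite(x2)) break;
    double f2 = f(x2);
    x0 = x1; f0 = f1; x1 = x2; f1 = f2;
    if (std::fabs(f2) < bestf) { bestf = std::fabs(f2); best = x2; }
    if (bestf == 0) break;
  }
  *defect = bestf;
  return best;
}

// warm-started Newton (numeric derivative) with bisection fallback;
// `guess` is typically the previous time step's solution
inline double solve_boundary_warm(const BoundaryFn& f, double lo, double hi,
                                  double guess, double* defect) {
  double x = guess;
  if (!(x > lo) || !(x < hi)) x = 0.5 * (lo + hi);
  double fx = f(x);
  double best = x, bestf = std::fabs(fx);
  for (int it = 0; it < 12; ++it) {
    if (bestf < 1e-17) { *defect = bestf; return best; }
    const double h = 1e-8 * x;
    const double fp = (f(x + h) - fx) / h;
    if (fp == 0 || !std::isfinite(fp)) break;
    const double xn = x - fx / fp;
    if (!(xn > lo) || !(xn < hi) || !std::isfinite(xn)) break;
    x = xn;
    fx = f(x);
    if (std::fabs(fx) < bestf) { bestf = std::fabs(fx); best = x; }
  }
  if (bestf < 1e-17) { *defect = bestf; return best; }
  return solve_boundary(f, lo, hi, defect);
}

} // namespace

// [[Rcpp::export(name = ".solve_tree_cpp")]]
List solve_tree_cpp(IntegerVector nn, NumericVector dx,
                    IntegerVector child1, IntegerVector child2, int root,
                    NumericVector tab_Amin, NumericVector tab_dA,
                    NumericMatrix tab_P, NumericMatrix tab_dP,
                    NumericMatrix tab_B, NumericMatrix tab_I,
                    NumericVector A0,
                    NumericVector qin, double T,
                    NumericVector R1, NumericVector R2, NumericVector Cd,
                    double rho, double fric0,
                    int n_steps, int n_out, int n_cycles_max, double tol,
                    double eps_filter) {
  const int n_seg = nn.size();
  const double dt = T / n_steps;
  const int out_every = n_steps / n_out;
  const int n_in = qin.size();
  const double dt_in = T / n_in;

  Tables Tb;
  Tb.m = tab_P.nrow();
  Tb.Amin.assign(tab_Amin.begin(), tab_Amin.end());
  Tb.dA.assign(tab_dA.begin(), tab_dA.end());
  Tb.P = tab_P; Tb.dP = tab_dP; Tb.B = tab_B; Tb.I = tab_I;

  std::vector<int> off(n_seg + 1, 0);
  for (int s = 0; s < n_seg; ++s) off[s + 1] = off[s] + nn[s];
  const int n_tot = off[n_seg];

  std::vector<double> A(n_tot), Q(n_tot, 0.0);
  for (int s = 0; s < n_seg; ++s)
    for (int j = 0; j < nn[s]; ++j) A[off[s] + j] = A0[s];

  std::vector<double> p_term(n_seg, 0.0), q_term(n_seg, 0.0);
  std::vector<double> q_junc(n_seg, 0.0);
  std::vector<double> F1(n_tot), F2(n_tot), S2(n_tot);
  std::vector<double> Ah(n_tot), Qh(n_tot);     // half-step (staggered)
  std::vector<double> An(n_tot), Qn(n_tot);

  // output buffers: current and previous cycle
  NumericMatrix Pcur(n_tot, n_out), Pprev(n_tot, n_out);
  NumericMatrix Aout(n_tot, n_out), Qout(n_tot, n_out);

  bool out_of_range = false;   // physical states off-table
  bool probe_oor = false;      // root-bracketing probes (benign)
  double max_defect = 0.0, max_cfl = 0.0;
  int cycles_done = 0;
  bool converged = false;
  double cycle_resid = NA_REAL;

  auto fail = [&](const std::string& what, int s, int j, double t) {
    std::ostringstream ss;
    ss << what << " (segment index " << s + 1 << ", grid index " << j + 1
       << ", t = " << t << " s)";
    stop(ss.str());
  };

  for (int cyc = 0; cyc < n_cycles_max && !converged; ++cyc) {
    for (int step = 0; step < n_steps; ++step) {
      const double t_new = (cyc * (double)n_steps + step + 1) * dt;

      // fluxes, sources, CFL at time n
      for (int s = 0; s < n_seg; ++s) {
        for (int j = 0; j < nn[s]; ++j) {
          const int k = off[s] + j;
          const double a = A[k], q = Q[k];
          if (!(a > 0) || !std::isfinite(a) || !std::isfinite(q))
            fail("negative area or non-finite state", s, j, t_new);
          F1[k] = q;
          F2[k] = q * q / a + interp(Tb.B, Tb, s, a, &out_of_range);
          S2[k] = -fric0 * q / std::sqrt(M_PI * a);
          const double dPa = interp(Tb.dP, Tb, s, a, &out_of_range);
          const double c = std::sqrt(a * dPa / rho);
          const double sp = (std::fabs(q / a) + c) * dt / dx[s];
          if (sp > max_cfl) max_cfl = sp;
          if (sp > 1.0)
            fail("CFL condition violated; reduce the Courant number",
                 s, j, t_new);
        }
      }

      // Richtmyer half step (values at j+1/2) and interior update
      for (int s = 0; s < n_seg; ++s) {
        const int o = off[s];
        const double lam = dt / dx[s];
        for (int j = 0; j < nn[s] - 1; ++j) {
          const int k = o + j;
          Ah[k] = 0.5 * (A[k] + A[k + 1]) - 0.5 * lam * (F1[k + 1] - F1[k]);
          Qh[k] = 0.5 * (Q[k] + Q[k + 1]) - 0.5 * lam * (F2[k + 1] - F2[k])
                  + 0.25 * dt * (S2[k] + S2[k + 1]);
        }
        for (int j = 0; j < nn[s] - 1; ++j) {
          const int k = o + j;
          const double a = Ah[k], q = Qh[k];
          if (!(a > 0) || !std::isfinite(a))
            fail("negative area at half step", s, j, t_new);
          F1[k] = q;                      // reuse flux arrays (half-step)
          F2[k] = q * q / a + interp(Tb.B, Tb, s, a, &out_of_range);
          S2[k] = -fric0 * q / std::sqrt(M_PI * a);
        }
        for (int j = 1; j < nn[s] - 1; ++j) {
          const int k = o + j;
          An[k] = A[k] - lam * (F1[k] - F1[k - 1]);
          Qn[k] = Q[k] - lam * (F2[k] - F2[k - 1])
                  + 0.5 * dt * (S2[k] + S2[k - 1]);
        }
      }

      // Boundary closures in conservative (half-cell flux) form: every
      // boundary node owns a half cell whose inner flux is the half-step
      // (Richtmyer) flux already computed, and whose outer flux is either
      // prescribed (inlet) or the solve unknown (junctions, terminals).
      // Mass then telescopes exactly through the whole tree: per-cycle
      // inlet volume equals the summed terminal outflow volumes at
      // machine precision once the run is periodic.

      // inlet: prescribed flow; half-cell update of the boundary area
      {
        const int s = root, o = off[s];
        double th = (t_new - 0.5 * dt);
        th -= T * std::floor(th / T);
        double ti = th / dt_in;
        int i0 = (int)ti; double fr = ti - i0;
        i0 %= n_in; int i1 = (i0 + 1) % n_in;
        const double q_half = (1 - fr) * qin[i0] + fr * qin[i1];
        double tn1 = t_new - T * std::floor(t_new / T);
        double tj = tn1 / dt_in;
        int j0 = (int)tj; double fj = tj - j0;
        j0 %= n_in; int j1 = (j0 + 1) % n_in;
        An[o] = A[o] + (dt / (0.5 * dx[s])) * (q_half - F1[o]);
        Qn[o] = (1 - fj) * qin[j0] + fj * qin[j1];
        if (!(An[o] > 0) || !std::isfinite(An[o]))
          fail("negative area at inlet", s, 0, t_new);
      }

      // junctions: unknown parent boundary flux; children areas follow
      // from pressure continuity, their fluxes from their own half-cell
      // balances, and the flux residual closes the system
      for (int s = 0; s < n_seg; ++s) {
        if (child1[s] < 0) continue;
        const int c1 = child1[s], c2 = child2[s];
        const int oP = off[s], nP = nn[s], o1 = off[c1], o2 = off[c2];
        struct JuncFn : BoundaryFn {
          const Tables* Tb; int s, c1, c2;
          double aP_n, a1_n, a2_n, QhP, Qh1, Qh2, rP, r1, r2; bool* oor;
          mutable double aP, a1, a2, q1, q2, pp;
          double operator()(double qb) const {
            aP = aP_n + rP * (QhP - qb);
            pp = interp(Tb->P, *Tb, s, aP, oor);
            a1 = inv_pressure(*Tb, c1, pp, oor);
            a2 = inv_pressure(*Tb, c2, pp, oor);
            q1 = Qh1 + (a1 - a1_n) / r1;
            q2 = Qh2 + (a2 - a2_n) / r2;
            return qb - q1 - q2;
          }
        } f;
        f.Tb = &Tb; f.s = s; f.c1 = c1; f.c2 = c2;
        f.aP_n = A[oP + nP - 1]; f.a1_n = A[o1]; f.a2_n = A[o2];
        f.QhP = F1[oP + nP - 2]; f.Qh1 = F1[o1]; f.Qh2 = F1[o2];
        f.rP = dt / (0.5 * dx[s]);
        f.r1 = dt / (0.5 * dx[c1]); f.r2 = dt / (0.5 * dx[c2]);
        f.oor = &probe_oor;
        // flux bounds keep the parent area inside the table
        const double aLo = Tb.Amin[s];
        const double aHi = Tb.Amin[s] + Tb.dA[s] * (Tb.m - 1);
        const double qLo = f.QhP + (f.aP_n - aHi) / f.rP;
        const double qHi = f.QhP + (f.aP_n - aLo) / f.rP;
        double defect;
        const double qb = solve_boundary_warm(f, qLo, qHi, q_junc[s],
                                              &defect);
        q_junc[s] = qb;
        f(qb);
        if (defect > max_defect) max_defect = defect;
        An[oP + nP - 1] = f.aP;  Qn[oP + nP - 1] = qb;
        An[o1] = f.a1;           Qn[o1] = f.q1;
        An[o2] = f.a2;           Qn[o2] = f.q2;
        if (!(f.aP > 0) || !(f.a1 > 0) || !(f.a2 > 0))
          fail("negative area at junction", s, nP - 1, t_new);
      }

      // terminals: unknown outflow flux feeding the implicit-Euler RCR
      // Windkessel (or a pure resistance when Cd is not finite)
      for (int s = 0; s < n_seg; ++s) {
        if (child1[s] >= 0) continue;   // not a terminal
        const int o = off[s], n = nn[s];
        const bool resistive = (R2[s] <= 0.0) || (Cd[s] <= 0.0);
        const double kfac = resistive ? 0.0 : dt / (R2[s] * Cd[s]);
        struct TermFn : BoundaryFn {
          const Tables* Tb; int s;
          double a_n, Qh, r, R1, R2, k, p_old, q_old;
          bool resistive; bool* oor;
          mutable double a, p;
          double operator()(double qb) const {
            a = a_n + r * (Qh - qb);
            const double pa = interp(Tb->P, *Tb, s, a, oor);
            p = pa;
            if (resistive) return pa - (R1 + R2) * qb;
            return pa * (1 + k) - p_old - R1 * (qb - q_old)
                   - k * (R1 + R2) * qb;
          }
        } f;
        f.Tb = &Tb; f.s = s; f.a_n = A[o + n - 1]; f.Qh = F1[o + n - 2];
        f.r = dt / (0.5 * dx[s]);
        f.R1 = R1[s]; f.R2 = R2[s]; f.k = kfac;
        f.p_old = p_term[s]; f.q_old = q_term[s];
        f.resistive = resistive; f.oor = &probe_oor;
        const double aLo = Tb.Amin[s];
        const double aHi = Tb.Amin[s] + Tb.dA[s] * (Tb.m - 1);
        const double qLo = f.Qh + (f.a_n - aHi) / f.r;
        const double qHi = f.Qh + (f.a_n - aLo) / f.r;
        double defect;
        const double qb = solve_boundary_warm(f, qLo, qHi, q_term[s],
                                              &defect);
        f(qb);
        An[o + n - 1] = f.a;  Qn[o + n - 1] = qb;
        p_term[s] = f.p;  q_term[s] = qb;
        if (!(f.a > 0)) fail("negative area at terminal", s, n - 1, t_new);
      }

      // conservative 2nd-difference filter on interior nodes: the
      // two-step scheme's half-state averaging makes the odd-even grid
      // mode invisible to the interior update, so it is damped here
      // explicitly; physiological wavelengths are essentially untouched
      if (eps_filter > 0) {
        for (int s = 0; s < n_seg; ++s) {
          const int o = off[s], n = nn[s];
          // area: flux form with zero end fluxes and half-cell weights at
          // the boundary nodes, so the filter moves no mass
          Ah[o] = An[o] + 2 * eps_filter * (An[o + 1] - An[o]);
          Ah[o + n - 1] = An[o + n - 1] +
            2 * eps_filter * (An[o + n - 2] - An[o + n - 1]);
          for (int j = 1; j < n - 1; ++j) {
            const int k = o + j;
            Ah[k] = An[k] + eps_filter * (An[k + 1] - 2 * An[k] + An[k - 1]);
            Qh[k] = Qn[k] + eps_filter * (Qn[k + 1] - 2 * Qn[k] + Qn[k - 1]);
          }
          for (int j = 0; j < n; ++j) An[o + j] = Ah[o + j];
          for (int j = 1; j < n - 1; ++j) Qn[o + j] = Qh[o + j];
        }
      }

      A.swap(An); Q.swap(Qn);
      // note: An/Qn now hold stale data; interior loop rewrites all
      // interior nodes and boundary solves rewrite ends each step, but
      // the swap requires every node to be set; copy to be safe
      An = A; Qn = Q;

      if ((step + 1) % out_every == 0) {
        const int k_out = (step + 1) / out_every - 1;
        for (int s = 0; s < n_seg; ++s)
          for (int j = 0; j < nn[s]; ++j) {
            const int k = off[s] + j;
            Aout(k, k_out) = A[k];
            Qout(k, k_out) = Q[k];
            Pcur(k, k_out) = interp(Tb.P, Tb, s, A[k], &out_of_range);
          }
      }
    }
    cycles_done = cyc + 1;
    if (cyc >= 1) {
      double num = 0, den = 0;
      for (int k = 0; k < n_tot; ++k)
        for (int j = 0; j < n_out; ++j) {
          const double d = Pcur(k, j) - Pprev(k, j);
          num += d * d; den += Pcur(k, j) * Pcur(k, j);
        }
      cycle_resid = std::sqrt(num / (den + 1e-300));
      if (cycle_resid < tol) converged = true;
    }
    if (!converged) std::swap(Pcur, Pprev);
  }
  if (converged) {} else std::swap(Pcur, Pprev); // undo last swap

  return List::create(
    _["A"] = Aout, _["Q"] = Qout, _["P"] = Pcur,
    _["offsets"] = IntegerVector(off.begin(), off.end()),
    _["n_cycles"] = cycles_done, _["converged"] = converged,
    _["cycle_resid"] = cycle_resid, _["max_mass_defect"] = max_defect,
    _["max_cfl"] = max_cfl, _["table_clamped"] = out_of_range);
}
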