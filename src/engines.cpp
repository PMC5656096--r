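// Event-driven engines for the age-structured birth-death-diffusion model,
// its coarse-grained (age-free) stochastic reduction, and the hybrid
// mean-field/stochastic scheme with a moving interface.
//
// Unit conventions: time in minutes, per-minute rates, space in lattice units
// (diffusivities enter as D/h^2), oxygen in uM.  All randomness comes from
// R's RNG via Rcpp, so set.seed() on the R side makes runs reproducible.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// ---------------------------------------------------------------------------
// Cell-cycle: oxygen-dependent age at the G1/S transition (MFPT summary).
// branch 1: a_plus * exp(-c/c0);  branch 2: a_minus*(c/c_cr - 1)^(-beta),
// infinite (quiescent) at or below c_cr.
struct CellCycle {
  int branch;
  double a_plus, a_minus, beta, c_cr, c0;
  double age_g1s(double c) const {
    if (branch == 1) return a_plus * std::exp(-c / c0);
    if (c <= c_cr) return INF;
    return a_minus * std::pow(c / c_cr - 1.0, -beta);
  }
};

// ---------------------------------------------------------------------------
// Euler-Lotka root: unique real lambda with 2 b e^{-(lambda+nu)A} = lambda+nu+b.
static double lambda_root(double A, double nu, double b) {
  if (!R_FINITE(A)) return -nu;       // no cell ever matures: pure death
  if (A <= 0.0) return b - nu;        // exponential is 1: closed form
  double lo = -nu, hi = b - nu;       // g(lo) = b > 0, g(hi) <= 0
  for (int it = 0; it < 200; ++it) {
    double mid = 0.5 * (lo + hi);
    double g = 2.0 * b * std::exp(-(mid + nu) * A) - (mid + nu + b);
    if (g > 0.0) lo = mid; else hi = mid;
    if (hi - lo < 1e-15 * (1.0 + std::fabs(mid))) break;
  }
  return 0.5 * (lo + hi);
}

// [[Rcpp::export(name = ".lambda_root_cpp")]]
double lambda_root_cpp(double A, double nu, double b) {
  return lambda_root(A, nu, b);
}

// Equilibrium age distribution: piecewise exponential with hazard-like rates
// r1 = lambda+nu on [0, A), r2 = lambda+nu+b on [A, Inf).
struct EqAge {
  double r1, r2, A, Z1, Z2, Z;
  void set(double lambda, double nu, double b, double A_) {
    A = A_;
    r1 = lambda + nu;
    r2 = lambda + nu + b;
    if (r1 <= 0.0) stop("equilibrium age distribution not normalisable (r1 <= 0)");
    if (R_FINITE(A)) {
      Z1 = -std::expm1(-r1 * A) / r1;
      Z2 = std::exp(-r1 * A) / r2;
    } else {
      Z1 = 1.0 / r1;
      Z2 = 0.0;
    }
    Z = Z1 + Z2;
  }
  double sample() const {
    double u = unif_rand();
    double uz = u * Z;
    if (uz < Z1 || Z2 == 0.0) {
      return -std::log1p(-uz * r1) / r1;
    }
    double w = (1.0 - u) * Z;             // upper-tail mass, <= Z2
    return A + (std::log(Z2) - std::log(w)) / r2;
  }
};

// [[Rcpp::export(name = ".eqage_sample_cpp")]]
NumericVector eqage_sample_cpp(int n, double lambda, double nu, double b, double A) {
  EqAge d; d.set(lambda, nu, b, A);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = d.sample();
  return out;
}

// ---------------------------------------------------------------------------
// Oxygen: quasi-steady tridiagonal solve of
//   0 = Dch2 (c_{i-1} - 2 c_i + c_{i+1}) - (k N_i + k2) c_i + S_i
// with no-flux (mirror) boundaries; Thomas algorithm.
static void ox_quasi_steady(std::vector<double>& c,
                            const std::vector<double>& N,
                            double Dch2, double k, double k2,
                            const std::vector<double>& S) {
  int n = (int)N.size();
  std::vector<double> diag(n), rhs(n), cp(n);
  for (int i = 0; i < n; ++i) {
    double nb = ((i > 0) ? 1.0 : 0.0) + ((i < n - 1) ? 1.0 : 0.0);
    diag[i] = nb * Dch2 + k * std::max(N[i], 0.0) + k2;
    rhs[i] = S[i];
  }
  // forward sweep (off-diagonals are all -Dch2)
  cp[0] = -Dch2 / diag[0];
  rhs[0] = rhs[0] / diag[0];
  for (int i = 1; i < n; ++i) {
    double m = diag[i] + Dch2 * cp[i - 1];
    cp[i] = -Dch2 / m;
    rhs[i] = (rhs[i] + Dch2 * rhs[i - 1]) / m;
  }
  c[n - 1] = rhs[n - 1];
  for (int i = n - 2; i >= 0; --i) c[i] = rhs[i] - cp[i] * c[i + 1];
}

// [[Rcpp::export(name = ".ox_quasi_steady_cpp")]]
NumericVector ox_quasi_steady_cpp(NumericVector N, double Dch2, double k,
                                  double k2, NumericVector S) {
  int n = N.size();
  std::vector<double> Nv(N.begin(), N.end()), Sv(S.begin(), S.end()), c(n);
  ox_quasi_steady(c, Nv, Dch2, k, k2, Sv);
  return wrap(c);
}

// One explicit step (Euler or RK4) of the dynamic oxygen PDE.
static void ox_rhs(const std::vector<double>& c, const std::vector<double>& N,
                   double Dch2, double k, double k2, const std::vector<double>& S,
                   std::vector<double>& out) {
  int n = (int)c.size();
  for (int i = 0; i < n; ++i) {
    double left = (i > 0) ? c[i - 1] : c[i];
    double right = (i < n - 1) ? c[i + 1] : c[i];
    out[i] = Dch2 * (left - 2.0 * c[i] + right) -
             (k * std::max(N[i], 0.0) + k2) * c[i] + S[i];
  }
}

// [[Rcpp::export(name = ".ox_step_cpp")]]
NumericVector ox_step_cpp(NumericVector c0, NumericVector N, double Dch2,
                          double k, double k2, NumericVector S, double dt,
                          int nsub, int method) {
  int n = c0.size();
  std::vector<double> c(c0.begin(), c0.end()), Nv(N.begin(), N.end()),
      Sv(S.begin(), S.end());
  std::vector<double> k1(n), k2v(n), k3(n), k4(n), tmp(n);
  double h = dt / nsub;
  for (int s = 0; s < nsub; ++s) {
    if (method == 0) { // Euler
      ox_rhs(c, Nv, Dch2, k, k2, Sv, k1);
      for (int i = 0; i < n; ++i) c[i] += h * k1[i];
    } else {           // classic RK4
      ox_rhs(c, Nv, Dch2, k, k2, Sv, k1);
      for (int i = 0; i < n; ++i) tmp[i] = c[i] + 0.5 * h * k1[i];
      ox_rhs(tmp, Nv, Dch2, k, k2, Sv, k2v);
      for (int i = 0; i < n; ++i) tmp[i] = c[i] + 0.5 * h * k2v[i];
      ox_rhs(tmp, Nv, Dch2, k, k2, Sv, k3);
      for (int i = 0; i < n; ++i) tmp[i] = c[i] + h * k3[i];
      ox_rhs(tmp, Nv, Dch2, k, k2, Sv, k4);
      for (int i = 0; i < n; ++i)
        c[i] += h / 6.0 * (k1[i] + 2.0 * k2v[i] + 2.0 * k3[i] + k4[i]);
    }
  }
  return wrap(c);
}

// ---------------------------------------------------------------------------
// Waiting-time sampler for a piecewise-constant total propensity: levels[s]
// on [breaks[s], breaks[s+1]).  Returns the event time, or Inf if the
// exponential deviate is not exhausted before the final break (the horizon).
// Factored out so the exact inversion the engines use can be tested against
// an independent thinning oracle.

// [[Rcpp::export(name = ".piecewise_event_time_cpp")]]
NumericVector piecewise_event_time_cpp(int ndraw, NumericVector breaks,
                                       NumericVector levels) {
  int ns = levels.size();
  NumericVector out(ndraw);
  for (int i = 0; i < ndraw; ++i) {
    double E = exp_rand();
    double t = breaks[0], ans = R_PosInf;
    for (int s = 0; s < ns; ++s) {
      double len = breaks[s + 1] - breaks[s];
      double a = levels[s];
      if (a * len >= E) { ans = t + E / a; break; }
      E -= a * len;
      t = breaks[s + 1];
    }
    out[i] = ans;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Age-structured compartment: cohorts (birth_time, count), sorted by birth
// time ascending (oldest first); cohorts [0, mat) are mature (age >= A).
struct Comp {
  std::vector<double> bt;
  std::vector<double> cnt;
  int mat = 0;
  double N = 0.0, M = 0.0;

  void refresh_mat(double t, double A) {
    double cut = t - A; // mature iff bt <= cut
    while (mat < (int)bt.size() && bt[mat] <= cut) { M += cnt[mat]; ++mat; }
    while (mat > 0 && bt[mat - 1] > cut) { --mat; M -= cnt[mat]; }
  }
  double next_cross(double A) const {
    if (!R_FINITE(A)) return INF;
    return (mat < (int)bt.size()) ? bt[mat] + A : INF;
  }
  // advance maturity boundary at a crossing instant t; uses the same
  // floating-point expression as next_cross so progress is guaranteed
  void apply_cross(double t, double A) {
    if (!R_FINITE(A)) return;
    while (mat < (int)bt.size() && bt[mat] + A <= t) { M += cnt[mat]; ++mat; }
  }

  void insert(double t, double A, double btime, double k) {
    int pos = (int)(std::upper_bound(bt.begin(), bt.end(), btime) - bt.begin());
    bt.insert(bt.begin() + pos, btime);
    cnt.insert(cnt.begin() + pos, k);
    N += k;
    bool mature = R_FINITE(A) && (btime <= t - A);
    if (mature) { ++mat; M += k; }
    // pos is < mat for mature, >= mat for immature, by sortedness
  }
  // remove one cell from a cohort chosen with weight cnt among [lo, hi)
  // returns its birth time
  double remove_one(int lo, int hi, double wtotal) {
    double u = unif_rand() * wtotal, acc = 0.0;
    int idx = hi - 1;
    for (int i = lo; i < hi; ++i) {
      acc += cnt[i];
      if (u <= acc) { idx = i; break; }
    }
    double btime = bt[idx];
    cnt[idx] -= 1.0;
    N -= 1.0;
    if (idx < mat) M -= 1.0;
    if (cnt[idx] <= 0.0) {
      bt.erase(bt.begin() + idx);
      cnt.erase(cnt.begin() + idx);
      if (idx < mat) --mat;
    }
    return btime;
  }
  double remove_mature() { return remove_one(0, mat, M); }
  double remove_any() { return remove_one(0, (int)bt.size(), N); }
  void clear() { bt.clear(); cnt.clear(); mat = 0; N = 0.0; M = 0.0; }
};

// ---------------------------------------------------------------------------
// Shared engine state for the full model (mode 0) and the hybrid (mode 1).
struct Engine {
  int mode, NL;
  double d, nu, b;
  double Dch2, kox, k2;
  std::vector<double> S;
  int ox_mode;      // 0 quasi-steady, 1 dynamic, 2 frozen
  double ox_dt;     // substep for dynamic oxygen
  CellCycle cc;
  double theta, sync_dt;
  bool debug_mass;

  double t = 0.0;
  std::vector<Comp> comp;
  std::vector<double> u;      // mean-field populations (cells/compartment), i < I
  double fracI = 0.0;         // fractional ledger of the interface density view
  int I = -1;                 // interface index; -1 = all-stochastic
  std::vector<double> c;      // oxygen
  std::vector<double> A;      // frozen a_G1/S per compartment
  std::vector<double> lam_c, lam_v; // lambda(c) cache for mean-field reaction
  std::vector<double> pop;    // scratch: population view for oxygen solve
  int n_reloc = 0, n_allstoch = 0;
  std::vector<double> reloc_t; std::vector<int> reloc_from, reloc_to;
  bool unstable = false;

  double popview(int i) const {
    if (mode == 1 && I >= 0 && i < I) return u[i];
    if (mode == 1 && i == I) return comp[i].N + fracI;
    return comp[i].N;
  }
  void fill_pop() {
    for (int i = 0; i < NL; ++i) pop[i] = popview(i);
  }
  void update_oxygen(double dt_elapsed) {
    if (ox_mode == 2) return;
    fill_pop();
    if (ox_mode == 0) {
      ox_quasi_steady(c, pop, Dch2, kox, k2, S);
    } else {
      int nsub = std::max(1, (int)std::ceil(dt_elapsed / ox_dt));
      std::vector<double> k1(NL);
      double h = dt_elapsed / nsub;
      for (int s = 0; s < nsub; ++s) {
        ox_rhs(c, pop, Dch2, kox, k2, S, k1);
        for (int i = 0; i < NL; ++i) c[i] += h * k1[i];
      }
    }
  }
  double lam_at(int i) {
    if (c[i] != lam_c[i]) {
      lam_c[i] = c[i];
      lam_v[i] = lambda_root(cc.age_g1s(c[i]), nu, b);
    }
    return lam_v[i];
  }
  void refresh_ages() { // recompute frozen a_G1/S and maturity boundaries
    int j0 = (mode == 1 && I >= 0) ? I : 0;
    for (int j = j0; j < NL; ++j) {
      A[j] = cc.age_g1s(c[j]);
      comp[j].refresh_mat(t, A[j]);
    }
  }

  int zcoord(int j) const {
    int z = ((j > 0) ? 1 : 0) + ((j < NL - 1) ? 1 : 0);
    if (mode == 1 && I >= 0 && j == I) z = (j < NL - 1) ? 1 : 0;
    return z;
  }
  // total stochastic propensity and per-compartment contributions
  double total_propensity() {
    double tot = 0.0;
    int j0 = (mode == 1 && I >= 0) ? I : 0;
    for (int j = j0; j < NL; ++j) {
      const Comp& q = comp[j];
      tot += b * q.M + nu * q.N + d * q.N * zcoord(j);
    }
    return tot;
  }
  double next_crossing() {
    double tc = INF;
    int j0 = (mode == 1 && I >= 0) ? I : 0;
    for (int j = j0; j < NL; ++j) {
      double x = comp[j].next_cross(A[j]);
      if (x < tc) tc = x;
    }
    return tc;
  }

  // advance the mean-field PDE over [t0, t0+dt]; hybrid only.  Oxygen and
  // lambda(c) are frozen between resynchronisations (operator splitting, as
  // in the full model); the PDE substep obeys the diffusive stability bound.
  void pde_advance(double dt) {
    if (mode != 1 || dt <= 0.0 || I <= 0) return;
    double dt_max = 0.45 / std::max(d, 1e-300);
    int nsub = std::max(1, (int)std::ceil(dt / dt_max));
    double h = dt / nsub;
    std::vector<double> du(I);
    for (int s = 0; s < nsub; ++s) {
      double uI = comp[I].N + fracI;
      for (int i = 0; i < I; ++i) {
        double left = (i > 0) ? u[i - 1] : u[i];
        double right = (i < I - 1) ? u[i + 1] : uI;
        du[i] = d * (left - 2.0 * u[i] + right) + lam_at(i) * u[i];
      }
      double fluxI = d * (u[I - 1] - uI); // gain to interface, antisymmetric
      for (int i = 0; i < I; ++i) u[i] += h * du[i];
      fracI += h * fluxI;
      for (int i = 0; i < I; ++i) {
        if (u[i] < 0.0) {
          if (u[i] > -1e-8) u[i] = 0.0; else unstable = true;
        }
      }
    }
  }

  void add_equilibrium_cells(int j, int n) {
    double Aj = A[j];
    if (!R_FINITE(Aj)) {
      // quiescent oxygen level: equilibrium distribution undefined; cells are
      // assigned age 0 (they can never mature here until oxygen recovers)
      for (int q = 0; q < n; ++q) comp[j].insert(t, Aj, t, 1.0);
      return;
    }
    EqAge dist;
    dist.set(lambda_root(Aj, nu, b), nu, b, Aj);
    for (int q = 0; q < n; ++q) {
      double age = dist.sample();
      comp[j].insert(t, Aj, t - age, 1.0);
    }
  }

  // step 6: make the interface cell count integer again
  void renormalise() {
    if (mode != 1 || I < 0) return;
    if (fracI == 0.0) return;
    double uI = comp[I].N + fracI;
    if (uI < 0.0) uI = 0.0;
    double fl = std::floor(uI);
    double fr = uI - fl;
    double n_new = fl + ((unif_rand() < fr) ? 1.0 : 0.0);
    double delta = n_new - comp[I].N;
    if (delta > 0.5) {
      add_equilibrium_cells(I, (int)std::lround(delta));
    } else if (delta < -0.5) {
      int nrem = (int)std::lround(-delta);
      for (int q = 0; q < nrem && comp[I].N > 0; ++q) comp[I].remove_any();
    }
    double mass_adj = uI - n_new; // must be absorbed by the mean-field domain
    if (I > 0) {
      double per = mass_adj / I;
      for (int i = 0; i < I; ++i) u[i] += per;
      fracI = 0.0;
    } else {
      fracI = mass_adj; // no mean-field compartment: keep in the ledger
    }
  }

  // step 7: relocate the interface
  void relocate() {
    if (mode != 1) return;
    if (I < 0) {
      // all-stochastic: try to re-establish an interface
      int best = -1;
      for (int i = 0; i < NL; ++i) if (comp[i].N > theta) best = i;
      if (best < 0) return;
      u.assign(best, 0.0);
      for (int i = 0; i < best; ++i) { u[i] = comp[i].N; comp[i].clear(); }
      log_reloc(-1, best);
      I = best; fracI = 0.0;
      return;
    }
    if (comp[I].N > theta) {
      while (I < NL - 1 && comp[I + 1].N > theta) {
        // rightward: old interface becomes mean-field, ages discarded
        u.push_back(comp[I].N + fracI);
        comp[I].clear();
        fracI = 0.0;
        log_reloc(I, I + 1);
        ++I;
      }
      return;
    }
    // leftward: condition failed at I
    while (I >= 0 && comp[I].N <= theta) {
      int newI = I - 1;
      if (newI < 0) {
        log_reloc(I, -1);
        I = -1; fracI = 0.0; ++n_allstoch;
        return;
      }
      double val = u[newI];
      u.pop_back();
      double fl = std::floor(val), fr = val - fl;
      double n_new = fl + ((unif_rand() < fr) ? 1.0 : 0.0);
      double mass_adj = val - n_new;
      if (newI > 0) {
        double per = mass_adj / newI;
        for (int i = 0; i < newI; ++i) u[i] += per;
        fracI = 0.0;
      } else {
        fracI = mass_adj;
      }
      log_reloc(I, newI);
      I = newI;
      A[I] = cc.age_g1s(c[I]);
      add_equilibrium_cells(I, (int)std::lround(n_new));
    }
  }
  void log_reloc(int from, int to) {
    ++n_reloc;
    if (reloc_t.size() < 100000) {
      reloc_t.push_back(t); reloc_from.push_back(from); reloc_to.push_back(to);
    }
  }

  double total_mass() {
    double m = 0.0;
    for (int i = 0; i < NL; ++i) m += popview(i);
    return m;
  }

  // categorical event draw + application; propensities evaluated at call time
  void fire_event() {
    int j0 = (mode == 1 && I >= 0) ? I : 0;
    double tot = total_propensity();
    double target = unif_rand() * tot, acc = 0.0;
    for (int j = j0; j < NL; ++j) {
      Comp& q = comp[j];
      double pb = b * q.M, pd = nu * q.N, pm = d * q.N * zcoord(j);
      if (target <= acc + pb + pd + pm) {
        double rloc = target - acc;
        if (rloc <= pb) {
          // birth: one mature cell is replaced by a newborn cohort of two
          q.remove_mature();
          q.insert(t, A[j], t, 2.0);
        } else if (rloc <= pb + pd) {
          q.remove_any();
        } else {
          // diffusion hop, preserving birth time
          int dest;
          bool leftok = (j > 0) && !(mode == 1 && I >= 0 && j == I);
          bool rightok = (j < NL - 1);
          if (leftok && rightok) dest = (unif_rand() < 0.5) ? j - 1 : j + 1;
          else dest = leftok ? j - 1 : j + 1;
          double btime = q.remove_any();
          comp[dest].insert(t, A[dest], btime, 1.0);
        }
        return;
      }
      acc += pb + pd + pm;
    }
    // numerically possible fall-through: ignore (treated as no-op)
  }

  // run until t_stop; fire events exactly; hybrid couples PDE + renorm + move
  void run_until(double t_stop) {
    while (t < t_stop) {
      double mass0 = debug_mass ? total_mass() : 0.0;
      double E = exp_rand();
      bool fired = false;
      while (true) {
        double tc = next_crossing();
        double seg_end = std::min(tc, t_stop);
        double tot = total_propensity();
        double seg = seg_end - t;
        if (tot > 0.0 && tot * seg >= E) {
          double t_ev = t + E / tot;
          pde_advance(t_ev - t);
          t = t_ev;
          fire_event();
          fired = true;
          break;
        }
        E -= tot * seg;
        pde_advance(seg_end - t);
        t = seg_end;
        if (seg_end == tc && tc < t_stop) {
          int j0 = (mode == 1 && I >= 0) ? I : 0;
          for (int j = j0; j < NL; ++j) comp[j].apply_cross(t, A[j]);
          continue;
        }
        break; // reached t_stop with no event
      }
      if (mode == 1) {
        double mass_pre = debug_mass ? total_mass() : 0.0;
        renormalise();
        relocate();
        if (debug_mass) {
          double mass1 = total_mass();
          // coupling ops conserve mass exactly; events change it by at most
          // 1 cell, plus the mean-field reaction's continuous contribution
          double react = 0.01 * std::max(1.0, mass0);
          if (std::fabs(mass1 - mass_pre) > 1e-6)
            stop("mass ledger violated by coupling ops at t=%f (pre=%f post=%f)",
                 t, mass_pre, mass1);
          if (std::fabs(mass_pre - mass0) > 1.0 + react)
            stop("mass ledger violated by event/PDE step at t=%f (start=%f pre=%f)",
                 t, mass0, mass_pre);
        }
      }
      if (!fired) return; // at t_stop
    }
  }
};

// [[Rcpp::export(name = ".sim_engine_cpp")]]
List sim_engine_cpp(int mode, int NL, double d, double nu, double b,
                    double Dch2, double kox, double k2, NumericVector S,
                    int ox_mode, double ox_dt,
                    int branch, double a_plus, double a_minus, double beta,
                    double c_cr, double c0,
                    double theta, double sync_dt,
                    NumericVector snap_times, NumericVector N0,
                    NumericVector c_init, int I0,
                    bool return_state, bool debug_mass) {
  RNGScope scope;
  Engine E;
  E.mode = mode; E.NL = NL; E.d = d; E.nu = nu; E.b = b;
  E.Dch2 = Dch2; E.kox = kox; E.k2 = k2;
  E.S.assign(S.begin(), S.end());
  E.ox_mode = ox_mode; E.ox_dt = ox_dt;
  E.cc.branch = branch; E.cc.a_plus = a_plus; E.cc.a_minus = a_minus;
  E.cc.beta = beta; E.cc.c_cr = c_cr; E.cc.c0 = c0;
  E.theta = theta; E.sync_dt = sync_dt; E.debug_mass = debug_mass;
  E.comp.resize(NL);
  E.c.assign(c_init.begin(), c_init.end());
  E.A.assign(NL, INF);
  E.lam_c.assign(NL, R_NegInf); E.lam_v.assign(NL, 0.0);
  E.pop.assign(NL, 0.0);
  E.I = (mode == 1) ? I0 : -1;

  for (int i = 0; i < NL; ++i) E.A[i] = E.cc.age_g1s(E.c[i]);
  // initial populations: mean-field keeps the real value, stochastic rounds
  // and draws equilibrium ages at the local oxygen level
  for (int i = 0; i < NL; ++i) {
    bool mf = (mode == 1 && E.I >= 0 && i < E.I);
    if (mf) { E.u.push_back(N0[i]); continue; }
    int n = (int)std::lround(N0[i]);
    if (n > 0) E.add_equilibrium_cells(i, n);
  }
  E.update_oxygen(0.0);
  E.refresh_ages();

  int nsnap = snap_times.size();
  NumericMatrix snapN(nsnap, NL), snapC(nsnap, NL), snapM(nsnap, NL);
  IntegerMatrix snapR(nsnap, NL);
  IntegerVector snapI(nsnap);

  double T_end = snap_times[nsnap - 1];
  int isnap = 0;
  double last_ox = 0.0;
  while (true) {
    // take due snapshots
    while (isnap < nsnap && snap_times[isnap] <= E.t + 1e-9) {
      for (int i = 0; i < NL; ++i) {
        snapN(isnap, i) = E.popview(i);
        snapC(isnap, i) = E.c[i];
        bool mf = (E.mode == 1 && E.I >= 0 && i < E.I);
        snapM(isnap, i) = mf ? NA_REAL : E.comp[i].M;
        snapR(isnap, i) = mf ? 0 : ((E.mode == 1 && i == E.I) ? 1 : 2);
      }
      snapI[isnap] = (E.mode == 1) ? E.I : NA_INTEGER;
      ++isnap;
    }
    if (isnap >= nsnap || E.t >= T_end) break;
    double t_stop = std::min(std::min(E.t + sync_dt, snap_times[isnap]), T_end);
    E.run_until(t_stop);
    // oxygen resynchronisation; a_G1/S (and, in the hybrid, lambda(c)) are
    // frozen between syncs and refreshed now
    E.update_oxygen(E.t - last_ox); last_ox = E.t;
    E.refresh_ages();
    if (E.unstable) stop("mean-field instability: negative density detected");
    Rcpp::checkUserInterrupt();
  }

  List state = R_NilValue;
  if (return_state) {
    List comps(NL);
    for (int i = 0; i < NL; ++i) {
      comps[i] = List::create(_["birth_time"] = wrap(E.comp[i].bt),
                              _["count"] = wrap(E.comp[i].cnt),
                              _["mature"] = E.comp[i].M);
    }
    state = List::create(_["compartments"] = comps, _["u"] = wrap(E.u),
                         _["frac"] = E.fracI, _["interface"] = E.I,
                         _["time"] = E.t, _["c"] = wrap(E.c));
  }
  return List::create(
      _["time"] = snap_times, _["N"] = snapN, _["c"] = snapC,
      _["mature"] = snapM, _["region"] = snapR, _["interface"] = snapI,
      _["n_relocations"] = E.n_reloc, _["n_all_stochastic"] = E.n_allstoch,
      _["reloc_time"] = wrap(E.reloc_t), _["reloc_from"] = wrap(E.reloc_from),
      _["reloc_to"] = wrap(E.reloc_to), _["state"] = state);
}

// ---------------------------------------------------------------------------
// Coarse-grained (age-free) SSA: per-compartment rates birth B(c_j) N_j,
// death nu N_j, hop d N_j per neighbour; B re-evaluated at oxygen syncs via
// the equilibrium birth rate (definitional route: division rate times the
// equilibrium mature mass fraction).
static double eq_birth_rate(double lambda, double nu, double b, double A) {
  if (!R_FINITE(A)) return 0.0;
  if (A <= 0.0) return b;
  double r1 = lambda + nu, r2 = lambda + nu + b;
  double e = std::exp(-r1 * A);
  double frac = (e / r2) / ((-std::expm1(-r1 * A)) / r1 + e / r2);
  return b * frac;
}

// [[Rcpp::export(name = ".eq_birth_rate_cpp")]]
double eq_birth_rate_cpp(double lambda, double nu, double b, double A) {
  return eq_birth_rate(lambda, nu, b, A);
}

// [[Rcpp::export(name = ".sim_cg_ssa_cpp")]]
List sim_cg_ssa_cpp(int NL, double d, double nu, double b,
                    double Dch2, double kox, double k2, NumericVector S,
                    int ox_mode, double ox_dt,
                    int branch, double a_plus, double a_minus, double beta,
                    double c_cr, double c0,
                    double sync_dt, NumericVector snap_times,
                    NumericVector N0, NumericVector c_init) {
  RNGScope scope;
  CellCycle cc{branch, a_plus, a_minus, beta, c_cr, c0};
  std::vector<double> N(NL), c(c_init.begin(), c_init.end()),
      Sv(S.begin(), S.end()), B(NL, 0.0);
  for (int i = 0; i < NL; ++i) N[i] = std::lround(N0[i]);

  auto update_ox_and_B = [&](double dt_el) {
    if (ox_mode == 0) ox_quasi_steady(c, N, Dch2, kox, k2, Sv);
    else if (ox_mode == 1) {
      int nsub = std::max(1, (int)std::ceil(dt_el / ox_dt));
      std::vector<double> k1(NL);
      double h = dt_el / nsub;
      for (int s = 0; s < nsub; ++s) {
        ox_rhs(c, N, Dch2, kox, k2, Sv, k1);
        for (int i = 0; i < NL; ++i) c[i] += h * k1[i];
      }
    }
    for (int i = 0; i < NL; ++i) {
      double A = cc.age_g1s(c[i]);
      B[i] = eq_birth_rate(lambda_root(A, nu, b), nu, b, A);
    }
  };
  update_ox_and_B(0.0);

  int nsnap = snap_times.size();
  NumericMatrix snapN(nsnap, NL), snapC(nsnap, NL);
  double T_end = snap_times[nsnap - 1];
  double t = 0.0;
  int isnap = 0;
  double last_sync = 0.0;
  while (true) {
    while (isnap < nsnap && snap_times[isnap] <= t + 1e-9) {
      for (int i = 0; i < NL; ++i) { snapN(isnap, i) = N[i]; snapC(isnap, i) = c[i]; }
      ++isnap;
    }
    if (isnap >= nsnap || t >= T_end) break;
    double t_stop = std::min(std::min(last_sync + sync_dt, snap_times[isnap]), T_end);
    // constant-propensity SSA until t_stop
    while (t < t_stop) {
      double tot = 0.0;
      for (int i = 0; i < NL; ++i) {
        int z = ((i > 0) ? 1 : 0) + ((i < NL - 1) ? 1 : 0);
        tot += (B[i] + nu + d * z) * N[i];
      }
      if (tot <= 0.0) { t = t_stop; break; }
      double wait = exp_rand() / tot;
      if (t + wait >= t_stop) { t = t_stop; break; }
      t += wait;
      double target = unif_rand() * tot, acc = 0.0;
      for (int i = 0; i < NL; ++i) {
        int z = ((i > 0) ? 1 : 0) + ((i < NL - 1) ? 1 : 0);
        double pb = B[i] * N[i], pd = nu * N[i], pm = d * z * N[i];
        if (target <= acc + pb + pd + pm) {
          double rloc = target - acc;
          if (rloc <= pb) N[i] += 1.0;
          else if (rloc <= pb + pd) N[i] -= 1.0;
          else {
            int dest;
            if (i > 0 && i < NL - 1) dest = (unif_rand() < 0.5) ? i - 1 : i + 1;
            else dest = (i > 0) ? i - 1 : i + 1;
            N[i] -= 1.0; N[dest] += 1.0;
          }
          break;
        }
        acc += pb + pd + pm;
      }
    }
    if (t >= last_sync + sync_dt - 1e-9) {
      update_ox_and_B(t - last_sync);
      last_sync = t;
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["time"] = snap_times, _["N"] = snapN, _["c"] = snapC);
}
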