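// Transient 2-D axisymmetric convection-diffusion-reaction solver for a
// laminar tube reactor.
//
// Discretisation: finite volumes in r (flux form with r-weighted metrics,
// cell-centred), first-order upwind advection plus central diffusion in z,
// and operator splitting in time: an explicit axial/reaction stage at the
// advective CFL step followed by an implicit (backward Euler) radial
// diffusion stage solved as one tridiagonal system per axial column.  The
// radial operators have constant coefficients, so their Thomas
// factorisations are computed once.
//
// Velocity is an imposed Poiseuille profile u(r) = 2*ubar*(1 - (r/R)^2);
// the momentum equation is not solved (Re is of order one and density
// variation is small).  Boundary conditions: Dirichlet inlet, zero-gradient
// outflow, symmetry at the axis, zero wall flux for species and Dirichlet
// wall (bath) temperature for the energy balance.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct Tridiag {
  // precomputed Thomas factorisation of (I - dt*A) with constant A
  std::vector<double> sub, cp, inv_denom;
  int n;
  void factor(const std::vector<double>& a, const std::vector<double>& b,
              const std::vector<double>& c) {
    n = (int)b.size();
    sub = a;
    cp.assign(n, 0.0);
    inv_denom.assign(n, 0.0);
    double denom = b[0];
    inv_denom[0] = 1.0 / denom;
    cp[0] = c[0] / denom;
    for (int j = 1; j < n; ++j) {
      denom = b[j] - a[j] * cp[j - 1];
      inv_denom[j] = 1.0 / denom;
      cp[j] = c[j] / denom;
    }
  }
  // solve in place on d
  inline void solve(double* d) const {
    double prev = d[0] * inv_denom[0];
    d[0] = prev;
    for (int j = 1; j < n; ++j) {
      prev = (d[j] - sub[j] * prev) * inv_denom[j];
      d[j] = prev;
    }
    for (int j = n - 2; j >= 0; --j) d[j] -= cp[j] * d[j + 1];
  }
};

// build (I - dt*Ar) for radial diffusion with diffusivity kappa;
// dirichlet_wall: true adds the half-cell wall-exchange term to the diagonal
static Tridiag radial_operator(int nr, double dr, double dt, double kappa,
                               const std::vector<double>& r_c,
                               const std::vector<double>& r_f,
                               bool dirichlet_wall, double* wall_coef) {
  std::vector<double> a(nr, 0.0), b(nr, 0.0), c(nr, 0.0);
  for (int j = 0; j < nr; ++j) {
    double wm = (j == 0) ? 0.0 : kappa * r_f[j] / (r_c[j] * dr * dr);
    double wp = (j == nr - 1) ? 0.0 : kappa * r_f[j + 1] / (r_c[j] * dr * dr);
    a[j] = -dt * wm;
    c[j] = -dt * wp;
    b[j] = 1.0 + dt * (wm + wp);
  }
  *wall_coef = 0.0;
  if (dirichlet_wall) {
    // exchange between the last cell centre and the wall over dr/2
    double ww = 2.0 * kappa * r_f[nr] / (r_c[nr - 1] * dr * dr);
    b[nr - 1] += dt * ww;
    *wall_coef = ww;
  }
  Tridiag t;
  t.factor(a, b, c);
  return t;
}

// [[Rcpp::export]]
List reactor_solve_cpp(double L, double radius, double ubar, int nr, int nz,
                       double D, double alpha, bool energy_on, double cA_in,
                       double cB_in, double T_in, double T_bath, double kA_si,
                       double kEa, double Rgas, double k2A, double k2Ea,
                       double dH, double rho_cp, double c_lim_in, double t_end,
                       double cfl, int n_save, NumericVector snapshot_times) {
  if (nr < 2 || nz < 2) stop("grid too small");
  if (t_end <= 0) stop("t_end must be positive");
  const double dr = radius / nr, dz = L / nz;
  std::vector<double> r_c(nr), r_f(nr + 1), u(nr), z_c(nz);
  for (int j = 0; j <= nr; ++j) r_f[j] = j * dr;
  for (int j = 0; j < nr; ++j) {
    r_c[j] = (j + 0.5) * dr;
    u[j] = 2.0 * ubar * (1.0 - (r_c[j] / radius) * (r_c[j] / radius));
  }
  for (int i = 0; i < nz; ++i) z_c[i] = (i + 0.5) * dz;

  const double umax = 2.0 * ubar;
  long nsteps = (long)std::ceil(t_end / (cfl * dz / umax));
  if (nsteps < 10) nsteps = 10;
  const double dt = t_end / nsteps;

  const bool impurity_on = (k2A > 0.0);
  const double k_const = kA_si * std::exp(-kEa / (Rgas * T_bath));
  const double k2_const = impurity_on ? k2A * std::exp(-k2Ea / (Rgas * T_bath)) : 0.0;

  // mixing-cup weights (flow-weighted radial average)
  std::vector<double> q(nr);
  double qsum = 0.0;
  for (int j = 0; j < nr; ++j) {
    q[j] = u[j] * r_c[j];
    qsum += q[j];
  }
  for (int j = 0; j < nr; ++j) q[j] /= qsum;

  const int N = nr * nz;
  std::vector<double> cA(N), cB(N, 0.0), cP(N, 0.0), cI(N, 0.0), T(N, T_bath);
  std::vector<double> nA(N), nB(N), nP(N), nI(N), nT(N);
  // initial fill: reactant A decaying linearly from the inlet value to zero
  // at the outlet, everything else empty, temperature at the bath value
  for (int i = 0; i < nz; ++i)
    for (int j = 0; j < nr; ++j) cA[j + nr * i] = cA_in * (1.0 - z_c[i] / L);

  double wall_dummy, wall_T;
  Tridiag triC = radial_operator(nr, dr, dt, D, r_c, r_f, false, &wall_dummy);
  Tridiag triT = radial_operator(nr, dr, dt, alpha, r_c, r_f, true, &wall_T);

  // saving layout
  int save_every = (int)std::max(1L, nsteps / std::max(1, n_save));
  int n_saved_max = (int)(nsteps / save_every) + 2;
  NumericVector save_t(n_saved_max), save_yield(n_saved_max),
      save_impurity(n_saved_max);
  NumericMatrix yield_profiles(n_saved_max, nz);
  int n_saved = 0;

  std::vector<double> snaps(snapshot_times.begin(), snapshot_times.end());
  std::sort(snaps.begin(), snaps.end());
  List snapshots;
  std::size_t isnap = 0;

  auto mixcup = [&](const std::vector<double>& f, int i) {
    double s = 0.0;
    for (int j = 0; j < nr; ++j) s += q[j] * f[j + nr * i];
    return s;
  };
  auto record = [&](double t) {
    save_t[n_saved] = t;
    save_yield[n_saved] = 100.0 * mixcup(cP, nz - 1) / c_lim_in;
    save_impurity[n_saved] = 100.0 * mixcup(cI, nz - 1) / c_lim_in;
    for (int i = 0; i < nz; ++i)
      yield_profiles(n_saved, i) = 100.0 * mixcup(cP, i) / c_lim_in;
    ++n_saved;
  };
  auto take_snapshot = [&](double t) {
    NumericMatrix mA(nr, nz), mB(nr, nz), mP(nr, nz), mI(nr, nz), mT(nr, nz);
    for (int i = 0; i < nz; ++i)
      for (int j = 0; j < nr; ++j) {
        mA(j, i) = cA[j + nr * i];
        mB(j, i) = cB[j + nr * i];
        mP(j, i) = cP[j + nr * i];
        mI(j, i) = cI[j + nr * i];
        mT(j, i) = T[j + nr * i];
      }
    snapshots.push_back(List::create(
        _["time"] = t, _["conc_a"] = mA, _["conc_b"] = mB, _["conc_p"] = mP,
        _["conc_i"] = mI, _["temperature"] = mT));
  };

  record(0.0);
  while (isnap < snaps.size() && snaps[isnap] <= 1e-12) {
    take_snapshot(0.0);
    ++isnap;
  }

  const double ax_D = D / (dz * dz), ax_a = alpha / (dz * dz);
  double t = 0.0;
  for (long step = 1; step <= nsteps; ++step) {
    // explicit stage: advection + axial diffusion + reaction sources
    for (int i = 0; i < nz; ++i) {
      const int up = (i == 0) ? -1 : i - 1;       // -1 marks the inlet ghost
      const int dn = (i == nz - 1) ? i : i + 1;   // zero-gradient outflow
      for (int j = 0; j < nr; ++j) {
        const int id = j + nr * i;
        const double a = cA[id], b = cB[id], p = cP[id], ii = cI[id];
        const double Tl = energy_on ? T[id] : T_bath;
        double k1 = energy_on ? kA_si * std::exp(-kEa / (Rgas * Tl)) : k_const;
        double rate = k1 * a * b;
        const double rcap = 0.99 * std::min(a, b) / dt;
        if (rate > rcap) rate = rcap;
        if (rate < 0.0) rate = 0.0;
        double rate2 = 0.0;
        if (impurity_on) {
          double k2 = energy_on ? k2A * std::exp(-k2Ea / (Rgas * Tl)) : k2_const;
          rate2 = k2 * p;
          const double r2cap = 0.99 * p / dt;
          if (rate2 > r2cap) rate2 = r2cap;
          if (rate2 < 0.0) rate2 = 0.0;
        }
        const double aup = (up < 0) ? cA_in : cA[j + nr * up];
        const double bup = (up < 0) ? cB_in : cB[j + nr * up];
        const double pup = (up < 0) ? 0.0 : cP[j + nr * up];
        const double iup = (up < 0) ? 0.0 : cI[j + nr * up];
        const double adn = cA[j + nr * dn], bdn = cB[j + nr * dn],
                     pdn = cP[j + nr * dn], idn = cI[j + nr * dn];
        const double conv = u[j] / dz;
        nA[id] = a + dt * (conv * (aup - a) + ax_D * (adn - 2 * a + aup) - rate);
        nB[id] = b + dt * (conv * (bup - b) + ax_D * (bdn - 2 * b + bup) - rate);
        nP[id] = p + dt * (conv * (pup - p) + ax_D * (pdn - 2 * p + pup) + rate - rate2);
        if (impurity_on)
          nI[id] = ii + dt * (conv * (iup - ii) + ax_D * (idn - 2 * ii + iup) + rate2);
        if (energy_on) {
          const double Tup = (up < 0) ? T_in : T[j + nr * up];
          const double Tdn = T[j + nr * dn];
          nT[id] = Tl + dt * (conv * (Tup - Tl) + ax_a * (Tdn - 2 * Tl + Tup) +
                              (-dH) * rate / rho_cp);
        }
        if (nA[id] < 0.0) nA[id] = 0.0;
        if (nB[id] < 0.0) nB[id] = 0.0;
        if (nP[id] < 0.0) nP[id] = 0.0;
        if (impurity_on && nI[id] < 0.0) nI[id] = 0.0;
      }
    }
    // implicit radial diffusion stage, one tridiagonal solve per column
    for (int i = 0; i < nz; ++i) {
      double* colA = &nA[nr * i];
      double* colB = &nB[nr * i];
      double* colP = &nP[nr * i];
      triC.solve(colA);
      triC.solve(colB);
      triC.solve(colP);
      if (impurity_on) triC.solve(&nI[nr * i]);
      if (energy_on) {
        double* colT = &nT[nr * i];
        colT[nr - 1] += dt * wall_T * T_bath;
        triT.solve(colT);
      }
    }
    cA.swap(nA);
    cB.swap(nB);
    cP.swap(nP);
    if (impurity_on) cI.swap(nI);
    if (energy_on) T.swap(nT);
    t = step * dt;

    if (step % save_every == 0 || step == nsteps) record(t);
    while (isnap < snaps.size() && t >= snaps[isnap] - 1e-9) {
      take_snapshot(t);
      ++isnap;
    }
    if (std::isnan(cA[nr * (nz - 1)]) || std::isnan(cP[nr * (nz - 1)]))
      stop("solver diverged (NaN in the field) at t = %g s, dt = %g s", t, dt);
  }

  // outlet mixing-cup state and mass balance terms at the final time
  double outA = mixcup(cA, nz - 1), outB = mixcup(cB, nz - 1),
         outP = mixcup(cP, nz - 1), outI = mixcup(cI, nz - 1),
         outT = energy_on ? mixcup(T, nz - 1) : T_bath;

  return List::create(
      _["times"] = save_t[Range(0, n_saved - 1)],
      _["yield_out"] = save_yield[Range(0, n_saved - 1)],
      _["impurity_out"] = save_impurity[Range(0, n_saved - 1)],
      _["yield_profiles"] = yield_profiles(Range(0, n_saved - 1), _),
      _["z"] = NumericVector(z_c.begin(), z_c.end()),
      _["r"] = NumericVector(r_c.begin(), r_c.end()),
      _["axial_velocity"] = NumericVector(u.begin(), u.end()),
      _["snapshots"] = snapshots,
      _["outlet"] = List::create(_["conc_a"] = outA, _["conc_b"] = outB,
                                 _["conc_p"] = outP, _["conc_i"] = outI,
                                 _["temperature"] = outT),
      _["n_steps"] = (double)nsteps, _["dt"] = dt);
}
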