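// Finite-difference right-hand side and RK4 time stepper for the
// three-species reaction-advection-diffusion system on a periodic grid.
//
// Discretization: 2nd-order central differences for diffusion and advection;
// the interaction term d/dx[(d/dx U) rho] in conservative flux form with
// face-centered fluxes F_{i+1/2} = (U_{i+1}-U_i)/dx * (rho_i+rho_{i+1})/2,
// so that transport moves mass without creating it.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct Pars {
  double ls, ld, le, mu;     // kinetic rates
  double vp, vm, D;          // transport
  double kap, kap0;          // interactions
  bool logistic;
  double ccp, cc0, ccm;      // carrying capacities (Inf in linear mode)
  int nx;
  double dx;
};

static inline double growth(double rho, double cc) {
  return std::isfinite(cc) ? rho * (1.0 - rho / cc) : rho;
}

static void rhs(const std::vector<double>& y, std::vector<double>& dy,
                const Pars& p) {
  const int nx = p.nx;
  const double* rp = &y[0];
  const double* r0 = &y[nx];
  const double* rm = &y[2 * nx];
  double* dp = &dy[0];
  double* d0 = &dy[nx];
  double* dm = &dy[2 * nx];
  const double idx = 1.0 / p.dx, idx2 = idx * idx;

  for (int i = 0; i < nx; ++i) {
    const int ip = (i + 1 == nx) ? 0 : i + 1;
    const int im = (i == 0) ? nx - 1 : i - 1;

    // kinetics (linear or saturating growth through the off-diagonal part)
    const double gp = p.logistic ? growth(rp[i], p.ccp) : rp[i];
    const double g0 = p.logistic ? growth(r0[i], p.cc0) : r0[i];
    const double gm = p.logistic ? growth(rm[i], p.ccm) : rm[i];
    double tp = -(p.ls + p.le + p.mu) * rp[i] + p.ld * g0 + p.le * gm;
    double t0 = -p.ld * r0[i] + p.ls * (gp + gm);
    double tm = -(p.ls + p.le + p.mu) * rm[i] + p.ld * g0 + p.le * gp;

    // diffusion + self-advection of the movers
    tp += p.D * (rp[ip] - 2.0 * rp[i] + rp[im]) * idx2
        - p.vp * 0.5 * (rp[ip] - rp[im]) * idx;
    tm += p.D * (rm[ip] - 2.0 * rm[i] + rm[im]) * idx2
        + p.vm * 0.5 * (rm[ip] - rm[im]) * idx;

    // interaction fluxes: U_+/- = -kappa rho_0 (attraction of movers to
    // settled regions), U_0 = +kappa_0 rho_0 (settled self-repulsion)
    if (p.kap != 0.0) {
      const double dUr = -p.kap * (r0[ip] - r0[i]) * idx;   // face i+1/2
      const double dUl = -p.kap * (r0[i] - r0[im]) * idx;   // face i-1/2
      tp += (dUr * 0.5 * (rp[i] + rp[ip]) - dUl * 0.5 * (rp[im] + rp[i])) * idx;
      tm += (dUr * 0.5 * (rm[i] + rm[ip]) - dUl * 0.5 * (rm[im] + rm[i])) * idx;
    }
    if (p.kap0 != 0.0) {
      const double dUr = p.kap0 * (r0[ip] - r0[i]) * idx;
      const double dUl = p.kap0 * (r0[i] - r0[im]) * idx;
      t0 += (dUr * 0.5 * (r0[i] + r0[ip]) - dUl * 0.5 * (r0[im] + r0[i])) * idx;
    }

    dp[i] = tp; d0[i] = t0; dm[i] = tm;
  }
}

static Pars make_pars(NumericVector par, int nx, double dx) {
  Pars p;
  p.ls = par["lambda_s"]; p.ld = par["lambda_d"];
  p.le = par["lambda_e"]; p.mu = par["mu"];
  p.vp = par["v_plus"]; p.vm = par["v_minus"]; p.D = par["D"];
  p.kap = par["kappa"]; p.kap0 = par["kappa_0"];
  p.logistic = par["logistic"] != 0.0;
  p.ccp = par["rho_plus_c"]; p.cc0 = par["rho_0_c"]; p.ccm = par["rho_minus_c"];
  p.nx = nx; p.dx = dx;
  return p;
}

// [[Rcpp::export(name = ".pde_rhs_cpp")]]
NumericMatrix pde_rhs_cpp(NumericMatrix state, NumericVector par, double dx) {
  const int nx = state.ncol();
  Pars p = make_pars(par, nx, dx);
  std::vector<double> y(3 * nx), dy(3 * nx);
  for (int i = 0; i < nx; ++i) {
    y[i] = state(0, i); y[nx + i] = state(1, i); y[2 * nx + i] = state(2, i);
  }
  rhs(y, dy, p);
  NumericMatrix out(3, nx);
  for (int i = 0; i < nx; ++i) {
    out(0, i) = dy[i]; out(1, i) = dy[nx + i]; out(2, i) = dy[2 * nx + i];
  }
  return out;
}

// Classical RK4 integration with snapshot collection.
//
// check_every / exit_tol: every `check_every` steps the state is compared
// with the state at the previous check; if the maximum pointwise change is
// below `exit_tol` the run stops early (converged pattern).  Traveling
// waves keep changing pointwise and are not cut short.
//
// neg_tol: small negative values (central-difference undershoots) are
// clipped to zero; anything below -neg_tol aborts the run as a dt/dx
// misconfiguration.  NaN/Inf aborts with the last good snapshot kept.
// [[Rcpp::export(name = ".pde_integrate_cpp")]]
List pde_integrate_cpp(NumericMatrix init, NumericVector par, double dx,
                       double dt, int n_steps, int stride,
                       int check_every, double exit_tol, double neg_tol) {
  const int nx = init.ncol();
  Pars p = make_pars(par, nx, dx);
  std::vector<double> y(3 * nx), k1(3 * nx), k2(3 * nx), k3(3 * nx),
      k4(3 * nx), tmp(3 * nx), prev;
  for (int i = 0; i < nx; ++i) {
    y[i] = init(0, i); y[nx + i] = init(1, i); y[2 * nx + i] = init(2, i);
  }

  std::vector<std::vector<double>> snaps;
  std::vector<double> snap_times;
  snaps.push_back(y); snap_times.push_back(0.0);

  std::string status = "completed";
  int steps_done = 0;

  for (int step = 1; step <= n_steps; ++step) {
    rhs(y, k1, p);
    for (int j = 0; j < 3 * nx; ++j) tmp[j] = y[j] + 0.5 * dt * k1[j];
    rhs(tmp, k2, p);
    for (int j = 0; j < 3 * nx; ++j) tmp[j] = y[j] + 0.5 * dt * k2[j];
    rhs(tmp, k3, p);
    for (int j = 0; j < 3 * nx; ++j) tmp[j] = y[j] + dt * k3[j];
    rhs(tmp, k4, p);

    bool bad = false;
    double ymin = 0.0;
    for (int j = 0; j < 3 * nx; ++j) {
      double v = y[j] + dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
      if (!std::isfinite(v)) { bad = true; break; }
      if (v < ymin) ymin = v;
      tmp[j] = v;
    }
    if (bad) { status = "diverged"; break; }
    if (ymin < -neg_tol) { status = "negative_density"; break; }
    for (int j = 0; j < 3 * nx; ++j) y[j] = tmp[j] < 0.0 ? 0.0 : tmp[j];
    steps_done = step;

    if (stride > 0 && step % stride == 0) {
      snaps.push_back(y); snap_times.push_back(step * dt);
    }
    if (check_every > 0 && step % check_every == 0) {
      if (!prev.empty()) {
        double dmax = 0.0;
        for (int j = 0; j < 3 * nx; ++j)
          dmax = std::max(dmax, std::fabs(y[j] - prev[j]));
        if (dmax < exit_tol) { status = "converged_early"; break; }
      }
      prev = y;
    }
  }

  if (snap_times.back() != steps_done * dt && status != "diverged" &&
      status != "negative_density") {
    snaps.push_back(y); snap_times.push_back(steps_done * dt);
  }

  const int ns = (int)snaps.size();
  NumericMatrix rp(nx, ns), r0(nx, ns), rm(nx, ns);
  NumericVector times(ns), Ntot(ns);
  for (int s = 0; s < ns; ++s) {
    times[s] = snap_times[s];
    double N = 0.0;
    for (int i = 0; i < nx; ++i) {
      rp(i, s) = snaps[s][i];
      r0(i, s) = snaps[s][nx + i];
      rm(i, s) = snaps[s][2 * nx + i];
      N += (rp(i, s) + r0(i, s) + rm(i, s)) * dx;
    }
    Ntot[s] = N;
  }
  return List::create(_["times"] = times, _["rho_plus"] = rp,
                      _["rho_0"] = r0, _["rho_minus"] = rm,
                      _["N"] = Ntot, _["status"] = status,
                      _["steps_done"] = steps_done);
}
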