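#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// sgn with sgn(0) = 0, the convention used throughout the drift terms
static inline double sgn(double x) { return (x > 0) - (x < 0); }

// Euler-Maruyama integration of the two-regime Langevin process.
//
// Gas-like paths follow dX = -mu(t) sgn(X) dt + sqrt(2 DeffG) dW, with the
// drift magnitude mu(t) = DeffG / lambda(t) chosen so the instantaneous
// stationary scale is lambda(t).  In adiabatic mode lambda(t) =
// sqrt(DeffG * t), floored at lambda(dt) to avoid the t -> 0 singularity,
// and at tc the path switches to pure diffusion with DeffL.  In fixed mode
// lambda is constant (lambda_fixed) and no switch happens.  Liquid paths
// are pure diffusion with DeffL throughout.
//
// regime: integer per path, 0 = gas, 1 = liquid.
// record_stride: every record_stride-th step is stored (plus t = 0).
// Returns an n_paths x (n_records) matrix of positions; all paths start
// at 0.  Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
NumericMatrix em_simulate_cpp(IntegerVector regime, double dt, int n_steps,
                              int record_stride, double DeffG, double DeffL,
                              double tc, bool adiabatic,
                              double lambda_fixed) {
  const int n_paths = regime.size();
  const int n_rec = n_steps / record_stride + 1;
  NumericMatrix out(n_paths, n_rec);
  std::vector<double> x(n_paths, 0.0);

  const double sdG = std::sqrt(2.0 * DeffG * dt);
  const double sdL = std::sqrt(2.0 * DeffL * dt);
  const double lambda_floor = std::sqrt(DeffG * dt);

  int rec = 1;
  for (int k = 0; k < n_steps; ++k) {
    const double t = k * dt;  // drift evaluated at the pre-step time
    double mu_dt = 0.0, sd_gas = sdG;
    bool gas_diffusive = false;
    if (adiabatic) {
      if (t > tc) {
        gas_diffusive = true;  // gas-like phase ended: DeffL diffusion
      } else {
        double lambda = std::sqrt(DeffG * std::max(t, dt));
        if (lambda < lambda_floor) lambda = lambda_floor;
        mu_dt = (DeffG / lambda) * dt;
      }
    } else {
      mu_dt = (DeffG / lambda_fixed) * dt;
    }
    for (int i = 0; i < n_paths; ++i) {
      if (regime[i] == 0) {
        if (gas_diffusive)
          x[i] += sdL * norm_rand();
        else
          x[i] += -mu_dt * sgn(x[i]) + sd_gas * norm_rand();
      } else {
        x[i] += sdL * norm_rand();
      }
    }
    if ((k + 1) % record_stride == 0) {
      for (int i = 0; i < n_paths; ++i) out(i, rec) = x[i];
      ++rec;
    }
  }
  return out;
}

// Thomas algorithm: solve a constant-coefficient symmetric tridiagonal
// system (diag d, off-diagonal o) in place.  n >= 2 assumed.
static void thomas_solve(int n, double d, double o,
                         std::vector<double>& rhs,
                         std::vector<double>& cp) {
  cp[0] = o / d;
  rhs[0] = rhs[0] / d;
  for (int i = 1; i < n; ++i) {
    const double m = 1.0 / (d - o * cp[i - 1]);
    cp[i] = o * m;
    rhs[i] = (rhs[i] - o * rhs[i - 1]) * m;
  }
  for (int i = n - 2; i >= 0; --i) rhs[i] -= cp[i] * rhs[i + 1];
}

// Crank-Nicolson time stepping for u_t = D u_xx on a uniform grid with
// homogeneous Dirichlet boundaries, with n_startup initial backward-Euler
// steps (Rannacher smoothing: damps the spurious oscillations CN produces
// from non-smooth initial data such as the Laplace kink).
// [[Rcpp::export]]
NumericVector cn_diffuse_cpp(NumericVector u0, double dx, double D,
                             int n_steps, double dt, int n_startup) {
  const int n = u0.size();
  std::vector<double> u(u0.begin(), u0.end());
  std::vector<double> rhs(n), cp(n);
  const double r = D * dt / (dx * dx);

  // interior unknowns u[1..n-2]; boundaries pinned at 0
  const int m = n - 2;
  u[0] = 0.0; u[n - 1] = 0.0;

  for (int k = 0; k < n_steps; ++k) {
    const bool be = k < n_startup;
    // backward Euler: (1 + 2r) u_i - r (u_{i-1} + u_{i+1}) = u_i^old
    // Crank-Nicolson: (1 + r) u_i - r/2 (...) = u_i^old + r/2 (lap)
    const double d = be ? (1.0 + 2.0 * r) : (1.0 + r);
    const double o = be ? (-r) : (-r / 2.0);
    for (int i = 1; i <= m; ++i) {
      if (be) {
        rhs[i - 1] = u[i];
      } else {
        rhs[i - 1] = u[i] + 0.5 * r * (u[i - 1] - 2.0 * u[i] + u[i + 1]);
      }
    }
    std::vector<double> sol(rhs.begin(), rhs.begin() + m);
    thomas_solve(m, d, o, sol, cp);
    for (int i = 1; i <= m; ++i) u[i] = sol[i - 1];
  }
  return NumericVector(u.begin(), u.end());
}
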