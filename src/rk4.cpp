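#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Replicator vector field in factored form:
//   F = x(1-x)(-A1 + y B1),  G = y(1-y)(-A2 + x B2)
static inline void field(double A1, double B1, double A2, double B2,
                         double x, double y, double &F, double &G) {
  F = x * (1.0 - x) * (-A1 + y * B1);
  G = y * (1.0 - y) * (-A2 + x * B2);
}

// Nearest corner of the unit square within conv_tol (euclidean), or 0.
// Corner ids: 1 E(0,0), 2 S(0,1), 3 N(1,0), 4 K(1,1).
static inline int near_corner(double x, double y, double conv_tol) {
  const double t2 = conv_tol * conv_tol;
  if (x * x + y * y <= t2) return 1;
  if (x * x + (1 - y) * (1 - y) <= t2) return 2;
  if ((1 - x) * (1 - x) + y * y <= t2) return 3;
  if ((1 - x) * (1 - x) + (1 - y) * (1 - y) <= t2) return 4;
  return 0;
}

// Fixed-step classical RK4 on the replicator system, with per-step
// clamping to [0,1]^2 (magnitude tracked; exceeding clamp_tol aborts),
// corner-convergence and interior-stall detection.
// status: 0 converged, 1 stalled, 2 max-steps, 3 clamp error, 4 non-finite
// [[Rcpp::export]]
List rk4_replicator(double A1, double B1, double A2, double B2,
                    double x0, double y0, double dt, int max_steps,
                    double conv_tol, double stall_tol,
                    int record_every, double clamp_tol = 1e-9) {
  std::vector<double> ts, xs, ys;
  const bool record = record_every > 0;
  if (record) {
    const size_t cap = (size_t)(max_steps / record_every) + 3;
    ts.reserve(cap); xs.reserve(cap); ys.reserve(cap);
  }
  double x = x0, y = y0, max_clamp = 0.0;
  int status = 2, corner = 0, step = 0;
  double F, G;

  if (record) { ts.push_back(0.0); xs.push_back(x); ys.push_back(y); }

  // initial state may already satisfy a terminal condition
  corner = near_corner(x, y, conv_tol);
  if (corner) status = 0;
  else {
    field(A1, B1, A2, B2, x, y, F, G);
    if (std::sqrt(F * F + G * G) < stall_tol) status = 1;
  }

  while (status == 2 && step < max_steps) {
    double k1x, k1y, k2x, k2y, k3x, k3y, k4x, k4y;
    field(A1, B1, A2, B2, x, y, k1x, k1y);
    field(A1, B1, A2, B2, x + 0.5 * dt * k1x, y + 0.5 * dt * k1y, k2x, k2y);
    field(A1, B1, A2, B2, x + 0.5 * dt * k2x, y + 0.5 * dt * k2y, k3x, k3y);
    field(A1, B1, A2, B2, x + dt * k3x, y + dt * k3y, k4x, k4y);
    x += dt / 6.0 * (k1x + 2.0 * k2x + 2.0 * k3x + k4x);
    y += dt / 6.0 * (k1y + 2.0 * k2y + 2.0 * k3y + k4y);
    ++step;

    if (!std::isfinite(x) || !std::isfinite(y)) { status = 4; break; }

    double ex = std::max(std::max(-x, x - 1.0), 0.0);
    double ey = std::max(std::max(-y, y - 1.0), 0.0);
    double clamp = std::max(ex, ey);
    if (clamp > max_clamp) max_clamp = clamp;
    if (clamp > clamp_tol) { status = 3; break; }
    if (x < 0.0) x = 0.0; else if (x > 1.0) x = 1.0;
    if (y < 0.0) y = 0.0; else if (y > 1.0) y = 1.0;

    if (record && (step % record_every == 0)) {
      ts.push_back(step * dt); xs.push_back(x); ys.push_back(y);
    }

    corner = near_corner(x, y, conv_tol);
    if (corner) { status = 0; break; }
    field(A1, B1, A2, B2, x, y, F, G);
    if (std::sqrt(F * F + G * G) < stall_tol) { status = 1; break; }
  }

  if (record && (ts.empty() || ts.back() != step * dt)) {
    ts.push_back(step * dt); xs.push_back(x); ys.push_back(y);
  }

  return List::create(
    _["times"] = wrap(ts), _["x"] = wrap(xs), _["y"] = wrap(ys),
    _["final"] = NumericVector::create(x, y),
    _["status"] = status, _["corner"] = corner,
    _["steps"] = step, _["max_clamp"] = max_clamp);
}

// Batch version for basin maps: integrate from each initial condition,
// return terminal corner id (0 if unresolved) and step count.
// [[Rcpp::export]]
List rk4_basin(double A1, double B1, double A2, double B2,
               NumericVector x0, NumericVector y0, double dt,
               int max_steps, double conv_tol, double stall_tol,
               double clamp_tol = 1e-9) {
  const int n = x0.size();
  IntegerVector corner(n), status(n), steps(n);
  for (int i = 0; i < n; ++i) {
    List r = rk4_replicator(A1, B1, A2, B2, x0[i], y0[i], dt, max_steps,
                            conv_tol, stall_tol, 0, clamp_tol);
    status[i] = as<int>(r["status"]);
    corner[i] = as<int>(r["corner"]);
    steps[i] = as<int>(r["steps"]);
  }
  return List::create(_["corner"] = corner, _["status"] = status,
                      _["steps"] = steps);
}
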