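#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Exact Voronoi-adjacency test for candidate site pairs.
//
// Sites i and j share a Voronoi edge iff some point x on their perpendicular
// bisector is at least as close to i (and j) as to every other site, over a
// segment of positive length. Writing x(t) = m + t*n with m the midpoint and
// n the unit bisector direction, |x - p_i|^2 <= |x - q|^2 reduces to a linear
// inequality a_q * t <= b_q for each other site q (the quadratic terms in t
// cancel), so adjacency is a 1-D feasibility problem solved in O(n) per pair.
// [[Rcpp::export(rng = false)]]
LogicalVector voronoi_pairs_cpp(NumericMatrix pts, IntegerMatrix cand) {
  const int n = pts.nrow(), m = cand.nrow();
  LogicalVector keep(m);
  for (int e = 0; e < m; ++e) {
    const int i = cand(e, 0), j = cand(e, 1);
    const double ix = pts(i, 0), iy = pts(i, 1);
    const double jx = pts(j, 0), jy = pts(j, 1);
    const double dx = jx - ix, dy = jy - iy;
    const double len = std::sqrt(dx * dx + dy * dy);
    if (len == 0.0) { keep[e] = false; continue; }
    const double mx = 0.5 * (ix + jx), my = 0.5 * (iy + jy);
    const double nx = -dy / len, ny = dx / len;
    const double tiny = 1e-12 * len;
    double tlo = -std::numeric_limits<double>::infinity();
    double thi = std::numeric_limits<double>::infinity();
    bool feasible = true;
    for (int q = 0; q < n; ++q) {
      if (q == i || q == j) continue;
      const double qx = pts(q, 0), qy = pts(q, 1);
      // |x - p_i|^2 <= |x - q|^2  with  x = m + t*n
      const double a = 2.0 * (nx * (qx - ix) + ny * (qy - iy));
      const double b = qx * qx + qy * qy - ix * ix - iy * iy
        - 2.0 * (mx * (qx - ix) + my * (qy - iy));
      if (a > tiny) {
        const double t = b / a;
        if (t < thi) thi = t;
      } else if (a < -tiny) {
        const double t = b / a;
        if (t > tlo) tlo = t;
      } else if (b < -tiny * len) {
        feasible = false;
      }
      if (thi - tlo <= 1e-9 * len) { feasible = false; }
      if (!feasible) break;
    }
    keep[e] = feasible;
  }
  return keep;
}

static inline double wrap_pi(double a) {
  // wrap to (-pi, pi]; mirrors the R helper (floor-based %% semantics)
  const double two_pi = 2.0 * M_PI;
  double w = (a + M_PI) - two_pi * std::floor((a + M_PI) / two_pi);
  if (w <= 0.0) w += two_pi;
  return w - M_PI;
}

// Euler-Maruyama integration of the overdamped elastic SPP sheet:
//   dr_i/dt   = v0 * (cos phi_i, sin phi_i) + mu * sum_j F_ij
//   dphi_i/dt = (1/tau) * sin(theta_i - phi_i) + sqrt(2 D) xi_i(t)
// with F_ij = k (|r_j - r_i| - r0) * (r_j - r_i)/|r_j - r_i| and theta_i the
// polar angle of the net force; the relaxation term is zero when the net
// force vanishes. Noise draws come from R's RNG, one N-vector per step in
// particle-index order, so an R-level loop over step() with the same seed
// reproduces this path.
// [[Rcpp::export]]
List sim_run_cpp(NumericMatrix pos0, NumericVector phi0, IntegerMatrix edges,
                 double k, double r0, double v0, double mu, double tau,
                 double D, double dt, int n_steps, int burn_in,
                 int sample_every) {
  const int n = pos0.nrow(), ne = edges.nrow();
  std::vector<double> x(n), y(n), phi(n), fx(n), fy(n);
  for (int i = 0; i < n; ++i) {
    x[i] = pos0(i, 0);
    y[i] = pos0(i, 1);
    phi[i] = phi0[i];
  }
  const double amp = std::sqrt(2.0 * D * dt);
  const int n_frames = (n_steps > burn_in) ? (n_steps - burn_in) / sample_every : 0;
  List frames_pos(n_frames), frames_phi(n_frames);
  NumericVector times(n_frames);
  int frame = 0;
  bool ok = true;
  int bad_step = -1;

  for (int s = 1; s <= n_steps && ok; ++s) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    for (int e = 0; e < ne; ++e) {
      const int i = edges(e, 0), j = edges(e, 1);
      const double dx = x[j] - x[i], dy = y[j] - y[i];
      const double d = std::sqrt(dx * dx + dy * dy);
      const double f = k * (d - r0) / d;
      fx[i] += f * dx; fy[i] += f * dy;
      fx[j] -= f * dx; fy[j] -= f * dy;
    }
    for (int i = 0; i < n; ++i) {
      const double c = std::cos(phi[i]), sn = std::sin(phi[i]);
      x[i] += dt * (v0 * c + mu * fx[i]);
      y[i] += dt * (v0 * sn + mu * fy[i]);
      double relax = 0.0;
      // |f| <= 1e-10 treated as zero: atan2 of a roundoff-level force is
      // ill-conditioned and the relaxation term vanishes with the force
      if (fx[i] * fx[i] + fy[i] * fy[i] > 1e-20) {
        relax = std::sin(std::atan2(fy[i], fx[i]) - phi[i]) / tau;
      }
      phi[i] = wrap_pi(phi[i] + dt * relax + amp * norm_rand());
      if (!std::isfinite(x[i]) || !std::isfinite(y[i])) {
        ok = false;
        bad_step = s;
      }
    }
    if (ok && s > burn_in && (s - burn_in) % sample_every == 0) {
      NumericMatrix p(n, 2);
      NumericVector ph(n);
      for (int i = 0; i < n; ++i) {
        p(i, 0) = x[i];
        p(i, 1) = y[i];
        ph[i] = phi[i];
      }
      frames_pos[frame] = p;
      frames_phi[frame] = ph;
      times[frame] = s * dt;
      ++frame;
    }
  }
  return List::create(_["positions"] = frames_pos, _["headings"] = frames_phi,
                      _["times"] = times, _["ok"] = ok,
                      _["bad_step"] = bad_step);
}
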