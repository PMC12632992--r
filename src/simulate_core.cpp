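#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Explicit first-order integration of the stoichiometric cortical pulling
// model: two asters in a sphere, a coarse-grained motor-binding probability
// field on the surface mesh, and poles coupled to chromosome plates by a
// viscous element along the spindle axis. Chromosome separation follows the
// imposed exponential law Dc(t) = c_f (1 - exp(-t/tau_c)) with the plates
// riding the instantaneous pole midpoint, so only the poles carry state.
//
// Per step (order matters; the pure-R engine mirrors it exactly):
//   1. impingement rates Omega_i at every patch from the current poles
//   2. explicit field update with the shared stoichiometric free fraction
//   3. cortical forces from the updated field
//   4. pole update by axis decomposition (parallel: (F_par + nu*cdot)/(eta+nu),
//      perpendicular: F_perp/eta)
// [[Rcpp::export]]
List cpp_simulate_spindle(NumericMatrix patches, double patch_area, double radius,
                          NumericVector x1_init, NumericVector x2_init,
                          double n_mt, double v_g, double lambda, double r_motor,
                          double force_prefactor, double kappa,
                          double eta, double nu,
                          double c_f, double tau_c,
                          double dt, double t_end, double sample_every) {
  const int n = patches.nrow();
  const int n_steps = (int)std::llround(t_end / dt);

  std::vector<double> P1(n, 0.0), P2(n, 0.0);
  std::vector<double> u1x(n), u1y(n), u1z(n), u2x(n), u2y(n), u2z(n);
  std::vector<double> O1(n), O2(n);

  double x1[3] = {x1_init[0], x1_init[1], x1_init[2]};
  double x2[3] = {x2_init[0], x2_init[1], x2_init[2]};

  // sample bookkeeping
  const int n_samp = (int)std::floor(t_end / sample_every + 1e-9) + 1;
  NumericVector s_t(n_samp), s_dpp(n_samp), s_dcc(n_samp);
  NumericMatrix s_x1(n_samp, 3), s_x2(n_samp, 3);
  int i_samp = 0;
  double next_sample = 0.0;

  const double quarter_r2 = 0.25 * r_motor * r_motor;
  double min_free = 1.0, min_p = 0.0;
  double t = 0.0;

  for (int step = 0; step <= n_steps; ++step) {
    double dsq = 0.0;
    for (int a = 0; a < 3; ++a) {
      double d = x1[a] - x2[a];
      dsq += d * d;
    }
    double d_pp = std::sqrt(dsq);
    if (d_pp <= 0.0)
      stop("poles coincide at t = %f s: spindle axis undefined", t);

    if (i_samp < n_samp && t + 1e-9 >= next_sample) {
      s_t[i_samp] = t;
      s_dpp[i_samp] = d_pp;
      s_dcc[i_samp] = c_f * (1.0 - std::exp(-t / tau_c));
      for (int a = 0; a < 3; ++a) {
        s_x1(i_samp, a) = x1[a];
        s_x2(i_samp, a) = x2[a];
      }
      ++i_samp;
      next_sample += sample_every;
    }
    if (step == n_steps) break;

    // 1. impingement rates + pole->patch unit vectors
    double o_max = 0.0;
    for (int k = 0; k < n; ++k) {
      double dx = patches(k, 0) - x1[0], dy = patches(k, 1) - x1[1], dz = patches(k, 2) - x1[2];
      double d1 = std::sqrt(dx * dx + dy * dy + dz * dz);
      u1x[k] = dx / d1; u1y[k] = dy / d1; u1z[k] = dz / d1;
      O1[k] = n_mt * lambda * quarter_r2 / (d1 * d1) * std::exp(-lambda * d1 / v_g);

      dx = patches(k, 0) - x2[0]; dy = patches(k, 1) - x2[1]; dz = patches(k, 2) - x2[2];
      double d2 = std::sqrt(dx * dx + dy * dy + dz * dz);
      u2x[k] = dx / d2; u2y[k] = dy / d2; u2z[k] = dz / d2;
      O2[k] = n_mt * lambda * quarter_r2 / (d2 * d2) * std::exp(-lambda * d2 / v_g);

      if (O1[k] > o_max) o_max = O1[k];
      if (O2[k] > o_max) o_max = O2[k];
    }
    if (dt * (o_max + kappa) >= 1.0)
      stop("explicit field update unstable: dt = %f with dt*(max Omega + kappa) = %f >= 1; reduce dt",
           dt, dt * (o_max + kappa));

    // 2. field update, 3. force accumulation
    double F1[3] = {0, 0, 0}, F2[3] = {0, 0, 0};
    for (int k = 0; k < n; ++k) {
      double free = 1.0 - P1[k] - P2[k];
      P1[k] += dt * (O1[k] * free - kappa * P1[k]);
      P2[k] += dt * (O2[k] * free - kappa * P2[k]);
      double f = 1.0 - P1[k] - P2[k];
      if (f < min_free) min_free = f;
      if (P1[k] < min_p) min_p = P1[k];
      if (P2[k] < min_p) min_p = P2[k];
      F1[0] += P1[k] * u1x[k]; F1[1] += P1[k] * u1y[k]; F1[2] += P1[k] * u1z[k];
      F2[0] += P2[k] * u2x[k]; F2[1] += P2[k] * u2y[k]; F2[2] += P2[k] * u2z[k];
    }
    for (int a = 0; a < 3; ++a) {
      F1[a] *= force_prefactor * patch_area;
      F2[a] *= force_prefactor * patch_area;
    }

    // 4. pole update; chromosome plate velocity along s_hat is the analytic
    //    derivative of the imposed law, split evenly between the two plates
    double s_hat[3];
    for (int a = 0; a < 3; ++a) s_hat[a] = (x1[a] - x2[a]) / d_pp;
    double dc_dot = (c_f / tau_c) * std::exp(-t / tau_c);
    double c1_par = 0.5 * dc_dot, c2_par = -0.5 * dc_dot;

    double F1par = F1[0] * s_hat[0] + F1[1] * s_hat[1] + F1[2] * s_hat[2];
    double F2par = F2[0] * s_hat[0] + F2[1] * s_hat[1] + F2[2] * s_hat[2];
    double v1par = (F1par + nu * c1_par) / (eta + nu);
    double v2par = (F2par + nu * c2_par) / (eta + nu);

    double r1 = 0.0, r2 = 0.0;
    for (int a = 0; a < 3; ++a) {
      double v1 = (F1[a] - F1par * s_hat[a]) / eta + v1par * s_hat[a];
      double v2 = (F2[a] - F2par * s_hat[a]) / eta + v2par * s_hat[a];
      x1[a] += dt * v1;
      x2[a] += dt * v2;
      r1 += x1[a] * x1[a];
      r2 += x2[a] * x2[a];
    }
    if (r1 >= radius * radius || r2 >= radius * radius)
      stop("pole escaped the cell at t = %f s (parameter pathology)", t + dt);

    t += dt;
  }

  return List::create(
    _["t_s"] = s_t, _["d_pp_um"] = s_dpp, _["d_cc_um"] = s_dcc,
    _["x1"] = s_x1, _["x2"] = s_x2,
    _["P1"] = NumericVector(P1.begin(), P1.end()),
    _["P2"] = NumericVector(P2.begin(), P2.end()),
    _["min_free"] = min_free, _["min_p"] = min_p);
}
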