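// BAOAB Langevin integrator for the alchemical theta coordinates.
//
// The sampled potential is the reduced composite potential evaluated at
// lambda = softmax(steepness * theta) per site, plus a harmonic confinement
// (restraint/2) * |theta|^2 that regularises the softmax gauge directions
// and the vertex plateaus.  Forces use the softmax Jacobian chain rule.
// The R-level RNG is used (norm_rand), so set.seed() on the R side makes
// trajectories bit-reproducible.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
List msld_run_cpp(NumericVector theta0, NumericVector vel0,
                  NumericVector hb, NumericMatrix C, // hb = h - b
                  IntegerVector site_start, IntegerVector site_len,
                  double steepness, double restraint,
                  double dt, double friction, double kT, double mass,
                  int n_steps, int save_interval) {
  const int P = theta0.size();
  const int M = site_start.size();
  const int n_frames = n_steps / save_interval;
  NumericMatrix lam_out(n_frames, P), theta_out(n_frames, P);
  IntegerVector steps_out(n_frames);

  std::vector<double> th(theta0.begin(), theta0.end());
  std::vector<double> v(vel0.begin(), vel0.end());
  std::vector<double> lam(P), g(P), f(P);

  const double c1 = std::exp(-friction * dt);
  const double c2 = (friction > 0.0)
    ? std::sqrt((1.0 - c1 * c1) * kT / mass) : 0.0;

  auto compute_force = [&]() {
    for (int s = 0; s < M; ++s) {
      const int a = site_start[s], L = site_len[s];
      double mx = th[a];
      for (int i = 1; i < L; ++i) if (th[a + i] > mx) mx = th[a + i];
      double Z = 0.0;
      for (int i = 0; i < L; ++i) {
        lam[a + i] = std::exp(steepness * (th[a + i] - mx));
        Z += lam[a + i];
      }
      for (int i = 0; i < L; ++i) lam[a + i] /= Z;
    }
    for (int p = 0; p < P; ++p) {
      double acc = hb[p];
      for (int q = 0; q < P; ++q) acc += C(p, q) * lam[q];
      g[p] = acc;
    }
    for (int s = 0; s < M; ++s) {
      const int a = site_start[s], L = site_len[s];
      double dot = 0.0;
      for (int i = 0; i < L; ++i) dot += g[a + i] * lam[a + i];
      for (int i = 0; i < L; ++i)
        f[a + i] = -steepness * lam[a + i] * (g[a + i] - dot)
                   - restraint * th[a + i];
    }
  };

  compute_force();
  int fi = 0, bad_step = -1;
  for (int step = 1; step <= n_steps; ++step) {
    for (int p = 0; p < P; ++p) v[p] += 0.5 * dt * f[p] / mass;   // B
    for (int p = 0; p < P; ++p) th[p] += 0.5 * dt * v[p];         // A
    if (friction > 0.0)
      for (int p = 0; p < P; ++p) v[p] = c1 * v[p] + c2 * norm_rand(); // O
    for (int p = 0; p < P; ++p) th[p] += 0.5 * dt * v[p];         // A
    compute_force();
    for (int p = 0; p < P; ++p) v[p] += 0.5 * dt * f[p] / mass;   // B

    bool ok = true;
    for (int p = 0; p < P; ++p)
      if (!std::isfinite(th[p]) || !std::isfinite(v[p])) ok = false;
    if (!ok) { bad_step = step; break; }

    if (step % save_interval == 0) {
      for (int p = 0; p < P; ++p) {
        lam_out(fi, p) = lam[p];
        theta_out(fi, p) = th[p];
      }
      steps_out[fi] = step;
      ++fi;
    }
  }

  return List::create(
    _["lambda"] = lam_out, _["theta"] = theta_out, _["step"] = steps_out,
    _["final_theta"] = NumericVector(th.begin(), th.end()),
    _["final_velocity"] = NumericVector(v.begin(), v.end()),
    _["n_saved"] = fi, _["bad_step"] = bad_step);
}
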