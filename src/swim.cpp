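// Stochastic 3-D run-and-tumble simulation of chemotactic cells in a
// static exponential ligand field L(x) = L0 * exp(g * x1).
//
// Per step and cell: (1) Euler update of the receptor methylation level at
// the local ligand concentration; (2) CheY-P and motor switching rates;
// (3) Bernoulli mode switch with p = 1 - exp(-lambda*dt); (4) runs advance
// the position and rotationally diffuse the heading, tumbles keep the cell
// in place and redraw the heading uniformly on exiting the tumble; (5)
// optional slow FliM-ring (motor adaptation) Euler update.
//
// Each cell owns an independent mt19937_64 stream seeded from
// (master seed, cell index), so results are reproducible and stable under
// changes of the population size.

#include <Rcpp.h>
#include <random>
#include <cmath>
using namespace Rcpp;

namespace {

struct Vec3 { double x, y, z; };

inline void normalize(Vec3 &u) {
  double n = std::sqrt(u.x * u.x + u.y * u.y + u.z * u.z);
  u.x /= n; u.y /= n; u.z /= n;
}

inline Vec3 random_unit(std::mt19937_64 &rng) {
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  double z = 2.0 * unif(rng) - 1.0;
  double phi = 2.0 * M_PI * unif(rng);
  double r = std::sqrt(std::max(0.0, 1.0 - z * z));
  return Vec3{r * std::cos(phi), r * std::sin(phi), z};
}

// two Gaussian angular increments (variance 2*Dr*dt) in the plane
// perpendicular to u; realizes <u(t).u(0)> = exp(-2*Dr*t) in 3-D
inline void rotational_diffusion(Vec3 &u, double sigma,
                                 std::mt19937_64 &rng,
                                 std::normal_distribution<double> &norm) {
  Vec3 e1;
  if (std::fabs(u.x) < 0.9) e1 = Vec3{0.0, -u.z, u.y};
  else e1 = Vec3{-u.z, 0.0, u.x};
  normalize(e1);
  Vec3 e2{u.y * e1.z - u.z * e1.y,
          u.z * e1.x - u.x * e1.z,
          u.x * e1.y - u.y * e1.x};
  double a = sigma * norm(rng), b = sigma * norm(rng);
  u.x += a * e1.x + b * e2.x;
  u.y += a * e1.y + b * e2.y;
  u.z += a * e1.z + b * e2.z;
  normalize(u);
}

} // namespace

// [[Rcpp::export(name = ".simulate_population_cpp")]]
List simulate_population_cpp(
    int n_cells, double T, double dt,
    double Y0, double tau,
    double alpha, double eps0, double eps1, double Ngain,
    double Ki, double Ka, double m_max,
    int asym, double VR, double VB,
    double omega, double eps2, double eps3, double K,
    int motor_adapt, double k_on, double k_off,
    double n1, double n2, double n0, double dn,
    double eps3_0, double eps3_1,
    double L0, double g, double v, double Dr,
    double t_win0, double t_win1, double sample_dt,
    double seed) {

  const int nsteps = (int)std::llround(T / dt);
  const int sample_every = std::max(1, (int)std::llround(sample_dt / dt));
  const int nsamp = nsteps / sample_every + 1;
  const double F0 = std::log(alpha / Y0 - 1.0);
  const double sigma_rot = std::sqrt(2.0 * Dr * dt);

  // adapted methylation at the origin concentration
  double lig0 = Ngain * std::log((1.0 + L0 / Ki) / (1.0 + L0 / Ka));
  double m_init = (F0 - eps0 - lig0) / eps1;
  m_init = std::min(std::max(m_init, 0.0), m_max);

  // adapted tumble bias for the initial motor mode
  double e3_init = motor_adapt ? (eps3_0 + eps3_1 * (n0 - n0)) : eps3;
  double dG0 = eps2 / 2.0 - e3_init * Y0 / (Y0 + K);
  double TB0 = 1.0 / (1.0 + std::exp(dG0));

  NumericVector x1_w0(n_cells), x1_w1(n_cells), x1_end(n_cells),
      perp_end(n_cells);
  NumericVector y_cell(n_cells);      // per-cell window-mean CheY-P
  NumericVector meanY(nsamp), meanL(nsamp), times(nsamp);
  double sumY_win = 0.0;              // population-and-time mean CheY-P
  long n_win = 0;
  double run_time_total = 0.0;        // run-length bookkeeping
  long n_runs_completed = 0;

  const int i_w0 = (int)std::llround(t_win0 / dt);
  const int i_w1 = (int)std::llround(t_win1 / dt);

  for (int c = 0; c < n_cells; ++c) {
    std::seed_seq ss{(unsigned long long)seed, (unsigned long long)c};
    std::mt19937_64 rng(ss);
    std::uniform_real_distribution<double> unif(0.0, 1.0);
    std::normal_distribution<double> norm(0.0, 1.0);

    Vec3 x{0.0, 0.0, 0.0};
    Vec3 u = random_unit(rng);
    double m = m_init;
    bool tumbling = unif(rng) < TB0;
    double n_flim = n0;
    double y_sum = 0.0;
    long y_n = 0;
    double run_start = tumbling ? -1.0 : 0.0;

    for (int i = 0; i < nsteps; ++i) {
      double t = i * dt;
      // (1) pathway update at local ligand
      double L = L0 * std::exp(g * x.x);
      double lig = Ngain * std::log((1.0 + L / Ki) / (1.0 + L / Ka));
      double F = eps0 + eps1 * m + lig;
      double dm;
      if (asym) {
        double a = 1.0 / (1.0 + std::exp(F));
        dm = VR * (1.0 - a) - VB * a;
      } else {
        dm = (F0 - F) / (tau * eps1);
      }
      m = std::min(std::max(m + dt * dm, 0.0), m_max);
      F = eps0 + eps1 * m + lig;
      // (2) CheY-P and motor
      double Y = alpha / (1.0 + std::exp(F));
      double e3 = motor_adapt ? (eps3_0 + eps3_1 * (n_flim - n0)) : eps3;
      double dG = eps2 / 2.0 - e3 * Y / (Y + K);
      double CW = 1.0 / (1.0 + std::exp(dG));
      // (3) mode switching
      if (tumbling) {
        double lamT = omega * std::exp(dG / 2.0);
        if (unif(rng) < -std::expm1(-lamT * dt)) {
          tumbling = false;
          u = random_unit(rng);   // reorient on tumble exit
          run_start = t;
        }
      } else {
        double lamR = omega * std::exp(-dG / 2.0);
        if (unif(rng) < -std::expm1(-lamR * dt)) {
          tumbling = true;
          if (run_start >= 0.0) {
            run_time_total += t - run_start;
            ++n_runs_completed;
          }
        }
      }
      // (4) motion
      if (!tumbling) {
        x.x += v * dt * u.x;
        x.y += v * dt * u.y;
        x.z += v * dt * u.z;
        if (Dr > 0.0) rotational_diffusion(u, sigma_rot, rng, norm);
      }
      // (5) slow FliM remodelling
      if (motor_adapt) {
        // CCW recruits FliM at rate k_off, CW releases it at k_on, each
        // saturating at the ring-size bounds (same law as flim_step)
        double bind = (n2 - n_flim) / ((n2 - n_flim) + dn);
        double unbind = (n_flim - n1) / ((n_flim - n1) + dn);
        n_flim += dt * (k_off * (1.0 - CW) * bind - k_on * CW * unbind);
        n_flim = std::min(std::max(n_flim, n1), n2);
      }
      // observables
      int i1 = i + 1;
      if (i1 == i_w0) x1_w0[c] = x.x;
      if (i1 == i_w1) x1_w1[c] = x.x;
      if (i1 % sample_every == 0) {
        int k = i1 / sample_every;
        double t1 = i1 * dt;
        meanY[k] += Y;
        meanL[k] += L0 * std::exp(g * x.x);
        if (t1 >= t_win0 && t1 <= t_win1) {
          sumY_win += Y;
          ++n_win;
          y_sum += Y;
          ++y_n;
        }
      }
    }
    x1_end[c] = x.x;
    perp_end[c] = std::sqrt(x.y * x.y + x.z * x.z);
    y_cell[c] = y_n > 0 ? y_sum / y_n : NA_REAL;
  }

  for (int k = 0; k < nsamp; ++k) {
    times[k] = k * sample_every * dt;
    if (k == 0) { meanY[k] = NA_REAL; meanL[k] = L0; }
    else { meanY[k] /= n_cells; meanL[k] /= n_cells; }
  }

  return List::create(
      _["x1_w0"] = x1_w0, _["x1_w1"] = x1_w1, _["x1_end"] = x1_end,
      _["perp_end"] = perp_end,
      _["y_cell"] = y_cell, _["times"] = times,
      _["meanY"] = meanY, _["meanL"] = meanL,
      _["Y_m"] = n_win > 0 ? sumY_win / n_win : NA_REAL,
      _["TB0"] = TB0, _["m_init"] = m_init,
      _["mean_run_length"] =
          n_runs_completed > 0 ? run_time_total / n_runs_completed : NA_REAL,
      _["n_runs"] = (double)n_runs_completed);
}
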