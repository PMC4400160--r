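// Core numerical routines: seeded RNG streams, alpha-kernel rendering, and
// the forward-Euler membrane integration.  All stochastic draws go through an
// explicitly seeded mt19937_64 so that results are reproducible from a single
// run seed without touching R's global RNG state.
#include <Rcpp.h>
#include <random>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// Fold integer-valued keys into one stream seed, returned as a double below
// 2^53 so it survives the round trip through R numerics.
// [[Rcpp::export]]
double derive_seed_cpp(NumericVector keys) {
  uint64_t h = 0x9E3779B97F4A7C15ULL;
  for (R_xlen_t i = 0; i < keys.size(); ++i) {
    h = splitmix64(h ^ (uint64_t)(int64_t)std::llround(keys[i]));
  }
  return (double)(h >> 11); // 53 bits
}

static std::mt19937_64 make_rng(double seed) {
  return std::mt19937_64((uint64_t)seed);
}

// [[Rcpp::export]]
NumericVector rnorm_seeded_cpp(int n, double mean, double sd, double seed) {
  std::mt19937_64 rng = make_rng(seed);
  std::normal_distribution<double> g(mean, sd);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = g(rng);
  return out;
}

// [[Rcpp::export]]
NumericVector runif_seeded_cpp(int n, double lo, double hi, double seed) {
  std::mt19937_64 rng = make_rng(seed);
  std::uniform_real_distribution<double> u(lo, hi);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = u(rng);
  return out;
}

// Accumulate peak-normalized alpha kernels g(t) = amp * (t/tau) * exp(1 - t/tau)
// onto a uniform grid of n_samples points spaced dt ms apart.  Events whose
// onset precedes t = 0 are truncated at 0 (only the t >= 0 part is kept).
//
// The alpha function is the impulse response of a critically damped
// second-order filter, so the whole trace is generated in O(n_samples) by
// the exact recursion (d = exp(-dt/tau)):
//   u[i] = d * u[i-1] + deposit[i]          (one-pole exponential)
//   s[i] = d * (s[i-1] + u[i-1])            (ramp * exponential)
//   g[i] = e * (dt/tau) * s[i]
// which reproduces the sampled kernel exactly for events on the grid; event
// times are rounded to the nearest sample (dt = 0.1 ms, far below the 1 ms
// synaptic jitter).
// [[Rcpp::export]]
NumericVector add_alpha_kernels_cpp(int n_samples, double dt,
                                    NumericVector times, NumericVector amps,
                                    double tau) {
  if (tau <= 0) stop("alpha kernel time constant must be positive");
  NumericVector out(n_samples); // zero-initialized
  const double d = std::exp(-dt / tau);
  const double gain = std::exp(1.0) * dt / tau;
  std::vector<double> dep(n_samples, 0.0);
  double u = 0.0, s = 0.0; // state just before sample 0
  for (R_xlen_t k = 0; k < times.size(); ++k) {
    const double a = amps[k];
    if (a == 0.0) continue;
    long idx = std::lround(times[k] / dt);
    if (idx >= n_samples) continue;
    if (idx < 0) {
      // event already in progress at t = 0: fold it into the initial state
      const double m = (double)(-idx);
      const double w = a * std::pow(d, m - 1.0);
      u += w;
      s += (m - 1.0) * w;
    } else {
      dep[idx] += a;
    }
  }
  for (int i = 0; i < n_samples; ++i) {
    const double s_new = d * (s + u);
    u = d * u + dep[i];
    s = s_new;
    out[i] = gain * s;
  }
  return out;
}

// Forward-Euler integration of the conductance-based membrane equation
//   V <- V - (dt/C) * [ g_e (V - E_e) + g_i (V - E_i) + g_rest (V - E_rest) ]
// with units mV, nS, nF, ms (the ms -> s conversion gives the 1e-3 factor).
// noise_mode: 0 none, 1 conductance (sigma_ns nS added i.i.d. per step to each
// channel, unclipped), 2 injected current (sigma_mv mV increment per step),
// 3 spiking threshold (redrawn per step around V_thresh with SD sigma_mv).
// A spike is recorded at the first step where V >= threshold; V resets.
// [[Rcpp::export]]
List simulate_trial_cpp(NumericVector g_e, NumericVector g_i,
                        double dt, double C, double g_rest,
                        double E_e, double E_i, double E_rest,
                        double V_thresh, double V_reset, double refractory,
                        int noise_mode, double sigma_ns, double sigma_mv,
                        double seed, bool return_voltage) {
  const int n = g_e.size();
  if (g_i.size() != n) stop("g_e and g_i must have the same length");
  std::mt19937_64 rng = make_rng(seed);
  std::normal_distribution<double> gauss(0.0, 1.0);

  const double k = dt * 1e-3 / C; // (ms -> s) / nF
  double V = E_rest;
  int refr_steps = (refractory > 0) ? (int)std::ceil(refractory / dt) : 0;
  int refr_left = 0;
  std::vector<double> spikes;
  NumericVector volt;
  if (return_voltage) volt = NumericVector(n);

  for (int i = 0; i < n; ++i) {
    double ge = g_e[i], gi = g_i[i];
    if (noise_mode == 1) {
      ge += sigma_ns * gauss(rng);
      gi += sigma_ns * gauss(rng);
    }
    double thr = V_thresh;
    if (noise_mode == 3) thr = V_thresh + sigma_mv * gauss(rng);

    if (refr_left > 0) {
      --refr_left;
      V = V_reset;
    } else {
      V = V - k * (ge * (V - E_e) + gi * (V - E_i) + g_rest * (V - E_rest));
      if (noise_mode == 2) V += sigma_mv * gauss(rng);
      if (!std::isfinite(V))
        stop("membrane potential diverged at step %d", i + 1);
      if (V >= thr) {
        spikes.push_back((i + 1) * dt);
        V = V_reset;
        refr_left = refr_steps;
      }
    }
    if (return_voltage) volt[i] = V;
  }

  List out = List::create(_["spike_times"] = NumericVector(spikes.begin(), spikes.end()));
  if (return_voltage) out["voltage"] = volt;
  return out;
}
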