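#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Small fast PRNG (xoshiro256++) with Box-Muller normals. Seeded from R's
// RNG stream, so set.seed() in R fully determines the simulation.
namespace {

struct Xoshiro {
  uint64_t s[4];
  double spare;
  bool has_spare;

  static uint64_t splitmix64(uint64_t& x) {
    uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  explicit Xoshiro(uint64_t seed) : spare(0.0), has_spare(false) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  double runif() {  // in (0, 1]
    return ((next() >> 11) + 1) * 0x1.0p-53;
  }
  double rnorm() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = runif(), u2 = runif();
    double m = std::sqrt(-2.0 * std::log(u1)), a = 6.283185307179586 * u2;
    spare = m * std::sin(a);
    has_spare = true;
    return m * std::cos(a);
  }
};

inline double tf_eval(const std::vector<double>& gx,
                      const std::vector<double>& gy, double x) {
  const int m = (int)gx.size();
  if (x < gx[0]) return 0.0;
  if (x >= gx[m - 1]) return gy[m - 1];
  int lo = 0, hi = m - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (gx[mid] <= x) lo = mid; else hi = mid;
  }
  double t = (x - gx[lo]) / (gx[lo + 1] - gx[lo]);
  return gy[lo] + t * (gy[lo + 1] - gy[lo]);
}

}  // namespace

// Explicit Euler-Maruyama integration of the stochastic rate network over an
// ensemble of realizations, accumulating across-realization moment sums of
// the rate at every step, windowed spike-count proxies per realization, and
// (optionally) full rate trajectories for the first keep_traj realizations.
// [[Rcpp::export(name = ".em_core")]]
List em_core(int n_real, int n_steps, double dt,
             NumericVector tau, NumericMatrix mu, NumericMatrix sigma,
             NumericMatrix L, NumericMatrix W,
             List gate_alpha, List gate_beta, NumericVector rbar,
             List tf_x, List tf_y,
             int half_steps, int keep_traj, bool gate_check) {
  const int n = tau.size();
  if (mu.nrow() != n_steps || mu.ncol() != n)
    stop("mu must be n_steps x n");
  const int npair = n * (n - 1) / 2;

  std::vector< std::vector<double> > gx(n), gy(n), ga(n), gb(n);
  int n_gates = 0;
  for (int j = 0; j < n; ++j) {
    gx[j] = as< std::vector<double> >(tf_x[j]);
    gy[j] = as< std::vector<double> >(tf_y[j]);
    ga[j] = as< std::vector<double> >(gate_alpha[j]);
    gb[j] = as< std::vector<double> >(gate_beta[j]);
    n_gates += (int)ga[j].size();
  }
  // flat copies for the hot loop (column-major like R matrices)
  std::vector<double> muv(mu.begin(), mu.end());
  std::vector<double> sgv(sigma.begin(), sigma.end());
  std::vector<double> Lv(L.begin(), L.end());
  std::vector<double> Wv(W.begin(), W.end());
  std::vector<double> tauv(tau.begin(), tau.end());
  std::vector<double> rbv(rbar.begin(), rbar.end());

  int n_blocks = (half_steps > 0) ? n_steps / half_steps : 0;
  int n_win = (n_blocks > 1) ? n_blocks - 1 : 0;

  NumericVector sum_r(n_steps * n), sumsq_r(n_steps * n);
  NumericVector cross_r(std::max(n_steps * npair, 1));
  NumericVector counts(std::max(n_win * n * n_real, 1));
  NumericVector traj(std::max(n_steps * n * keep_traj, 1));
  double gate_min = 1.0, gate_max = 0.0;

  std::vector<double> x(n), r(n), z(n), g(n), drive(n), s(n_gates);
  std::vector<int> s_off(n + 1, 0);
  for (int j = 0; j < n; ++j) s_off[j + 1] = s_off[j] + (int)ga[j].size();
  std::vector<double> block(std::max(n_blocks * n, 1));
  const double sqdt = std::sqrt(dt), dt_s = dt / 1000.0;

  // derive the stream seed from R's RNG so set.seed() governs everything
  uint64_t seed64;
  {
    RNGScope scope;
    double a = unif_rand(), b = unif_rand();
    seed64 = (uint64_t)(a * 9007199254740992.0) ^
             ((uint64_t)(b * 9007199254740992.0) << 11);
  }
  Xoshiro rng(seed64);

  for (int rep = 0; rep < n_real; ++rep) {
    for (int j = 0; j < n; ++j) {
      x[j] = muv[0 + n_steps * j];
      r[j] = tf_eval(gx[j], gy[j], x[j]);
      double f = r[j] / rbv[j];
      for (int q = s_off[j]; q < s_off[j + 1]; ++q) {
        int qq = q - s_off[j];
        s[q] = ga[j][qq] * f / (gb[j][qq] + ga[j][qq] * f);
      }
    }
    std::fill(block.begin(), block.end(), 0.0);

    for (int i = 0; i < n_steps; ++i) {
      // composite gates and synaptic drive (previous-step values)
      for (int k = 0; k < n; ++k) {
        double acc = 0.0;
        for (int q = s_off[k]; q < s_off[k + 1]; ++q) acc += s[q];
        g[k] = acc;
      }
      for (int j = 0; j < n; ++j) drive[j] = 0.0;
      for (int k = 0; k < n; ++k) {
        const double gk = g[k];
        if (gk != 0.0) {
          const double* wc = &Wv[n * k];
          for (int j = 0; j < n; ++j) drive[j] += wc[j] * gk;
        }
      }
      // gate update from previous-step rates
      for (int k = 0; k < n; ++k) {
        double f = r[k] / rbv[k];
        for (int q = s_off[k]; q < s_off[k + 1]; ++q) {
          int qq = q - s_off[k];
          s[q] += dt * (ga[k][qq] * f * (1.0 - s[q]) - gb[k][qq] * s[q]);
          if (gate_check) {
            if (s[q] < gate_min) gate_min = s[q];
            if (s[q] > gate_max) gate_max = s[q];
          }
        }
      }
      // correlated noise and state update
      for (int j = 0; j < n; ++j) z[j] = rng.rnorm();
      for (int j = 0; j < n; ++j) {
        double acc = 0.0;
        const double* lr = &Lv[j];   // row j, stride n
        for (int m = 0; m <= j; ++m) acc += lr[n * m] * z[m];
        x[j] += dt / tauv[j] * (-x[j] + muv[i + n_steps * j] + drive[j])
          + sgv[i + n_steps * j] / tauv[j] * sqdt * acc;
      }
      // new rates, recorded at sample slot i
      for (int j = 0; j < n; ++j) {
        double rj = tf_eval(gx[j], gy[j], x[j]);
        r[j] = rj;
        sum_r[i + n_steps * j] += rj;
        sumsq_r[i + n_steps * j] += rj * rj;
        if (rep < keep_traj)
          traj[i + n_steps * (j + n * rep)] = rj;
        if (n_blocks > 0) {
          int b = i / half_steps;
          if (b < n_blocks) block[b + n_blocks * j] += rj;
        }
      }
      int p = 0;
      for (int j = 0; j < n; ++j)
        for (int k = j + 1; k < n; ++k, ++p)
          cross_r[i + n_steps * p] += r[j] * r[k];
    }
    for (int j = 0; j < n; ++j)
      for (int w = 0; w < n_win; ++w)
        counts[w + n_win * (j + n * rep)] =
          dt_s * (block[w + n_blocks * j] + block[w + 1 + n_blocks * j]);
  }

  return List::create(
    _["sum_r"] = sum_r, _["sumsq_r"] = sumsq_r, _["cross_r"] = cross_r,
    _["counts"] = counts, _["traj"] = traj, _["n_win"] = n_win,
    _["gate_min"] = gate_min, _["gate_max"] = gate_max);
}
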