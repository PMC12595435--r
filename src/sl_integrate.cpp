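#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// xoshiro256++ with splitmix64 seeding; the 64-bit seed is drawn from R's
// RNG at entry, so runs remain reproducible under set.seed() while the hot
// loop avoids R RNG API calls (millions of normal draws per run).
namespace {

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion
    for (int i = 0; i < 4; ++i) {
      seed += 0x9e3779b97f4a7c15ULL;
      uint64_t z = seed;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() {  // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  bool have_spare = false;
  double spare = 0.0;
  double norm() {  // Marsaglia polar
    if (have_spare) { have_spare = false; return spare; }
    double u, v, s;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s = u * u + v * v;
    } while (s >= 1.0 || s == 0.0);
    const double m = std::sqrt(-2.0 * std::log(s) / s);
    spare = v * m;
    have_spare = true;
    return u * m;
  }
};

}  // namespace

// Euler-Maruyama integration of the feedback-modified Stuart-Landau network
//
//   dz_j = [ (lambda_j + i*omega_j - |z_j|^2) z_j
//            + S * R(t)^Z * C_j(t) + u(t) ] dt + beta dW_j
//
// with C_j(t) = sum_k A_jk (z_k(t - tau_jk) - z_j(t))   (diffusive, default)
//            or sum_k A_jk  z_k(t - tau_jk)             (direct sum)
//
// R(t) is the instantaneous Kuramoto order parameter computed from the
// current phases; u(t) is a real pulse applied identically to every node.
// Delays are handled with a ring buffer of past states; the pre-onset
// history is the initial state held constant. Noise uses R's RNG so that
// set.seed() upstream makes runs bit-reproducible.
//
// edge_src/edge_dst are 0-based directed edges (each undirected link listed
// in both directions); edge_delay is the per-edge delay in whole steps.

// [[Rcpp::export]]
List sl_integrate_cpp(IntegerVector edge_src,
                      IntegerVector edge_dst,
                      IntegerVector edge_delay,
                      int n_nodes,
                      NumericVector omega,
                      NumericVector lambda,
                      double coupling,
                      double feedback_exponent,
                      double noise_sd_step,
                      double dt,
                      int n_steps,
                      int transient_steps,
                      double pert_strength,
                      int pert_on_step,
                      int pert_off_step,
                      NumericVector z0_re,
                      NumericVector z0_im,
                      bool diffusive,
                      bool amplitude_feedback,
                      bool record_states,
                      int keep_every,
                      double blowup_guard)
{
  const int n_edges = edge_src.size();
  const double guard2 = blowup_guard * blowup_guard;

  uint64_t rng_seed;
  {
    RNGScope scope;  // derive the stream seed from R's RNG (set.seed())
    rng_seed = (uint64_t)(unif_rand() * 4294967296.0) << 32;
    rng_seed |= (uint64_t)(unif_rand() * 4294967296.0);
  }
  Xoshiro rng(rng_seed);

  int max_delay = 0;
  bool uniform_delay = true;
  const int d0 = n_edges > 0 ? edge_delay[0] : 0;
  for (int e = 0; e < n_edges; ++e) {
    if (edge_delay[e] > max_delay) max_delay = edge_delay[e];
    if (edge_delay[e] != d0) uniform_delay = false;
  }
  const int L = max_delay + 1;

  // ring buffer of past states, pre-filled with the initial state
  std::vector<double> hre((size_t)L * n_nodes), him((size_t)L * n_nodes);
  for (int s = 0; s < L; ++s)
    for (int j = 0; j < n_nodes; ++j) {
      hre[(size_t)s * n_nodes + j] = z0_re[j];
      him[(size_t)s * n_nodes + j] = z0_im[j];
    }

  std::vector<int> degree(n_nodes, 0);
  for (int e = 0; e < n_edges; ++e) degree[edge_dst[e]]++;

  std::vector<double> zre(z0_re.begin(), z0_re.end());
  std::vector<double> zim(z0_im.begin(), z0_im.end());
  std::vector<double> cre(n_nodes), cim(n_nodes);

  // the rotation exp(i*omega*dt) is applied exactly each step (operator
  // splitting); a naive Euler rotation at omega*dt ~ 0.06 inflates the
  // limit-cycle amplitude by ~omega^2*dt/2 and breaks the sqrt(lambda)
  // fixed point
  std::vector<double> rot_c(n_nodes), rot_s(n_nodes);
  for (int j = 0; j < n_nodes; ++j) {
    rot_c[j] = std::cos(omega[j] * dt);
    rot_s[j] = std::sin(omega[j] * dt);
  }

  NumericVector r_series(n_steps - transient_steps);

  int n_kept = 0;
  NumericMatrix st_re, st_im;
  if (record_states) {
    n_kept = (n_steps - transient_steps + keep_every - 1) / keep_every;
    st_re = NumericMatrix(n_kept, n_nodes);
    st_im = NumericMatrix(n_kept, n_nodes);
  }
  int kept_row = 0;

  for (int t = 0; t < n_steps; ++t) {
    // instantaneous order parameter from current phases
    double sx = 0.0, sy = 0.0;
    for (int j = 0; j < n_nodes; ++j) {
      double a = std::sqrt(zre[j] * zre[j] + zim[j] * zim[j]);
      if (a > 1e-300) { sx += zre[j] / a; sy += zim[j] / a; }
      else            { sx += 1.0; }
    }
    sx /= n_nodes; sy /= n_nodes;
    const double R = std::sqrt(sx * sx + sy * sy);

    if (t >= transient_steps) {
      r_series[t - transient_steps] = R;
      if (record_states && (t - transient_steps) % keep_every == 0) {
        for (int j = 0; j < n_nodes; ++j) {
          st_re(kept_row, j) = zre[j];
          st_im(kept_row, j) = zim[j];
        }
        ++kept_row;
      }
    }

    const double Rz =
      (feedback_exponent == 0.0) ? 1.0 : std::pow(R, feedback_exponent);

    std::fill(cre.begin(), cre.end(), 0.0);
    std::fill(cim.begin(), cim.end(), 0.0);
    if (uniform_delay) {
      const int slot0 = (((t - d0) % L) + L) % L;
      const double* hre0 = &hre[(size_t)slot0 * n_nodes];
      const double* him0 = &him[(size_t)slot0 * n_nodes];
      for (int e = 0; e < n_edges; ++e) {
        cre[edge_dst[e]] += hre0[edge_src[e]];
        cim[edge_dst[e]] += him0[edge_src[e]];
      }
    } else {
      for (int e = 0; e < n_edges; ++e) {
        int slot = t - edge_delay[e];
        slot = ((slot % L) + L) % L;
        const size_t off = (size_t)slot * n_nodes + edge_src[e];
        cre[edge_dst[e]] += hre[off];
        cim[edge_dst[e]] += him[off];
      }
    }
    if (diffusive) {
      for (int j = 0; j < n_nodes; ++j) {
        cre[j] -= degree[j] * zre[j];
        cim[j] -= degree[j] * zim[j];
      }
    }

    const double u =
      (t >= pert_on_step && t < pert_off_step) ? pert_strength : 0.0;
    const double sr_global = coupling * Rz;

    const int next = (t + 1) % L;
    bool blow = false;
    for (int j = 0; j < n_nodes; ++j) {
      const double a2 = zre[j] * zre[j] + zim[j] * zim[j];
      const double g = lambda[j] - a2;
      // feedback gain: per-node amplitude |z_j|^Z, or global R^Z
      const double sr = amplitude_feedback
        ? ((feedback_exponent == 0.0)
             ? coupling
             : coupling * std::pow(std::sqrt(a2), feedback_exponent))
        : sr_global;
      const double dre = g * zre[j] + sr * cre[j] + u;
      const double dim = g * zim[j] + sr * cim[j];
      const double xre = zre[j] + dt * dre + noise_sd_step * rng.norm();
      const double xim = zim[j] + dt * dim + noise_sd_step * rng.norm();
      zre[j] = xre * rot_c[j] - xim * rot_s[j];
      zim[j] = xre * rot_s[j] + xim * rot_c[j];
      hre[(size_t)next * n_nodes + j] = zre[j];
      him[(size_t)next * n_nodes + j] = zim[j];
      if (zre[j] * zre[j] + zim[j] * zim[j] > guard2) blow = true;
    }
    if (blow)
      stop("numerical blow-up: |z| exceeded %g at t = %g s; "
           "reduce dt or coupling", blowup_guard, t * dt);
  }

  List out = List::create(
    _["r"] = r_series,
    _["t0"] = transient_steps * dt,
    _["dt"] = dt,
    _["z_final_re"] = NumericVector(zre.begin(), zre.end()),
    _["z_final_im"] = NumericVector(zim.begin(), zim.end()));
  if (record_states) {
    out["states_re"] = st_re;
    out["states_im"] = st_im;
    out["keep_every"] = keep_every;
  }
  return out;
}
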