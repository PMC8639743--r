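#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// SplitMix64: small, fast, well-mixed 64-bit stream. Each point gets its own
// stream keyed by (master seed, point index), so results do not depend on the
// order in which points are evaluated and runs are reproducible across
// platforms (no dependence on std::uniform_int_distribution internals).
struct SplitMix64 {
  uint64_t state;
  explicit SplitMix64(uint64_t seed) : state(seed) {}
  uint64_t next() {
    uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // unbiased integer in [0, bound): Lemire multiply-shift with rejection
  uint64_t below(uint64_t bound) {
    unsigned __int128 m = (unsigned __int128)next() * bound;
    uint64_t l = (uint64_t)m;
    if (l < bound) {
      uint64_t t = (-bound) % bound;
      while (l < t) {
        m = (unsigned __int128)next() * bound;
        l = (uint64_t)m;
      }
    }
    return (uint64_t)(m >> 64);
  }
};

// Conditional-permutation inference for the Local Moran statistic.
//
// z    : mean-centred values of the analyzed (non-neighborless) points
// nbrs : list of integer vectors, 1-based neighbor indices into z
// m2   : sum(z^2)/n, the second moment used to scale the statistic
// n_perm: number of conditional permutations per point
// seed : master seed (any non-negative integer)
//
// For each point i the observed value z[i] is held fixed and the |N(i)|
// neighbor slots are refilled by sampling without replacement from the other
// n-1 observed values; the pseudo p-value is one-sided in the tail matching
// the sign of the observed I_i, p = (R + 1) / (M + 1).
// [[Rcpp::export]]
List cond_perm_local_moran(NumericVector z, List nbrs, double m2,
                           int n_perm, double seed) {
  const int n = z.size();
  if (nbrs.size() != n) stop("z and neighbor list lengths differ");
  if (n_perm < 1) stop("n_perm must be >= 1");
  if (!(m2 > 0)) stop("m2 must be positive (zero-variance input?)");

  NumericVector I_obs(n), lag_obs(n), pval(n), perm_mean(n), perm_sd(n);
  const uint64_t master = (uint64_t)seed;
  std::vector<int> pool(n > 1 ? n - 1 : 0);

  for (int i = 0; i < n; ++i) {
    IntegerVector nb = nbrs[i];
    const int k = nb.size();
    if (k == 0) stop("point without neighbors passed to permutation engine");

    double s = 0.0;
    for (int t = 0; t < k; ++t) {
      int j = nb[t] - 1;
      if (j < 0 || j >= n || j == i) stop("invalid neighbor index");
      s += z[j];
    }
    const double lag = s / k;
    const double Ii = z[i] / m2 * lag;
    lag_obs[i] = lag;
    I_obs[i] = Ii;

    // candidate donors: every index but i
    int idx = 0;
    for (int j = 0; j < n; ++j) if (j != i) pool[idx++] = j;

    SplitMix64 rng(master + (uint64_t)(i + 1) * 0x9E3779B97F4A7C15ULL);
    // I_perm = factor * sum(z over drawn donors), factor = z_i / (m2 * k),
    // so extremeness can be decided on the donor sum alone
    const double factor = z[i] / (m2 * (double)k);
    const double s_obs = s;
    const bool upper = (Ii >= 0.0);
    long extreme = 0;
    double acc = 0.0, acc2 = 0.0;
    const int npool = n - 1;

    for (int m = 0; m < n_perm; ++m) {
      // partial Fisher-Yates draw of k donors without replacement; the pool
      // stays shuffled between permutations, which preserves uniformity
      double sp = 0.0;
      for (int t = 0; t < k; ++t) {
        int r = t + (int)rng.below((uint64_t)(npool - t));
        int tmp = pool[t]; pool[t] = pool[r]; pool[r] = tmp;
        sp += z[pool[t]];
      }
      acc += sp;
      acc2 += sp * sp;
      if (factor == 0.0) { ++extreme; continue; }  // I_perm == I_obs == 0
      bool ext;
      if (factor > 0.0) ext = upper ? (sp >= s_obs) : (sp <= s_obs);
      else              ext = upper ? (sp <= s_obs) : (sp >= s_obs);
      if (ext) ++extreme;
    }

    pval[i] = (double)(extreme + 1) / (double)(n_perm + 1);
    const double mu = acc / n_perm;
    perm_mean[i] = factor * mu;
    double var = acc2 / n_perm - mu * mu;
    perm_sd[i] = var > 0 ? std::fabs(factor) * std::sqrt(var) : 0.0;
  }

  return List::create(_["I"] = I_obs, _["lag"] = lag_obs, _["pseudo_p"] = pval,
                      _["perm_mean"] = perm_mean, _["perm_sd"] = perm_sd);
}
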