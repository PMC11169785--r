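#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// xoshiro256++ with splitmix64 seeding: a fast, seedable stream for the
// bulk Gaussian draws of the synthetic generator (independent of R's RNG).
static inline uint64_t splitmix64(uint64_t& s) {
  uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(seed);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

// n standard normal draws (Marsaglia polar method) from the stream keyed
// by `seed`.
// [[Rcpp::export]]
NumericVector cpp_randn(int n, double seed) {
  Xoshiro rng(static_cast<uint64_t>(seed));
  NumericVector out(n);
  int i = 0;
  while (i < n) {
    double u, v, s;
    do {
      u = 2.0 * rng.unif() - 1.0;
      v = 2.0 * rng.unif() - 1.0;
      s = u * u + v * v;
    } while (s >= 1.0 || s == 0.0);
    double r = std::sqrt(-2.0 * std::log(s) / s);
    out[i++] = u * r;
    if (i < n) out[i++] = v * r;
  }
  return out;
}
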