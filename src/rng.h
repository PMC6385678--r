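#ifndef WEPATH_RNG_H
#define WEPATH_RNG_H

#include <cmath>
#include <cstdint>

// Deterministic counter-style RNG: a splitmix64 stream keyed by
// (global seed, walker id, iteration).  Replicated walkers receive fresh
// ids at resampling, so sibling trajectories decorrelate immediately after
// a split, and propagation is bitwise reproducible independent of call
// order and of R's global RNG state.
static inline uint64_t wep_sm_next(uint64_t& s) {
  s += 0x9E3779B97F4A7C15ULL;
  uint64_t z = s;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct WepRng {
  uint64_t s;
  bool have;
  double g;
  WepRng(double seed, int wid, int iter) {
    uint64_t t = (uint64_t)(int64_t)seed;
    t ^= 0x8f1bbcdcbfa53e0bULL;
    wep_sm_next(t);
    t += (uint64_t)(int64_t)wid * 0xD1B54A32D192ED03ULL;
    wep_sm_next(t);
    t += (uint64_t)(int64_t)iter * 0xA0761D6478BD642FULL;
    s = wep_sm_next(t);
    have = false;
    g = 0.0;
  }
  double unif() {
    uint64_t z = wep_sm_next(s);
    return ((z >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double norm() {
    if (have) { have = false; return g; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double th = 6.283185307179586476925287 * u2;
    g = r * std::sin(th);
    have = true;
    return r * std::cos(th);
  }
};

#endif
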