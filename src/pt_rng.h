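#ifndef PT_RNG_H
#define PT_RNG_H

#include <cstdint>

// Splittable counter-seeded generator: each photon packet gets an
// independent xoshiro256++ stream derived from (run seed, packet index)
// through splitmix64, so results are reproducible under any scheduling.

namespace pt {

inline uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

class Rng {
  uint64_t s[4];
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

public:
  Rng(uint64_t seed, uint64_t stream) {
    uint64_t x = seed ^ (stream * 0xD2B74407B1CE6E93ULL + 0x8E9C4D1F0AF7B2A5ULL);
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
    if (!(s[0] | s[1] | s[2] | s[3])) s[0] = 1;
  }

  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform deviate in [0, 1)
  inline double u01() { return (next() >> 11) * 0x1.0p-53; }
};

} // namespace pt

#endif
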