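// Event-level simulator for the stochastic E/I integrate-and-fire network.
//
// All randomness comes from a private PCG32 stream derived from
// (master seed, stream index), so rasters are reproducible bit-for-bit
// and independent of R's global RNG state.

#include <Rcpp.h>
#include <cstdint>
#include <vector>

using namespace Rcpp;

static inline uint64_t splitmix64(uint64_t& x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Pcg32 {
  uint64_t state;
  uint64_t inc;
  Pcg32(uint64_t seed, uint64_t seq) {
    state = 0U;
    inc = (seq << 1u) | 1u;
    nextInt();
    state += seed;
    nextInt();
  }
  inline uint32_t nextInt() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31u));
  }
  // uniform double in [0, 1)
  inline double unif() { return nextInt() * 2.3283064365386963e-10; }
  // uniform integer in [0, n), n <= 2^31; negligible modulo bias avoided
  // by the multiply-shift trick
  inline int unifInt(int n) {
    return (int)(((uint64_t)nextInt() * (uint64_t)n) >> 32);
  }
};

static inline Pcg32 makeStream(double masterSeed, double streamIndex) {
  uint64_t x = (uint64_t)(int64_t)masterSeed;
  x = x * 0x9E3779B97F4A7C15ULL + (uint64_t)(int64_t)streamIndex;
  uint64_t seed = splitmix64(x);
  uint64_t seq = splitmix64(x);
  return Pcg32(seed, seq);
}

// piecewise-linear sigmoid firing probability
static inline double phi(double V, double theta, double Gamma) {
  double p = (V - theta) * Gamma;
  if (p < 0.0) return 0.0;
  if (p > 1.0) return 1.0;
  return p;
}

// [[Rcpp::export(name = ".simulate_network_cpp")]]
List simulate_network_cpp(int N, int NE, double J, double W, double mu,
                          double theta, double Gamma, double Iext,
                          int tTotal, int tTransient, double initProb,
                          double masterSeed, double streamIndex) {
  Pcg32 rng = makeStream(masterSeed, streamIndex);

  std::vector<double> V(N, 0.0);
  std::vector<uint8_t> X(N, 0);

  std::vector<int> evNeuron, evTime, driveTimes;
  int Trec = tTotal - tTransient;
  std::vector<int> activity(Trec > 0 ? Trec : 0, 0);
  evNeuron.reserve(1 << 16);
  evTime.reserve(1 << 16);

  // initial condition at t = 0: V = 0, each neuron active independently
  int nSpk = 0, nE = 0;
  for (int i = 0; i < N; ++i) {
    if (rng.unif() < initProb) {
      X[i] = 1;
      ++nSpk;
      if (i < NE) ++nE;
    }
  }
  auto record = [&](int t) {
    if (t < tTransient) return;
    int tr = t - tTransient;
    activity[tr] = nSpk;
    for (int i = 0; i < N; ++i)
      if (X[i]) {
        evNeuron.push_back(i + 1);
        evTime.push_back(tr);
      }
  };
  auto drive = [&](int t) {
    if (nSpk == 0) {
      int k = rng.unifInt(N);
      X[k] = 1;
      nSpk = 1;
      if (k < NE) nE = 1;
      if (t >= tTransient) driveTimes.push_back(t - tTransient);
    }
  };
  drive(0);
  record(0);

  double invN = 1.0 / (double)N;
  for (int t = 1; t < tTotal; ++t) {
    // recurrent field is identical for all neurons (homogeneous weights)
    double rec = Iext + invN * (J * (double)nE - W * (double)(nSpk - nE));
    int newSpk = 0, newE = 0;
    for (int i = 0; i < N; ++i) {
      double v = X[i] ? 0.0 : mu * V[i] + rec;
      V[i] = v;
      double p = phi(v, theta, Gamma);
      uint8_t x = (p > 0.0) && (rng.unif() < p);
      X[i] = x;
      if (x) {
        ++newSpk;
        if (i < NE) ++newE;
      }
    }
    nSpk = newSpk;
    nE = newE;
    drive(t);
    record(t);
  }

  return List::create(_["neuron"] = wrap(evNeuron), _["time"] = wrap(evTime),
                      _["driveTimes"] = wrap(driveTimes),
                      _["activity"] = wrap(activity));
}
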