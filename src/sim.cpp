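#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// Self-contained PCG32 generator so that simulated traces are reproducible
// bit-for-bit from the configuration seed alone, independently of R's RNG
// stream (O'Neill's PCG-XSH-RR 64/32, public-domain reference algorithm).
struct Pcg32 {
  uint64_t state, inc;
  Pcg32(uint64_t seed, uint64_t seq = 54u) {
    state = 0u;
    inc = (seq << 1u) | 1u;
    nextU32();
    state += seed;
    nextU32();
  }
  uint32_t nextU32() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31));
  }
  // uniform in (0,1)
  double unif() { return (nextU32() + 0.5) * (1.0 / 4294967296.0); }

  bool haveSpare = false;
  double spare = 0.0;
  double norm() {  // Marsaglia polar method with cached spare
    if (haveSpare) { haveSpare = false; return spare; }
    double u, v, s;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s = u * u + v * v;
    } while (s >= 1.0 || s == 0.0);
    double f = std::sqrt(-2.0 * std::log(s) / s);
    spare = v * f;
    haveSpare = true;
    return u * f;
  }
  int poisson(double lambda) {  // Knuth; bin means here are O(1)
    double L = std::exp(-lambda), p = 1.0;
    int k = 0;
    do { ++k; p *= unif(); } while (p > L);
    return k - 1;
  }
};

enum State { FREE = 0, SHORT = 1, LONG = 2 };

// [[Rcpp::export(name = ".simulateFcsCpp")]]
List simulateFcsCpp(int nParticles, double boxSize, double dFree,
                    double wXY, double wZ, double brightness,
                    double rateHz, double durationS,
                    double konS, double koffS, double konL, double koffL,
                    int seed, int nSub) {
  const long nBins = (long)std::llround(rateHz * durationS);
  const double dt = 1.0 / rateHz;
  const double dtSub = dt / nSub;
  const double sigma = std::sqrt(2.0 * dFree * dtSub);
  const double half = boxSize / 2.0;
  const double iw2 = 2.0 / (wXY * wXY);
  const double iz2 = 2.0 / (wZ * wZ);
  const double meanScale = brightness * dt;

  const double kOn = konS + konL;
  const double pBind = (kOn > 0) ? 1.0 - std::exp(-kOn * dtSub) : 0.0;
  const double pShortGiven = (kOn > 0) ? konS / kOn : 0.0;
  const double pOffS = (koffS > 0) ? 1.0 - std::exp(-koffS * dtSub) : 0.0;
  const double pOffL = (koffL > 0) ? 1.0 - std::exp(-koffL * dtSub) : 0.0;

  Pcg32 rng((uint64_t)seed);

  // equilibrium state probabilities of the 3-state chain for the start
  double wS = (koffS > 0) ? konS / koffS : 0.0;
  double wL = (koffL > 0) ? konL / koffL : 0.0;
  double Z = 1.0 + wS + wL;
  double pS0 = wS / Z, pL0 = wL / Z;

  std::vector<double> x(nParticles), y(nParticles), z(nParticles);
  std::vector<int> st(nParticles);
  for (int i = 0; i < nParticles; ++i) {
    x[i] = rng.unif() * boxSize;
    y[i] = rng.unif() * boxSize;
    z[i] = rng.unif() * boxSize;
    double u = rng.unif();
    st[i] = (u < pS0) ? SHORT : (u < pS0 + pL0 ? LONG : FREE);
  }

  IntegerVector countsOut((R_xlen_t)nBins);
  double occ[3] = {0.0, 0.0, 0.0};

  for (long b = 0; b < nBins; ++b) {
    for (int sub = 0; sub < nSub; ++sub) {
      for (int i = 0; i < nParticles; ++i) {
        if (st[i] == FREE) {
          x[i] += sigma * rng.norm();
          y[i] += sigma * rng.norm();
          z[i] += sigma * rng.norm();
          // periodic wrap
          if (x[i] < 0) x[i] += boxSize; else if (x[i] >= boxSize) x[i] -= boxSize;
          if (y[i] < 0) y[i] += boxSize; else if (y[i] >= boxSize) y[i] -= boxSize;
          if (z[i] < 0) z[i] += boxSize; else if (z[i] >= boxSize) z[i] -= boxSize;
          if (pBind > 0) {
            double u = rng.unif();
            if (u < pBind)
              st[i] = (u < pBind * pShortGiven) ? SHORT : LONG;
          }
        } else if (st[i] == SHORT) {
          if (pOffS > 0 && rng.unif() < pOffS) st[i] = FREE;
        } else {
          if (pOffL > 0 && rng.unif() < pOffL) st[i] = FREE;
        }
      }
    }
    // expected count for this bin from the Gaussian observation volume
    double inten = 0.0;
    for (int i = 0; i < nParticles; ++i) {
      occ[st[i]] += 1.0;
      double dx = x[i] - half, dy = y[i] - half, dz = z[i] - half;
      double e = iw2 * (dx * dx + dy * dy) + iz2 * dz * dz;
      if (e < 18.0) inten += std::exp(-e);  // exp(-18) ~ 1.5e-8: negligible
    }
    countsOut[b] = rng.poisson(meanScale * inten);
  }

  double tot = occ[0] + occ[1] + occ[2];
  NumericVector occupancy = NumericVector::create(
      _["free"] = occ[0] / tot, _["short"] = occ[1] / tot,
      _["long"] = occ[2] / tot);
  return List::create(_["counts"] = countsOut, _["occupancy"] = occupancy);
}

// 8-connected component labeling of a logical mask (column-major matrix).
// [[Rcpp::export(name = ".label8Cpp")]]
IntegerMatrix label8Cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<long> stack;
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      stack.push_back((long)j * nr + i);
      lab(i, j) = next;
      while (!stack.empty()) {
        long p = stack.back(); stack.pop_back();
        int pi = (int)(p % nr), pj = (int)(p / nr);
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj) continue;
            int qi = pi + di, qj = pj + dj;
            if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
            if (mask(qi, qj) && !lab(qi, qj)) {
              lab(qi, qj) = next;
              stack.push_back((long)qj * nr + qi);
            }
          }
        }
      }
    }
  }
  return lab;
}
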