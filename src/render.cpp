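// Pixel-level inner loops: forward rendering of camera counts and block
// binning. Kept in C++ because a trial is ~18M pixel-frames and the
// generator is run hundreds of times in recovery experiments.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

// Deterministic, portable Gaussian draws: xoshiro256++ (Blackman & Vigna,
// public domain) + Box-Muller. The distribution adapters in <random> are not
// implementation-stable, and the generator seed must fully determine the
// rendered stacks bit-for-bit across platforms.
struct GaussGen {
  uint64_t s[4];
  bool have_spare = false;
  double spare = 0.0;
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  explicit GaussGen(uint64_t seed) {
    // splitmix64 seeding, as recommended for xoshiro
    for (int i = 0; i < 4; ++i) {
      seed += 0x9e3779b97f4a7c15ULL;
      uint64_t z = seed;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  double operator()() {
    if (have_spare) { have_spare = false; return spare; }
    double u1, u2;
    do {
      u1 = (next() >> 11) * (1.0 / 9007199254740992.0);  // [0,1)
    } while (u1 <= 0.0);
    u2 = (next() >> 11) * (1.0 / 9007199254740992.0);
    double r = std::sqrt(-2.0 * std::log(u1));
    double th = 6.283185307179586476925286766559 * u2;
    spare = r * std::sin(th);
    have_spare = true;
    return r * std::cos(th);
  }
};

// lut: (n_levels x n_frames) noiseless counts per render level and frame;
// level: 0-based level index per pixel; returns (npix x n_frames) counts
// with Gaussian noise, rounded, clipped to [0, max_count].
// [[Rcpp::export]]
NumericMatrix render_counts_cpp(const NumericMatrix& lut,
                                const IntegerVector& level,
                                double noise_sd, double max_count,
                                double seed) {
  const int npix = level.size();
  const int nt = lut.ncol();
  const int nlev = lut.nrow();
  NumericMatrix out(npix, nt);
  GaussGen g(static_cast<uint64_t>(seed));
  const bool noisy = noise_sd > 0;
  for (int t = 0; t < nt; ++t) {
    const double* col = &lut(0, t);
    double* o = &out(0, t);
    for (int p = 0; p < npix; ++p) {
      int lv = level[p];
      if (lv < 0 || lv >= nlev) stop("level index out of range");
      double v = col[lv];
      if (noisy) v += noise_sd * g();
      v = std::nearbyint(v);
      if (v < 0) v = 0;
      else if (v > max_count) v = max_count;
      o[p] = v;
    }
  }
  return out;
}

// Block-average binning of a [h x w x nt] stack by `factor` (h, w divisible
// by factor). Each output pixel is the arithmetic mean of its block.
// [[Rcpp::export]]
NumericVector bin_stack_cpp(const NumericVector& stack, int h, int w, int nt,
                            int factor) {
  const int h2 = h / factor, w2 = w / factor;
  NumericVector out(static_cast<R_xlen_t>(h2) * w2 * nt);
  const double inv = 1.0 / (factor * factor);
  const double* in = stack.begin();
  double* o = out.begin();
  for (int t = 0; t < nt; ++t) {
    const double* f = in + static_cast<R_xlen_t>(t) * h * w;
    double* g = o + static_cast<R_xlen_t>(t) * h2 * w2;
    for (int c = 0; c < w; ++c) {
      const double* colp = f + static_cast<R_xlen_t>(c) * h;
      double* gcol = g + static_cast<R_xlen_t>(c / factor) * h2;
      for (int r = 0; r < h; ++r) {
        gcol[r / factor] += colp[r];
      }
    }
    for (int k = 0; k < h2 * w2; ++k) g[k] *= inv;
  }
  out.attr("dim") = IntegerVector::create(h2, w2, nt);
  return out;
}

// Add Gaussian noise to a stack and clip to [0, max_count] in one pass.
// [[Rcpp::export]]
NumericVector noise_clip_cpp(NumericVector stack, double noise_sd,
                             double max_count, double seed) {
  NumericVector out = clone(stack);
  GaussGen g(static_cast<uint64_t>(seed));
  const R_xlen_t n = out.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    double v = out[i];
    if (noise_sd > 0) v += noise_sd * g();
    v = std::nearbyint(v);
    if (v < 0) v = 0;
    else if (v > max_count) v = max_count;
    out[i] = v;
  }
  return out;
}

// 3x3 median filter with edge replication.
// [[Rcpp::export]]
NumericMatrix median3x3_cpp(const NumericMatrix& m) {
  const int h = m.nrow(), w = m.ncol();
  NumericMatrix out(h, w);
  double nb[9];
  for (int c = 0; c < w; ++c) {
    for (int r = 0; r < h; ++r) {
      int k = 0;
      for (int dc = -1; dc <= 1; ++dc) {
        int cc = std::min(std::max(c + dc, 0), w - 1);
        for (int dr = -1; dr <= 1; ++dr) {
          int rr = std::min(std::max(r + dr, 0), h - 1);
          nb[k++] = m(rr, cc);
        }
      }
      std::nth_element(nb, nb + 4, nb + 9);
      out(r, c) = nb[4];
    }
  }
  return out;
}
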