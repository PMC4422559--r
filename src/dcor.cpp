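#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <string>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Deterministic, platform-stable RNG for noise injection.
//
// Streams are keyed by (global seed, variant, condition, metabolite id,
// transcript id) via FNV-1a string hashing combined with splitmix64, so the
// draws for a given pair do not depend on row order in the input files.
// Normals come from a hand-rolled Box-Muller transform: std::normal_distribution
// is implementation-defined and would break cross-platform reproducibility.
// ---------------------------------------------------------------------------

static inline uint64_t splitmix64(uint64_t &state) {
  uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline uint64_t fnv1a(const char *s, uint64_t h) {
  while (*s) {
    h ^= (uint64_t)(unsigned char)(*s++);
    h *= 0x100000001B3ULL;
  }
  return h;
}

struct NoiseRng {
  uint64_t state;
  bool have_spare;
  double spare;

  explicit NoiseRng(uint64_t seed) : state(seed), have_spare(false), spare(0.0) {}

  double unif() {
    // 53-bit mantissa uniform in (0, 1)
    uint64_t x = splitmix64(state);
    return ((x >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }

  double normal() {
    if (have_spare) {
      have_spare = false;
      return spare;
    }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double th = 6.283185307179586476925286766559 * u2;
    spare = r * std::sin(th);
    have_spare = true;
    return r * std::cos(th);
  }
};

static uint64_t key_hash(double seed, const std::vector<std::string> &keys) {
  uint64_t h = 0xCBF29CE484222325ULL;
  // fold the numeric seed in through its integer value
  uint64_t s = (uint64_t)(int64_t)seed;
  uint64_t st = s ^ 0x9E3779B97F4A7C15ULL;
  h ^= splitmix64(st);
  h *= 0x100000001B3ULL;
  for (size_t i = 0; i < keys.size(); ++i) {
    h = fnv1a(keys[i].c_str(), h);
    h = fnv1a("\x1f", h); // separator so ("ab","c") != ("a","bc")
  }
  return h;
}

// ---------------------------------------------------------------------------
// Sample distance correlation (Szekely), double-centering form.
// x, y: n samples of dimension dx, dy (row-major: sample i at x + i*dx).
// Returns 0 when either side has zero distance variance.
// ---------------------------------------------------------------------------

static double dcor_core(const double *x, const double *y, int n, int dx, int dy,
                        std::vector<double> &A, std::vector<double> &B,
                        std::vector<double> &rm) {
  A.assign((size_t)n * n, 0.0);
  B.assign((size_t)n * n, 0.0);
  rm.assign(2 * (size_t)n, 0.0);

  // pairwise Euclidean distances
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      for (int k = 0; k < dx; ++k) {
        double d = x[(size_t)i * dx + k] - x[(size_t)j * dx + k];
        s += d * d;
      }
      double d1 = std::sqrt(s);
      A[(size_t)i * n + j] = d1;
      A[(size_t)j * n + i] = d1;
      s = 0.0;
      for (int k = 0; k < dy; ++k) {
        double d = y[(size_t)i * dy + k] - y[(size_t)j * dy + k];
        s += d * d;
      }
      double d2 = std::sqrt(s);
      B[(size_t)i * n + j] = d2;
      B[(size_t)j * n + i] = d2;
    }
  }

  double *rma = rm.data();
  double *rmb = rm.data() + n;
  double ga = 0.0, gb = 0.0;
  for (int i = 0; i < n; ++i) {
    double sa = 0.0, sb = 0.0;
    for (int j = 0; j < n; ++j) {
      sa += A[(size_t)i * n + j];
      sb += B[(size_t)i * n + j];
    }
    rma[i] = sa / n;
    rmb[i] = sb / n;
    ga += sa;
    gb += sb;
  }
  ga /= (double)n * n;
  gb /= (double)n * n;

  double vxy = 0.0, vxx = 0.0, vyy = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double a = A[(size_t)i * n + j] - rma[i] - rma[j] + ga;
      double b = B[(size_t)i * n + j] - rmb[i] - rmb[j] + gb;
      vxy += a * b;
      vxx += a * a;
      vyy += b * b;
    }
  }
  double n2 = (double)n * n;
  vxy /= n2; vxx /= n2; vyy /= n2;
  if (vxx <= 0.0 || vyy <= 0.0) return 0.0;
  if (vxy <= 0.0) return 0.0;
  return std::sqrt(vxy / std::sqrt(vxx * vyy));
}

// [[Rcpp::export]]
double dcor_cpp(NumericMatrix x, NumericMatrix y) {
  int n = x.nrow();
  if (y.nrow() != n) stop("x and y must have the same number of samples");
  if (n < 2) stop("need at least 2 paired samples");
  int dx = x.ncol(), dy = y.ncol();
  // to row-major
  std::vector<double> xr((size_t)n * dx), yr((size_t)n * dy);
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < dx; ++k) xr[(size_t)i * dx + k] = x(i, k);
    for (int k = 0; k < dy; ++k) yr[(size_t)i * dy + k] = y(i, k);
  }
  std::vector<double> A, B, rm;
  return dcor_core(xr.data(), yr.data(), n, dx, dy, A, B, rm);
}

// [[Rcpp::export]]
NumericVector noise_inject_cpp(NumericVector values, double cv, double seed,
                               CharacterVector keys) {
  std::vector<std::string> ks;
  for (int i = 0; i < keys.size(); ++i) ks.push_back(as<std::string>(keys[i]));
  NoiseRng rng(key_hash(seed, ks));
  NumericVector out(values.size());
  for (int i = 0; i < values.size(); ++i) {
    double v = values[i];
    out[i] = v + cv * std::fabs(v) * rng.normal();
  }
  return out;
}

// ---------------------------------------------------------------------------
// Delayed dynamic dependence for all metabolite x transcript pairs.
//
// met_avg : n_met x 11 replicate-averaged metabolite samples (minutes 0..10)
// met_rep : n_met x (R*11) per-replicate samples, replicate-major blocks
// trd     : n_tr x 25 transcript-derivative samples (minutes 0..24)
// pairing : 0 = average, 1 = concat_replicates, 2 = replicates_3d
// Returns dd_max (n_met x n_tr), argmax delay in minutes, and optionally the
// full n_met x n_tr x 11 delay profile.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List dd_matrix_cpp(NumericMatrix met_avg, NumericMatrix met_rep, int n_rep,
                   NumericMatrix trd, CharacterVector met_ids,
                   CharacterVector tr_ids, int pairing, double cv, double seed,
                   std::string variant_key, std::string cond_key,
                   bool return_delays = false) {
  const int n_met = met_avg.nrow();
  const int n_tr = trd.nrow();
  const int n_delay = 11;
  const int W = 11; // window length in samples
  if (met_avg.ncol() != W) stop("metabolite grid must have 11 samples (0..10 min)");
  if (trd.ncol() != 25) stop("transcript-derivative grid must have 25 samples (0..24 min)");
  if (pairing == 2 && n_rep < 2) stop("replicates_3d needs at least 2 replicates");
  if (met_rep.ncol() != n_rep * W) stop("met_rep must be n_met x (R*11)");

  NumericMatrix dd_max(n_met, n_tr);
  IntegerMatrix argmax(n_met, n_tr);
  NumericVector delays;
  if (return_delays) delays = NumericVector((R_xlen_t)n_met * n_tr * n_delay);

  // sample count and dimension per pairing
  int n, dx, dy;
  if (pairing == 0) { n = W; dx = 1; dy = 1; }
  else if (pairing == 1) { n = W * n_rep; dx = 1; dy = 1; }
  else { n = W; dx = n_rep; dy = n_rep; }

  std::vector<double> xs((size_t)n * dx), ys((size_t)n * dy);
  std::vector<double> A, B, rm;
  A.reserve((size_t)n * n);
  B.reserve((size_t)n * n);

  for (int i = 0; i < n_met; ++i) {
    std::string mid = as<std::string>(met_ids[i]);
    for (int j = 0; j < n_tr; ++j) {
      std::vector<std::string> ks;
      ks.push_back(variant_key);
      ks.push_back(cond_key);
      ks.push_back(mid);
      ks.push_back(as<std::string>(tr_ids[j]));
      NoiseRng rng(key_hash(seed, ks));

      double best = -1.0;
      int best_d = 0;
      for (int d = 0; d < n_delay; ++d) {
        // metabolite side
        if (pairing == 0) {
          for (int t = 0; t < W; ++t) {
            double v = met_avg(i, t);
            xs[t] = v + cv * std::fabs(v) * rng.normal();
          }
        } else if (pairing == 1) {
          for (int r = 0; r < n_rep; ++r)
            for (int t = 0; t < W; ++t) {
              double v = met_rep(i, r * W + t);
              xs[(size_t)r * W + t] = v + cv * std::fabs(v) * rng.normal();
            }
        } else {
          for (int t = 0; t < W; ++t)
            for (int r = 0; r < n_rep; ++r) {
              double v = met_rep(i, r * W + t);
              xs[(size_t)t * n_rep + r] = v + cv * std::fabs(v) * rng.normal();
            }
        }
        // transcript-derivative window [d, d+10], tiled across replicates
        if (pairing == 0) {
          for (int t = 0; t < W; ++t) {
            double v = trd(j, d + t);
            ys[t] = v + cv * std::fabs(v) * rng.normal();
          }
        } else if (pairing == 1) {
          for (int r = 0; r < n_rep; ++r)
            for (int t = 0; t < W; ++t) {
              double v = trd(j, d + t);
              ys[(size_t)r * W + t] = v + cv * std::fabs(v) * rng.normal();
            }
        } else {
          for (int t = 0; t < W; ++t)
            for (int r = 0; r < n_rep; ++r) {
              double v = trd(j, d + t);
              ys[(size_t)t * n_rep + r] = v + cv * std::fabs(v) * rng.normal();
            }
        }
        double dc = dcor_core(xs.data(), ys.data(), n, dx, dy, A, B, rm);
        if (return_delays)
          delays[((R_xlen_t)i * n_tr + j) * n_delay + d] = dc;
        if (dc > best) { best = dc; best_d = d; }
      }
      dd_max(i, j) = best;
      argmax(i, j) = best_d;
    }
    if (i % 16 == 0) Rcpp::checkUserInterrupt();
  }

  List out = List::create(_["dd_max"] = dd_max, _["argmax"] = argmax);
  if (return_delays) {
    delays.attr("dim") = IntegerVector::create(n_delay, n_tr, n_met);
    out["dd_by_delay"] = delays;
  }
  return out;
}
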