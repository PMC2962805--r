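#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <cstddef>

using namespace Rcpp;

// XOR + population count over two bit-plane ranges; the hot loop of the
// IBS kernel. Hardware POPCNT is used when the CPU has it (runtime
// dispatch); the portable fallback is a SWAR bit-count.
static inline uint64_t popcnt_swar(uint64_t x) {
  x = x - ((x >> 1) & 0x5555555555555555ULL);
  x = (x & 0x3333333333333333ULL) + ((x >> 2) & 0x3333333333333333ULL);
  x = (x + (x >> 4)) & 0x0f0f0f0f0f0f0f0fULL;
  return (x * 0x0101010101010101ULL) >> 56;
}

static long xor_popcnt_generic(const uint64_t *a, const uint64_t *b,
                               const uint64_t *c, const uint64_t *d,
                               int W) {
  uint64_t s = 0;
  for (int w = 0; w < W; ++w)
    s += popcnt_swar(a[w] ^ b[w]) + popcnt_swar(c[w] ^ d[w]);
  return (long)s;
}

#if defined(__x86_64__) || defined(__i386__)
__attribute__((target("popcnt")))
static long xor_popcnt_hw(const uint64_t *a, const uint64_t *b,
                          const uint64_t *c, const uint64_t *d, int W) {
  uint64_t s = 0;
  for (int w = 0; w < W; ++w)
    s += (uint64_t)__builtin_popcountll(a[w] ^ b[w]) +
         (uint64_t)__builtin_popcountll(c[w] ^ d[w]);
  return (long)s;
}

static long (*resolve_xor_popcnt())(const uint64_t *, const uint64_t *,
                                    const uint64_t *, const uint64_t *,
                                    int) {
  __builtin_cpu_init();
  if (__builtin_cpu_supports("popcnt")) return xor_popcnt_hw;
  return xor_popcnt_generic;
}

static long (*const xor_popcnt)(const uint64_t *, const uint64_t *,
                                const uint64_t *, const uint64_t *, int) =
    resolve_xor_popcnt();
#else
static long (*const xor_popcnt)(const uint64_t *, const uint64_t *,
                                const uint64_t *, const uint64_t *, int) =
    xor_popcnt_generic;
#endif

// Sample HWE genotypes for blocks of samples with cohort-specific allele
// frequencies. freq is n_snps x n_cohorts; sizes gives samples per cohort.
// Returns sum(sizes) x n_snps dosage matrix, cohort blocks stacked in order.
// Uses R's RNG so results are reproducible from set.seed().
// [[Rcpp::export]]
NumericMatrix cpp_hwe_genotypes(NumericMatrix freq, IntegerVector sizes) {
  const int m = freq.nrow(), C = freq.ncol();
  int n = 0;
  for (int c = 0; c < C; ++c) n += sizes[c];
  NumericMatrix G(n, m);
  RNGScope scope;
  for (int j = 0; j < m; ++j) {
    double *col = &G(0, j);
    int row = 0;
    for (int c = 0; c < C; ++c) {
      const double p = freq(j, c);
      const double c1 = (1.0 - p) * (1.0 - p);
      const double c2 = c1 + 2.0 * p * (1.0 - p);
      for (int i = 0; i < sizes[c]; ++i, ++row) {
        const double u = unif_rand();
        col[row] = (u > c1) + (u > c2);
      }
    }
  }
  return G;
}

// Pairwise IBS for a complete (no missing) dosage matrix in {0,1,2}.
// Genotypes are packed into two bit planes per sample, A = (g >= 1) and
// B = (g == 2), so that for any pair
//   |g_i - g_j| = (A_i xor A_j) + (B_i xor B_j)
// holds bitwise at every SNP, and the allele-sharing distance is two
// XOR+popcount sweeps per pair. Exact integer arithmetic throughout.
// [[Rcpp::export]]
NumericMatrix cpp_ibs_complete(NumericMatrix G) {
  const int n = G.nrow(), m = G.ncol();
  const int W = (m + 63) / 64;
  std::vector<uint64_t> A((std::size_t)n * W, 0u), B((std::size_t)n * W, 0u);
  for (int j = 0; j < m; ++j) {
    const double *gcol = &G[(std::size_t)j * n];
    const std::size_t w = j >> 6;
    const uint64_t bit = 1ULL << (j & 63);
    for (int i = 0; i < n; ++i) {
      const double g = gcol[i];
      if (g != 0.0 && g != 1.0 && g != 2.0)
        stop("genotype entries must be 0, 1, 2 or NA");
      if (g >= 1.0) A[(std::size_t)i * W + w] |= bit;
      if (g == 2.0) B[(std::size_t)i * W + w] |= bit;
    }
  }
  NumericMatrix S(n, n);
  const double denom = 2.0 * m;
  for (int i = 0; i < n; ++i) {
    S(i, i) = 1.0;
    const uint64_t *Ai = &A[(std::size_t)i * W];
    const uint64_t *Bi = &B[(std::size_t)i * W];
    for (int j = i + 1; j < n; ++j) {
      const uint64_t *Aj = &A[(std::size_t)j * W];
      const uint64_t *Bj = &B[(std::size_t)j * W];
      const long dsum = xor_popcnt(Ai, Aj, Bi, Bj, W);
      const double ibs = 1.0 - (double)dsum / denom;
      S(i, j) = ibs;
      S(j, i) = ibs;
    }
  }
  return S;
}

// Pairwise IBS with per-pair exclusion of missing genotypes (NA). Returns
// the IBS matrix and the matrix of shared non-missing SNP counts N_ij.
// O(n^2 m); intended for real-data matrices, not the simulation loop.
// [[Rcpp::export]]
List cpp_ibs_missing(NumericMatrix G) {
  const int n = G.nrow(), m = G.ncol();
  NumericMatrix S(n, n);
  IntegerMatrix N(n, n);
  // -1 encodes missing
  std::vector<signed char> g((std::size_t)n * m);
  for (std::size_t idx = 0; idx < g.size(); ++idx) {
    const double v = G[idx];
    if (ISNAN(v)) {
      g[idx] = -1;
    } else {
      if (v != 0.0 && v != 1.0 && v != 2.0)
        stop("genotype entries must be 0, 1, 2 or NA");
      g[idx] = (signed char)v;
    }
  }
  for (int i = 0; i < n; ++i) {
    S(i, i) = 1.0;
    int ni = 0;
    for (int k = 0; k < m; ++k)
      if (g[(std::size_t)k * n + i] >= 0) ++ni;
    N(i, i) = ni;
    for (int j = 0; j < i; ++j) {
      long dsum = 0;
      int nij = 0;
      for (int k = 0; k < m; ++k) {
        const signed char a = g[(std::size_t)k * n + i];
        const signed char b = g[(std::size_t)k * n + j];
        if (a >= 0 && b >= 0) {
          ++nij;
          dsum += (a > b) ? a - b : b - a;
        }
      }
      N(i, j) = nij;
      N(j, i) = nij;
      const double ibs = (nij > 0) ? 1.0 - (double)dsum / (2.0 * nij) : NA_REAL;
      S(i, j) = ibs;
      S(j, i) = ibs;
    }
  }
  return List::create(_["ibs"] = S, _["pair_counts"] = N);
}
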