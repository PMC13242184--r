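#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Smallest integer t in [0, denom] with (double)t/denom >= theta, using the
// same floating-point comparison as the naive formulation so thresholding at
// exact rational boundaries (e.g. 4/5 >= 0.8) never disagrees with it.
static int min_matches(double theta, int denom) {
  if (denom <= 0) return 1; // unreachable similarity for an all-gap target
  int t = (int)std::ceil(theta * (double)denom) ;
  if (t > denom) t = denom;
  while (t > 0 && (double)(t - 1) / denom >= theta) --t;
  while (t <= denom && (double)t / denom < theta) ++t;
  return t; // may be denom + 1 only if even denom/denom < theta (impossible for theta <= 1)
}

// Per-sequence weights 1/n_i for the effective-sequence count.
// mat: N x L integer codes, gap = gap code, inclusive threshold theta.
// Symmetric: identity = matching codes (gap-gap included) / L.
// Asymmetric: identity into j = (codes equal & j non-gap) / (j's non-gap count);
// code equality implies both rows are non-gap, so one pass serves both directions.
// [[Rcpp::export]]
NumericVector neff_weights_cpp(IntegerMatrix mat, int gap, double theta,
                               bool symmetric) {
  const int n = mat.nrow(), L = mat.ncol();
  std::vector<int> m((size_t)n * L);          // row-major copy for cache locality
  for (int j = 0; j < L; ++j)
    for (int i = 0; i < n; ++i)
      m[(size_t)i * L + j] = mat(i, j);

  std::vector<int> nn(n, 1);
  if (symmetric) {
    const int tmin = min_matches(theta, L);
    const int allowed = L - tmin;             // mismatches tolerated
    for (int i = 0; i < n; ++i) {
      const int* a = &m[(size_t)i * L];
      for (int j = i + 1; j < n; ++j) {
        const int* b = &m[(size_t)j * L];
        int mm = 0, k = 0;
        for (; k < L; ++k)
          if (a[k] != b[k] && ++mm > allowed) break;  // early exit
        if (k == L) { ++nn[i]; ++nn[j]; }
      }
      if (i % 64 == 0) Rcpp::checkUserInterrupt();
    }
  } else {
    std::vector<int> nongap(n, 0), tmin(n, 0);
    for (int i = 0; i < n; ++i) {
      int c = 0;
      const int* a = &m[(size_t)i * L];
      for (int k = 0; k < L; ++k) if (a[k] != gap) ++c;
      nongap[i] = c;
      tmin[i] = min_matches(theta, c);
    }
    for (int i = 0; i < n; ++i) {
      const int* a = &m[(size_t)i * L];
      for (int j = i + 1; j < n; ++j) {
        const int* b = &m[(size_t)j * L];
        int match = 0;
        for (int k = 0; k < L; ++k)
          if (a[k] == b[k] && a[k] != gap) ++match;
        if (nongap[j] > 0 && match >= tmin[j]) ++nn[j]; // S(i->j) >= theta
        if (nongap[i] > 0 && match >= tmin[i]) ++nn[i]; // S(j->i) >= theta
      }
      if (i % 64 == 0) Rcpp::checkUserInterrupt();
    }
  }
  NumericVector w(n);
  for (int i = 0; i < n; ++i) w[i] = 1.0 / nn[i];
  return w;
}
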