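#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Multiresolution hash-grid positional encoding (instant-NGP style).
// Coordinates live in the unit cube; level l has `res[l]` cells per axis
// (res[l] + 1 vertices). A vertex is addressed densely when the full vertex
// grid fits in the table, otherwise by the xor-of-primes spatial hash.
// Each vertex stores F trainable features; the encoding of a point is the
// trilinear blend of its 8 corner features, concatenated across levels.

static inline uint32_t vertex_index(uint32_t i, uint32_t j, uint32_t k,
                                    uint32_t nvert, uint32_t tsize) {
  const uint64_t dense = (uint64_t)nvert * nvert * nvert;
  if (dense <= tsize) {
    return i + nvert * (j + nvert * k);
  }
  const uint32_t h = i ^ (j * 2654435761u) ^ (k * 805459861u);
  return h % tsize;
}

// [[Rcpp::export]]
NumericMatrix cpp_hash_encode(NumericMatrix coords, List tables,
                              IntegerVector res) {
  const int n = coords.nrow(), L = res.size();
  NumericMatrix table0 = tables[0];
  const int F = table0.ncol();
  NumericMatrix out(n, L * F);
  for (int l = 0; l < L; ++l) {
    NumericMatrix tab = tables[l];
    const uint32_t tsize = tab.nrow();
    const uint32_t r = res[l], nvert = r + 1;
    const double *tp = REAL(tab);
    for (int m = 0; m < n; ++m) {
      double p[3], fr[3];
      uint32_t i0[3];
      for (int a = 0; a < 3; ++a) {
        double c = coords(m, a);
        if (c < 0.0) c = 0.0; else if (c > 1.0) c = 1.0;
        p[a] = c * r;
        uint32_t ii = (uint32_t)p[a];
        if (ii >= r && r > 0) ii = r - 1;
        i0[a] = ii;
        fr[a] = p[a] - ii;
      }
      double acc[8];  // up to F accumulators (F small)
      for (int f = 0; f < F; ++f) acc[f] = 0.0;
      for (int dk = 0; dk < 2; ++dk)
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            const double w = (di ? fr[0] : 1 - fr[0]) *
                             (dj ? fr[1] : 1 - fr[1]) *
                             (dk ? fr[2] : 1 - fr[2]);
            const uint32_t idx = vertex_index(i0[0] + di, i0[1] + dj,
                                              i0[2] + dk, nvert, tsize);
            for (int f = 0; f < F; ++f)
              acc[f] += w * tp[idx + (size_t)tsize * f];
          }
      for (int f = 0; f < F; ++f) out(m, l * F + f) = acc[f];
    }
  }
  return out;
}

// Gradient of the encoding with respect to the table entries: scatter-add of
// upstream gradients times the trilinear weights. Returns one T x F matrix
// per level.
// [[Rcpp::export]]
List cpp_hash_encode_grad(NumericMatrix coords, NumericMatrix gradout,
                          IntegerVector res, IntegerVector tsizes, int F) {
  const int n = coords.nrow(), L = res.size();
  List grads(L);
  for (int l = 0; l < L; ++l) {
    const uint32_t tsize = tsizes[l];
    NumericMatrix g(tsize, F);
    double *gp = REAL(g);
    const uint32_t r = res[l], nvert = r + 1;
    for (int m = 0; m < n; ++m) {
      double p[3], fr[3];
      uint32_t i0[3];
      for (int a = 0; a < 3; ++a) {
        double c = coords(m, a);
        if (c < 0.0) c = 0.0; else if (c > 1.0) c = 1.0;
        p[a] = c * r;
        uint32_t ii = (uint32_t)p[a];
        if (ii >= r && r > 0) ii = r - 1;
        i0[a] = ii;
        fr[a] = p[a] - ii;
      }
      for (int dk = 0; dk < 2; ++dk)
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            const double w = (di ? fr[0] : 1 - fr[0]) *
                             (dj ? fr[1] : 1 - fr[1]) *
                             (dk ? fr[2] : 1 - fr[2]);
            const uint32_t idx = vertex_index(i0[0] + di, i0[1] + dj,
                                              i0[2] + dk, nvert, tsize);
            for (int f = 0; f < F; ++f)
              gp[idx + (size_t)tsize * f] += w * gradout(m, l * F + f);
          }
    }
    grads[l] = g;
  }
  return grads;
}
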