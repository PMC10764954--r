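// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <cstdint>
using namespace Rcpp;

// Fused attenuation-field kernels. Training evaluates, per batch, the whole
// chain encoder -> MLP -> ray rendering -> squared-error loss -> gradients
// in one call, keeping every large intermediate inside C++ (single-precision
// internally; parameters and gradients cross the boundary in double). This
// is a performance fusion of the modular double-precision path
// (cpp_hash_encode / cpp_mlp_forward / cpp_mlp_backward), against which it
// is unit-tested.

static inline uint32_t vidx(uint32_t i, uint32_t j, uint32_t k,
                            uint32_t nvert, uint32_t tsize) {
  const uint64_t dense = (uint64_t)nvert * nvert * nvert;
  if (dense <= tsize) return i + nvert * (j + nvert * k);
  return (i ^ (j * 2654435761u) ^ (k * 805459861u)) % tsize;
}

// Encode coords (N x 3, unit cube) into fX (N x L*F), float. Optionally
// caches the 8 corner table indices and trilinear weights per (point, level)
// so the backward scatter can reuse them without re-hashing.
static void encode_f(const arma::mat &coords, const std::vector<arma::fmat> &tabs,
                     const IntegerVector &res, int F, arma::fmat &fX,
                     std::vector<uint32_t> *cidx = nullptr,
                     std::vector<float> *cw = nullptr) {
  const int n = coords.n_rows, L = res.size();
  if (cidx) { cidx->resize((size_t)n * L * 8); cw->resize((size_t)n * L * 8); }
  for (int l = 0; l < L; ++l) {
    const arma::fmat &tab = tabs[l];
    const uint32_t tsize = tab.n_rows;
    const uint32_t r = res[l], nvert = r + 1;
    for (int m = 0; m < n; ++m) {
      double p[3], fr[3]; uint32_t i0[3];
      for (int a = 0; a < 3; ++a) {
        double c = coords(m, a);
        if (c < 0) c = 0; else if (c > 1) c = 1;
        p[a] = c * r;
        uint32_t ii = (uint32_t)p[a];
        if (ii >= r && r > 0) ii = r - 1;
        i0[a] = ii; fr[a] = p[a] - ii;
      }
      float acc0 = 0.f, acc1 = 0.f;
      size_t cbase = cidx ? ((size_t)l * n + m) * 8 : 0;
      int corner = 0;
      for (int dk = 0; dk < 2; ++dk)
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di, ++corner) {
            const float w = (di ? fr[0] : 1 - fr[0]) *
                            (dj ? fr[1] : 1 - fr[1]) *
                            (dk ? fr[2] : 1 - fr[2]);
            const uint32_t idx = vidx(i0[0] + di, i0[1] + dj, i0[2] + dk,
                                      nvert, tsize);
            acc0 += w * tab(idx, 0);
            if (F > 1) acc1 += w * tab(idx, 1);
            if (cidx) { (*cidx)[cbase + corner] = idx; (*cw)[cbase + corner] = w; }
          }
      fX(m, l * F) = acc0;
      if (F > 1) fX(m, l * F + 1) = acc1;
    }
  }
}

static void relu_(arma::fmat &M) {
  M.transform([](float v) { return v > 0.f ? v : 0.f; });
}

struct MlpW {
  arma::fmat W1, W2, W3, W4;
  arma::frowvec b1, b2, b3;
  float b4;
};

static MlpW load_weights(const List &mlp) {
  MlpW w;
  w.W1 = arma::conv_to<arma::fmat>::from(as<arma::mat>(mlp["W1"]));
  w.W2 = arma::conv_to<arma::fmat>::from(as<arma::mat>(mlp["W2"]));
  w.W3 = arma::conv_to<arma::fmat>::from(as<arma::mat>(mlp["W3"]));
  w.W4 = arma::conv_to<arma::fmat>::from(as<arma::mat>(mlp["W4"]));
  w.b1 = arma::conv_to<arma::frowvec>::from(as<arma::rowvec>(mlp["b1"]));
  w.b2 = arma::conv_to<arma::frowvec>::from(as<arma::rowvec>(mlp["b2"]));
  w.b3 = arma::conv_to<arma::frowvec>::from(as<arma::rowvec>(mlp["b3"]));
  w.b4 = (float)as<double>(mlp["b4"]);
  return w;
}

static std::vector<arma::fmat> load_tables(const List &tables) {
  std::vector<arma::fmat> tabs(tables.size());
  for (int l = 0; l < tables.size(); ++l)
    tabs[l] = arma::conv_to<arma::fmat>::from(as<arma::mat>(tables[l]));
  return tabs;
}

// Forward-only fused inference: attenuation at N coordinates.
// [[Rcpp::export]]
NumericVector cpp_afn_infer(const arma::mat &coords, List tables,
                            IntegerVector res, int F, List mlp) {
  std::vector<arma::fmat> tabs = load_tables(tables);
  MlpW w = load_weights(mlp);
  const int n = coords.n_rows;
  arma::fmat X(n, (int)res.size() * F);
  encode_f(coords, tabs, res, F, X);
  arma::fmat H = X * w.W1; H.each_row() += w.b1; relu_(H);
  arma::fmat H2 = H * w.W2; H2.each_row() += w.b2; relu_(H2);
  arma::fmat H3 = H2 * w.W3; H3.each_row() += w.b3; relu_(H3);
  arma::fvec Z4 = H3 * w.W4 + w.b4;
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = std::exp(Z4[i] > 30.f ? 30.f : Z4[i]);
  return out;
}

// Fused training batch. coords: (n_rays*k) x 3 ordered ray-major within
// sample blocks (index = ray + n*(sample-1)); seg: n x k segment lengths in
// cm; p: n acquired line integrals. Returns the mean squared loss, rendered
// values, and gradients of every trainable tensor (loss = mean over rays).
// [[Rcpp::export]]
List cpp_afn_train_batch(const arma::mat &coords, List tables,
                         IntegerVector res, int F, List mlp,
                         const arma::mat &seg, const arma::vec &p,
                         double grad_clip) {
  std::vector<arma::fmat> tabs = load_tables(tables);
  MlpW w = load_weights(mlp);
  const int n = seg.n_rows, k = seg.n_cols;
  const int N = n * k, L = res.size();

  arma::fmat X(N, L * F);
  std::vector<uint32_t> cidx;
  std::vector<float> cwgt;
  encode_f(coords, tabs, res, F, X, &cidx, &cwgt);
  arma::fmat H1 = X * w.W1; H1.each_row() += w.b1; relu_(H1);
  arma::fmat H2 = H1 * w.W2; H2.each_row() += w.b2; relu_(H2);
  arma::fmat H3 = H2 * w.W3; H3.each_row() += w.b3; relu_(H3);
  arma::fvec Z4 = H3 * w.W4 + w.b4;
  arma::fvec h = Z4;
  h.transform([](float v) { return std::exp(v > 30.f ? 30.f : v); });

  // render: phat_j = sum_i h(j,i) seg(j,i)
  arma::vec phat(n, arma::fill::zeros);
  for (int i = 0; i < k; ++i)
    for (int j = 0; j < n; ++j)
      phat[j] += (double)h[j + (size_t)n * i] * seg(j, i);
  arma::vec resid = phat - p;
  double loss = arma::dot(resid, resid) / n;

  // dL/dh and clipped exponential derivative
  arma::fvec dZ4(N);
  for (int i = 0; i < k; ++i)
    for (int j = 0; j < n; ++j) {
      const size_t m = j + (size_t)n * i;
      double dh = 2.0 / n * resid[j] * seg(j, i);
      double e = std::exp(Z4[m] > 30.f ? 30.f : (double)Z4[m]);
      if (e > grad_clip) e = grad_clip;
      dZ4[m] = (float)(dh * e);
    }

  auto mask_relu = [](arma::fmat &dZ, const arma::fmat &H) {
    float *d = dZ.memptr();
    const float *hh = H.memptr();
    const size_t nn = dZ.n_elem;
    for (size_t i = 0; i < nn; ++i) if (hh[i] <= 0.f) d[i] = 0.f;
  };
  arma::fmat gW4 = H3.t() * dZ4;
  float gb4 = arma::accu(dZ4);
  arma::fmat dZ3 = dZ4 * w.W4.t();
  mask_relu(dZ3, H3);
  arma::fmat gW3 = H2.t() * dZ3;
  arma::frowvec gb3 = arma::sum(dZ3, 0);
  arma::fmat dZ2 = dZ3 * w.W3.t();
  mask_relu(dZ2, H2);
  arma::fmat gW2 = H1.t() * dZ2;
  arma::frowvec gb2 = arma::sum(dZ2, 0);
  arma::fmat dZ1 = dZ2 * w.W2.t();
  mask_relu(dZ1, H1);
  arma::fmat gW1 = X.t() * dZ1;
  arma::frowvec gb1 = arma::sum(dZ1, 0);
  arma::fmat dX = dZ1 * w.W1.t();

  // encoder gradient: scatter the cached trilinear weights times dX
  List gtab(L);
  for (int l = 0; l < L; ++l) {
    const uint32_t tsize = tabs[l].n_rows;
    arma::mat g(tsize, F, arma::fill::zeros);
    const float *d0col = dX.colptr(l * F);
    const float *d1col = F > 1 ? dX.colptr(l * F + 1) : nullptr;
    const size_t base = (size_t)l * N * 8;
    for (int m = 0; m < N; ++m) {
      const size_t cb = base + (size_t)m * 8;
      const float d0 = d0col[m];
      const float d1 = d1col ? d1col[m] : 0.f;
      for (int corner = 0; corner < 8; ++corner) {
        const uint32_t idx = cidx[cb + corner];
        const double wgt = cwgt[cb + corner];
        g(idx, 0) += wgt * d0;
        if (F > 1) g(idx, 1) += wgt * d1;
      }
    }
    gtab[l] = g;
  }

  return List::create(
    Named("loss") = loss, Named("phat") = phat, Named("tables") = gtab,
    Named("W1") = arma::conv_to<arma::mat>::from(gW1),
    Named("b1") = arma::conv_to<arma::rowvec>::from(gb1),
    Named("W2") = arma::conv_to<arma::mat>::from(gW2),
    Named("b2") = arma::conv_to<arma::rowvec>::from(gb2),
    Named("W3") = arma::conv_to<arma::mat>::from(gW3),
    Named("b3") = arma::conv_to<arma::rowvec>::from(gb3),
    Named("W4") = arma::conv_to<arma::mat>::from(gW4),
    Named("b4") = (double)gb4);
}
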