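// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Fused forward pass of the AFN head: three ReLU hidden layers of equal
// width and a linear output with exponential activation (clamped at exp(30)
// for numerical safety). Returns the attenuation vector and, if requested,
// the hidden activations needed for the backward pass.
// [[Rcpp::export]]
List cpp_mlp_forward(const arma::mat &X,
                     const arma::mat &W1, const arma::rowvec &b1,
                     const arma::mat &W2, const arma::rowvec &b2,
                     const arma::mat &W3, const arma::rowvec &b3,
                     const arma::mat &W4, const arma::rowvec &b4,
                     bool cache) {
  arma::mat H1 = X * W1; H1.each_row() += b1;
  H1.transform([](double v) { return v > 0.0 ? v : 0.0; });
  arma::mat H2 = H1 * W2; H2.each_row() += b2;
  H2.transform([](double v) { return v > 0.0 ? v : 0.0; });
  arma::mat H3 = H2 * W3; H3.each_row() += b3;
  H3.transform([](double v) { return v > 0.0 ? v : 0.0; });
  arma::vec Z4 = H3 * W4 + b4(0);
  arma::vec h = Z4;
  h.transform([](double v) { return std::exp(v > 30.0 ? 30.0 : v); });
  if (!cache) return List::create(Named("h") = h);
  return List::create(Named("h") = h, Named("H1") = H1, Named("H2") = H2,
                      Named("H3") = H3, Named("Z4") = Z4);
}

// Fused backward pass: dL/dh in, gradients of all weights/biases plus the
// gradient with respect to the encoder features X out. The derivative of the
// exponential output activation is clipped to `grad_clip`.
// [[Rcpp::export]]
List cpp_mlp_backward(const arma::mat &X, const arma::mat &H1,
                      const arma::mat &H2, const arma::mat &H3,
                      const arma::vec &Z4, const arma::vec &dh,
                      const arma::mat &W1, const arma::mat &W2,
                      const arma::mat &W3, const arma::mat &W4,
                      double grad_clip) {
  arma::vec dZ4 = Z4;
  dZ4.transform([grad_clip](double v) {
    double e = std::exp(v > 30.0 ? 30.0 : v);
    return e > grad_clip ? grad_clip : e;
  });
  dZ4 %= dh;
  arma::mat gW4 = H3.t() * dZ4;
  double gb4 = arma::accu(dZ4);
  arma::mat dZ3 = dZ4 * W4.t();
  dZ3 %= arma::conv_to<arma::mat>::from(H3 > 0.0);
  arma::mat gW3 = H2.t() * dZ3;
  arma::rowvec gb3 = arma::sum(dZ3, 0);
  arma::mat dZ2 = dZ3 * W3.t();
  dZ2 %= arma::conv_to<arma::mat>::from(H2 > 0.0);
  arma::mat gW2 = H1.t() * dZ2;
  arma::rowvec gb2 = arma::sum(dZ2, 0);
  arma::mat dZ1 = dZ2 * W2.t();
  dZ1 %= arma::conv_to<arma::mat>::from(H1 > 0.0);
  arma::mat gW1 = X.t() * dZ1;
  arma::rowvec gb1 = arma::sum(dZ1, 0);
  arma::mat dX = dZ1 * W1.t();
  return List::create(Named("W1") = gW1, Named("b1") = gb1,
                      Named("W2") = gW2, Named("b2") = gb2,
                      Named("W3") = gW3, Named("b3") = gb3,
                      Named("W4") = gW4, Named("b4") = gb4,
                      Named("dX") = dX);
}
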