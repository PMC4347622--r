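// Fitting criterion and analytic gradient of the single-hidden-layer
// network: E = sum((y - yhat)^2) + lambda * sum(w^2) over all weights of
// both layers. The parameter vector packs W1 ((p+1) x H, column-major,
// row 0 = hidden biases) followed by w2 (length H+1, entry 0 = output
// bias). Called thousands of times per ensemble fit, hence compiled.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline void unpack(const vec &par, int p, int H, mat &W1, vec &w2) {
  W1 = reshape(par.head((p + 1) * H), p + 1, H);
  w2 = par.tail(H + 1);
}

// [[Rcpp::export]]
double nn_fn_cpp(const arma::vec &par, const arma::mat &x1,
                 const arma::vec &y, double lambda, int p, int H) {
  mat W1;
  vec w2;
  unpack(par, p, H, W1, w2);
  mat s = 1.0 / (1.0 + exp(-(x1 * W1)));
  vec r = w2(0) + s * w2.tail(H) - y;
  return dot(r, r) + lambda * dot(par, par);
}

// [[Rcpp::export]]
arma::vec nn_gr_cpp(const arma::vec &par, const arma::mat &x1,
                    const arma::vec &y, double lambda, int p, int H) {
  mat W1;
  vec w2;
  unpack(par, p, H, W1, w2);
  mat s = 1.0 / (1.0 + exp(-(x1 * W1)));
  vec r = w2(0) + s * w2.tail(H) - y;

  vec g2(H + 1);
  g2(0) = 2.0 * accu(r);
  g2.tail(H) = 2.0 * (s.t() * r);

  mat delta = (r * w2.tail(H).t()) % s % (1.0 - s);
  mat g1 = 2.0 * (x1.t() * delta);

  vec grad(par.n_elem);
  grad.head((p + 1) * H) = vectorise(g1);
  grad.tail(H + 1) = g2;
  return grad + 2.0 * lambda * par;
}

// [[Rcpp::export]]
arma::vec nn_predict_cpp(const arma::vec &par, const arma::mat &x1,
                         int p, int H) {
  mat W1;
  vec w2;
  unpack(par, p, H, W1, w2);
  mat s = 1.0 / (1.0 + exp(-(x1 * W1)));
  return w2(0) + s * w2.tail(H);
}
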